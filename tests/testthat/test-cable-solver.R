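# The backward-Euler cable integrator: axial assembly, passive analytics,
# reference-vs-compiled equivalence, conservation and ordering invariants.

test_that("axial conductances match the hand-evaluated formula", {
  # two identical cylinders, l = 5 um, d = 1 um, Ra = 100 Ohm cm:
  # r = 4*100*5e-4 / (pi * (1e-4)^2) = 6.3662e6 Ohm, g = 1/r
  m <- morphology(data.frame(id = 1:2, type = c("soma", "dendrite"),
                             parent = c(0L, 1L), parent_pos = 0.5,
                             length = c(5, 5), diameter = c(1, 1),
                             stringsAsFactors = FALSE))
  cell <- discretize(m, max_seg_len = 5, Ra = 100)
  ax <- assemble_axial_conductances(cell)
  r_full <- 4 * 100 * (5 * 1e-4) / (pi * (1e-4)^2)
  expect_equal(ax$g_S, 1 / r_full, tolerance = 1e-12)
  expect_equal(ax$g_S, 1.5707963e-7, tolerance = 1e-6)
  # one-compartment cell: empty table
  expect_equal(nrow(assemble_axial_conductances(build_oc()$cell)), 0)
})

test_that("a passive compartment follows the RC charging curve", {
  m <- passive_oc()
  dt <- 0.0078125 / 8
  tr <- simulate_model(m, 0.02, dur = 30, settle = 50, dt = dt)
  g <- 3e-4; area <- pi * 10 * 10 * 1e-8; cm_mF <- 1e-3
  tau <- cm_mF / g
  i_dens <- 0.02e-6 / area
  v_an <- -65 + (i_dens / g) * (1 - exp(-tr$t / tau))
  expect_lt(max(abs(tr$v - v_an)) / (i_dens / g), 0.001)  # within 0.1 %
})

test_that("equal-potential coupled passive segments carry no axial flux", {
  m <- passive_bas()
  st <- cable_init_state(m)
  for (i in 1:20) st <- cable_step(m, st, 0.0078125)
  # no stimulus, uniform start at E_leak: stays exactly uniform
  expect_lt(diff(range(st$v)), 1e-10)
  expect_equal(st$v[1], -65, tolerance = 1e-9)
})

test_that("the linear solve is direct: residual at machine precision", {
  for (model in list(oc_model(), bas_model())) {
    st <- cable_init_state(model)
    worst <- 0
    for (i in 1:25) {
      st <- cable_step(model, st, 0.0078125, stim_nA = 0.3)
      worst <- max(worst, attr(st, "residual"))
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("reference stepper and compiled engine agree to solver precision", {
  dt <- 0.0078125
  cases <- list(list(oc_model(), 0.2, 256),
                list(bas_model(), 0.3, 128),
                list(syn_model(), 0.3, 96))
  for (case in cases) {
    model <- case[[1]]; amp <- case[[2]]; n <- case[[3]]
    st <- cable_init_state(model)
    vr <- numeric(n)
    for (i in seq_len(n)) {
      st <- cable_step(model, st, dt, stim_nA = amp)
      vr[i] <- st$v[model$cell$soma_seg]
    }
    vc <- simulate_model(model, amp, dur = n * dt, settle = 0, dt = dt)
    expect_lt(max(abs(vr - vc$v)), 1e-9)
  }
})

test_that("the scheme self-converges and subthreshold traces are dt-robust", {
  oc <- oc_model()
  dt <- 0.0078125
  ref <- simulate_model(oc, 0.2, dur = 50, settle = 100, dt = dt / 8)
  pick <- function(tr, k) tr$v[seq(k, length(tr$v), by = k)]
  e1 <- max(abs(simulate_model(oc, 0.2, dur = 50, settle = 100, dt = dt)$v -
                pick(ref, 8)))
  e2 <- max(abs(simulate_model(oc, 0.2, dur = 50, settle = 100, dt = dt / 2)$v -
                pick(ref, 4)))
  expect_lt(e2, e1)  # halving dt shrinks the error on a firing run
  # subthreshold: halving dt changes the trace by far less than 0.5 mV
  s1 <- simulate_model(oc, 0.005, dur = 100, settle = 100, dt = dt)
  s2 <- simulate_model(oc, 0.005, dur = 100, settle = 100, dt = dt / 2)
  expect_lt(max(abs(s1$v - pick(s2, 2))), 0.5)
})

test_that("results are independent of section ordering", {
  mk <- function(order) {
    secs <- data.frame(
      id = c(1L, 2L, 3L, 4L),
      type = c("soma", "dendrite", "dendrite", "dendrite"),
      parent = c(0L, 1L, 2L, 2L), parent_pos = c(0.5, 0.5, 1, 1),
      length = c(10, 60, 40, 80), diameter = c(10, 1.5, 1, 0.8),
      stringsAsFactors = FALSE)[order, ]
    cell <- discretize(morphology(secs), max_seg_len = 5, Ra = 100)
    mechs <- load_mechanism_set("hh")
    soma <- which(cell$segments$type == "soma")
    pnn_model("perm", cell, mechs,
              list(na_hh = soma, k_hh = soma,
                   leak = seq_len(nrow(cell$segments))),
              stim_dur = 1000)
  }
  t1 <- simulate_model(mk(1:4), 0.05, dur = 20, settle = 50)
  t2 <- simulate_model(mk(c(1, 2, 4, 3)), 0.05, dur = 20, settle = 50)
  expect_lt(max(abs(t1$v - t2$v)), 1e-9)
})

test_that("the resting one-compartment model is quiescent near -65 mV", {
  tr <- memo("oc_rest", simulate_model(oc_model(), 0))
  expect_true(all(abs(tr$v + 65) < 1))
  expect_true(all(tr$v < -20))
})

test_that("ball-and-stick input resistance matches finite-cable theory", {
  m <- passive_bas()
  tr <- simulate_model(m, 0.01, dur = 400, settle = 100)
  r_meas <- (tr$v[length(tr$v)] - (-65)) / 0.01 * 1e6  # mV/nA -> Ohm
  g <- 3e-4; Ra <- 100
  rm <- 1 / g
  d <- 1e-4; l <- 0.1                     # cm
  lambda <- sqrt(rm * d / (4 * Ra))
  r_inf <- sqrt((rm / (pi * d)) * (4 * Ra / (pi * d^2)))
  r_cable <- r_inf / tanh(l / lambda)
  g_soma <- g * pi * 10 * 10 * 1e-8
  r_an <- 1 / (g_soma + 1 / r_cable)
  expect_lt(abs(r_meas - r_an) / r_an, 0.01)
})
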