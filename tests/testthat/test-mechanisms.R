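# Channel kinetics, Nernst reversals, calcium dynamics, Markov schemes and
# the mechanism-definition schema.

test_that("nernst reproduces closed-form values and properties", {
  p <- nernst_params(34, 2)
  expect_equal(nernst(p, 2, 1e-4), 131.06, tolerance = 1e-4)
  expect_equal(nernst(p, 1, 1), 0)
  # z = 1, ratio e: E = RT/F, frozen closed-form value at 22 C
  expect_equal(nernst(nernst_params(22, 1), exp(1), 1), 25.4339, tolerance = 1e-4)
  # antisymmetry and linearity in T
  expect_equal(nernst(p, 0.3, 1.7), -nernst(p, 1.7, 0.3))
  expect_equal(nernst(nernst_params(2 * 307.15 - 273.15, 2), 2, 1e-4),
               2 * nernst(p, 2, 1e-4))
  expect_error(nernst(p, -1, 1), "positive")
})

test_that("gate rates match the textbook values at -65 mV", {
  hh <- load_mechanism_set("hh")
  n <- hh$k_hh$gates[[1]]
  a <- rate_eval(n$alpha, -65); b <- rate_eval(n$beta, -65)
  expect_equal(a, 0.05820, tolerance = 1e-3)
  expect_equal(b, 0.125, tolerance = 1e-9)
  expect_equal(a / (a + b), 0.3177, tolerance = 1e-3)
  # fixed point: derivative vanishes at inf
  expect_equal(gate_derivative(n, a / (a + b), -65), 0, tolerance = 1e-12)
  # derivative from x = 0 equals alpha
  expect_equal(gate_derivative(n, 0, -65), a, tolerance = 1e-12)
})

test_that("q10 scaling divides tau by q10 per 10 degrees", {
  g <- list(name = "x", exponent = 1,
            alpha = list(form = "constant", rate = 0.2),
            beta = list(form = "constant", rate = 0.3))
  d_ref <- gate_derivative(g, 0.1, -50, temperature_C = 6.3, q10 = 3, tref_C = 6.3)
  d_hot <- gate_derivative(g, 0.1, -50, temperature_C = 16.3, q10 = 3, tref_C = 6.3)
  expect_equal(d_hot / d_ref, 3)
})

test_that("channel_current follows the ohmic gating law", {
  hh <- load_mechanism_set("hh")
  na <- hh$na_hh
  expect_equal(channel_current(na, c(1, 1), v = 0, erev = 50), -6)
  expect_equal(channel_current(na, c(0, 1), v = 0, erev = 50), 0)
  expect_equal(channel_current(na, c(0.3, 0.7), v = 50, erev = 50), 0)
  expect_error(channel_current(na, c(1.5, 1), v = 0, erev = 50), "corrupted")
})

test_that("calcium pool dynamics match the linear ODE solution", {
  pool <- calcium_pool()
  expect_equal(calcium_derivative(pool, 0, pool$ca_rest), 0)
  # steady state under constant current
  i_ca <- -0.05
  ca_ss <- pool$ca_rest - pool$k * pool$tau * i_ca
  expect_equal(calcium_derivative(pool, i_ca, ca_ss), 0, tolerance = 1e-15)
  # exact-exponential relaxation reaches the closed form after 10 tau
  ca <- pool$ca_rest * 50
  for (step in 1:100) {  # 100 steps of tau/10
    dtt <- pool$tau / 10
    target <- pool$ca_rest - pool$k * pool$tau * i_ca
    ca <- target + (ca - target) * exp(-dtt / pool$tau)
  }
  expect_equal(ca, ca_ss, tolerance = 1e-4)
  # with zero current, relaxation toward rest is monotone
  ca <- pool$ca_rest * 10; prev <- ca
  for (step in 1:50) {
    ca <- pool$ca_rest + (ca - pool$ca_rest) * exp(-1 / pool$tau)
    expect_lt(ca, prev); prev <- ca
  }
})

test_that("bundled mechanism sets load and validate", {
  hh <- load_mechanism_set("hh")
  expect_named(hh, c("na_hh", "k_hh", "leak"))
  expect_equal(vapply(hh$na_hh$gates, function(g) g$exponent, numeric(1)), c(3, 1))
  expect_equal(hh$k_hh$gates[[1]]$exponent, 4)
  toy <- load_mechanism_set("toy_allen")
  expect_setequal(names(toy),
                  c("Ih", "NaV", "Kd", "Kv2like", "K_T", "Kv3_1", "Im_v2",
                    "SK", "Ca_HVA", "Ca_LVA", "leak"))
  expect_s3_class(attr(toy, "ca_pool"), "calcium_pool")
  expect_true(toy$Ca_HVA$writes_ca)
  expect_equal(toy$Kd$kind, "markov")
})

test_that("schema errors name the offending mechanisms", {
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(mechanisms = list(
    list(name = "neg", kind = "leak", gbar = -1, erev = -65),
    list(name = "norev", kind = "leak", gbar = 1e-4))),
    bad, auto_unbox = TRUE)
  expect_error(load_mechanism_set(bad), "neg.*negative gbar")
  expect_error(load_mechanism_set(bad), "norev.*missing reversal")
})

test_that("gating curves are well behaved on [-120, 60] mV", {
  v <- seq(-120, 60, by = 0.5)
  for (set in c("hh", "toy_allen")) {
    mechs <- load_mechanism_set(set)
    for (mech in mechs) {
      for (g in mech$gates %||% list()) {
        cv <- pnnsim:::gate_curves(g, v, 34, mech$q10, mech$tref_C)
        expect_true(all(cv$inf >= 0 & cv$inf <= 1),
                    label = paste(set, mech$name, g$name, "inf in [0,1]"))
        expect_true(all(cv$tau > 0),
                    label = paste(set, mech$name, g$name, "tau > 0"))
      }
    }
  }
})

test_that("Markov exact-exponential update matches a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  set.seed(11)
  for (n in 2:4) {
    for (rep in 1:3) {
      # random reversible-ish scheme with sigmoid voltage dependence
      trans <- list()
      for (i in seq_len(n - 1)) {
        trans[[length(trans) + 1]] <- list(
          from = i, to = i + 1,
          rate = list(form = "sigmoid", rate = runif(1, 0.1, 2),
                      vhalf = runif(1, -60, -20), scale = runif(1, 5, 15)))
        trans[[length(trans) + 1]] <- list(
          from = i + 1, to = i,
          rate = list(form = "sigmoid", rate = runif(1, 0.1, 2),
                      vhalf = runif(1, -60, -20), scale = -runif(1, 5, 15)))
      }
      mk <- list(states = paste0("S", 1:n), conducting = n, transitions = trans)
      p0 <- runif(n); p0 <- p0 / sum(p0)
      v <- runif(1, -80, 0); dtt <- 0.5
      p1 <- markov_step(p0, mk, v, dtt)
      Q <- pnnsim:::markov_generator(mk, v)
      p_ref <- as.numeric(Matrix::expm(Q * dtt) %*% p0)
      expect_equal(p1, p_ref, tolerance = 1e-10)
      expect_equal(sum(p1), 1, tolerance = 1e-9)
      expect_true(all(p1 >= -1e-12))
      # stationary distribution is a fixed point
      ps <- pnnsim:::markov_stationary(mk, v)
      expect_equal(markov_step(ps, mk, v, dtt), ps, tolerance = 1e-9)
    }
  }
})

test_that("mechanism_spec rejects inconsistent definitions", {
  expect_error(mechanism_spec("x", "gated", gbar = -0.1, erev = 0), "non-negative")
  expect_error(mechanism_spec("x", "gated", gbar = 0.1, erev = 0), "gate")
  expect_error(mechanism_spec("x", "leak", gbar = 0.1), "reversal")
  expect_error(mechanism_spec("x", "gated", gbar = 0.1, erev = 0,
                              gates = list(list(name = "m", exponent = -2))),
               "non-negative integers")
})
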