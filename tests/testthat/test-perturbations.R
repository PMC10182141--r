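# Perturbation semantics: region-restricted capacitance scaling,
# conductance factors, reversal shifts (calcium via extracellular
# concentration), and the comparison statistics.

test_that("the identity perturbation is a no-op and apply is pure", {
  oc <- oc_model()
  ident <- pnn_perturbation()
  expect_equal(ident$label, "baseline")
  m <- apply_perturbation(oc, ident)
  expect_equal(m$cm, oc$cm)
  expect_equal(m$mechs, oc$mechs)
  # purity: applying a real perturbation leaves the input untouched
  cm_before <- oc$cm
  invisible(apply_perturbation(oc, pnn_perturbation(cm_factor = 2)))
  expect_identical(oc$cm, cm_before)
  # repeated application yields identical derived models
  p <- pnn_perturbation(cm_factor = 1.5, g_factors = c(na_hh = 2))
  expect_equal(apply_perturbation(oc, p), apply_perturbation(oc, p))
})

test_that("sprx and all coincide for the one-compartment model", {
  oc <- oc_model()
  a <- apply_perturbation(oc, pnn_perturbation(1.5, "all"))
  s <- apply_perturbation(oc, pnn_perturbation(1.5, "sprx"))
  expect_equal(a$cm, s$cm)
})

test_that("sprx restricts the capacitance change on the ball-and-stick model", {
  bas <- bas_model()
  s <- apply_perturbation(bas, pnn_perturbation(1.5, "sprx"))
  mask <- proximal_mask(bas$cell)
  expect_equal(s$cm[mask], rep(1.5, length(mask)))
  expect_equal(s$cm[-mask], rep(1, nrow(bas$cell$segments)) [-mask])
  # and the restriction is dynamically relevant: all vs sprx traces diverge
  a <- apply_perturbation(bas, pnn_perturbation(1.5, "all"))
  ta <- simulate_model(a, 0.2, dur = 120, settle = 300)
  ts <- simulate_model(s, 0.2, dur = 120, settle = 300)
  expect_gt(max(abs(ta$v - ts$v)), 1)
})

test_that("calcium reversal shifts act through the extracellular concentration", {
  syn <- syn_model()
  np <- nernst_params(syn$temperature_C, 2)
  e0 <- nernst(np, syn$pool$ca_out, syn$pool$ca_rest)
  # additive shift: E_Ca(0) moves by exactly dE (closed-form inversion)
  for (dE in c(-20, 10, 30)) {
    m <- apply_perturbation(syn, pnn_perturbation(e_shifts = c(ca = dE)))
    expect_equal(nernst(np, m$pool$ca_out, m$pool$ca_rest), e0 + dE,
                 tolerance = 1e-6)
  }
  # +30 mV at 34 C multiplies [Ca]_out by ~9.65
  m30 <- apply_perturbation(syn, pnn_perturbation(e_shifts = c(ca = 30)))
  expect_equal(m30$pool$ca_out / syn$pool$ca_out, 9.6499, tolerance = 1e-4)
  # the x10 concentration protocol lands on the printed altered reversal
  m10 <- apply_perturbation(syn, pnn_perturbation(ca_out_factor = 10))
  expect_equal(nernst(np, m10$pool$ca_out, 1e-4), 161.53, tolerance = 5e-3)
})

test_that("reversal shifts address ions, conductance factors mechanisms", {
  syn <- syn_model()
  m <- apply_perturbation(syn, pnn_perturbation(e_shifts = c(k = -10)))
  kmechs <- names(syn$mechs)[vapply(syn$mechs, function(x) x$ion == "k", logical(1))]
  expect_gt(length(kmechs), 3)
  for (nm in kmechs) expect_equal(m$mechs[[nm]]$erev, syn$mechs[[nm]]$erev - 10)
  m2 <- apply_perturbation(syn, pnn_perturbation(g_factors = c(SK = 4)))
  expect_equal(m2$mechs$SK$gbar, 4 * syn$mechs$SK$gbar)
  expect_error(apply_perturbation(oc_model(),
                                  pnn_perturbation(g_factors = c(SK = 2))),
               "absent mechanism")
  # leak shifts hit both somatic and dendritic leak on BAS
  bas <- apply_perturbation(bas_model(), pnn_perturbation(e_shifts = c(leak = 5)))
  expect_equal(bas$mechs$leak$erev, -54.3 + 5)
  expect_equal(bas$mechs$leak_dend$erev, -60)
})

test_that("perturbation validation enforces the documented ranges", {
  expect_error(pnn_perturbation(g_factors = c(na_hh = 0.2)), "0.3")
  expect_error(pnn_perturbation(e_shifts = c(na = 25)), "20")
  expect_error(pnn_perturbation(e_shifts = c(cl = 5)), "unknown ion")
  expect_error(pnn_perturbation(cm_factor = 0), "positive")
  expect_silent(pnn_perturbation(e_shifts = c(ca = 30)))  # Ca exempt from +-20
})

test_that("relative_difference_at_max_common is exact on constructed curves", {
  grid <- seq(0, 0.5, by = 0.01)
  f <- ifelse(grid >= 0.1 & grid <= 0.4, 100 * grid, 0)
  a <- structure(data.frame(I_nA = grid, f_Hz = f),
                 class = c("fi_curve", "data.frame"))
  b <- a; b$f_Hz <- 0.62 * a$f_Hz
  expect_identical(relative_difference_at_max_common(a, a), 0)
  expect_equal(relative_difference_at_max_common(a, b), 0.38, tolerance = 1e-12)
  disjoint <- a
  disjoint$f_Hz <- ifelse(grid > 0.45, 10, 0)
  expect_error(relative_difference_at_max_common(a, disjoint),
               "no common sustained current")
})

test_that("scans validate ranges and include the identity member", {
  expect_error(scan_parameter(oc_model(), "conductance:na_hh", c(0.2, 1)),
               "0.3")
  res <- scan_parameter(oc_model(), "reversal:na", c(-10, 0, 10),
                        dI = 0.05, I_cap = 0.1, probes = 0.05,
                        thresholds = FALSE)
  expect_length(res$curves, 4)  # baseline + 3
  zero <- res$curves[[which(vapply(names(res$curves), function(x)
    grepl("\\+0$", x), logical(1)))[1]]]
  expect_equal(zero$f_Hz, res$curves$baseline$f_Hz)
  tidy <- as.data.frame(res)
  expect_named(tidy, c("model", "label", "I_nA", "f_Hz"))
})

test_that("scenario runs report gaps instead of failing wholesale", {
  cfg <- load_scan_config("fig6")
  expect_length(cfg$scenarios, 5)
  expect_equal(cfg$scenarios[[1]]$e_shifts$na, 10)
  expect_equal(cfg$scenarios[[1]]$cm_factor, 1.5)
  # on OC the Allen-mechanism scenarios are all gaps, baseline remains
  res <- suppressMessages(
    run_scan_config(oc_model(), cfg, dI = 0.05, I_cap = 0.1,
                    probes = 0.05, thresholds = FALSE))
  expect_length(res$gaps, 5)
  expect_named(res$curves, "baseline")
  # empty scenario list: baseline only, no gaps
  res0 <- run_scenarios(oc_model(), list(), dI = 0.05, I_cap = 0.1,
                        probes = 0.05, thresholds = FALSE)
  expect_named(res0$curves, "baseline")
  expect_length(res0$gaps, 0)
})

test_that("config files validate against the schema", {
  for (nm in paste0("fig", 2:6)) expect_silent(load_scan_config(nm))
  bad <- tempfile(fileext = ".json")
  writeLines('{"kind": "scan"}', bad)
  expect_error(load_scan_config(bad), "schema violation")
  writeLines('{"kind": "scan", "axis": "cm"', bad)  # truncated
  expect_error(load_scan_config(bad), class = "error")
})
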