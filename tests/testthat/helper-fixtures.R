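# Shared fixtures.  Expensive simulation products (models, f-I curves,
# thresholds) are memoized so acceptance and unit tests can share them.

.fixture_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

oc_model <- function() memo("oc", build_oc())
bas_model <- function() memo("bas", build_bas())

# the standard synthetic Allen-like fixture used across the suite
# (small enough that a 2600 ms simulation takes ~1 s)
syn_fixture <- function() memo("syn42", generate_synthetic_cell(42, n_dendrites = 2, depth = 1))
syn_model <- function() syn_fixture()$model

# passive variants for cable-theory checks
passive_oc <- function(g_leak = 3e-4, e_leak = -65) {
  morph <- morphology(data.frame(id = 1L, type = "soma", parent = 0L,
                                 parent_pos = 0.5, length = 10, diameter = 10,
                                 stringsAsFactors = FALSE))
  cell <- discretize(morph)
  leak <- mechanism_spec("leak", "leak", gbar = g_leak, erev = e_leak, ion = "leak")
  pnn_model("passiveOC", cell, list(leak = leak), list(leak = 1L),
            cm = 1, v_init = e_leak, stim_dur = 1000)
}

passive_bas <- function(g_leak = 3e-4, e_leak = -65) {
  morph <- morphology(data.frame(
    id = c(1L, 2L), type = c("soma", "dendrite"), parent = c(0L, 1L),
    parent_pos = c(0.5, 0.5), length = c(10, 1000), diameter = c(10, 1),
    stringsAsFactors = FALSE))
  cell <- discretize(morph, max_seg_len = 5, Ra = 100)
  leak <- mechanism_spec("leak", "leak", gbar = g_leak, erev = e_leak, ion = "leak")
  pnn_model("passiveBAS", cell, list(leak = leak),
            list(leak = seq_len(nrow(cell$segments))),
            cm = 1, v_init = e_leak, stim_dur = 1000)
}

# sustained frequency of a model at one current (cached per model label)
f_at <- function(model, amp, key = NULL, dt = 0.0078125) {
  compute <- function() {
    tr <- simulate_model(model, amp, dt = dt)
    sustained_frequency(detect_spikes(tr), c(0, model$stim_dur), model$rate_window)
  }
  if (is.null(key)) compute()
  else memo(paste0("f_", key, "_", amp, "_", dt), compute())
}

oc_threshold <- function(cm_factor = 1) memo(paste0("thr_oc_", cm_factor), {
  m <- apply_perturbation(oc_model(), pnn_perturbation(cm_factor = cm_factor))
  find_threshold(m)
})

bas_threshold <- function(cm_factor = 1, region = "all")
  memo(paste0("thr_bas_", region, "_", cm_factor), {
    m <- apply_perturbation(bas_model(),
                            pnn_perturbation(cm_factor = cm_factor,
                                             cm_region = region))
    find_threshold(m)
  })
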