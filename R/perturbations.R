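# Parameter perturbations modelling hypothesized effects of perineuronal-net
# degradation: specific-capacitance scaling (everywhere or restricted to the
# soma + proximal dendrites), conductance scaling, and reversal-potential
# shifts (for calcium, via the fixed extracellular concentration that sets
# the initial Nernst reversal).

#' Perturbation specification
#'
#' @param cm_factor multiplier on the specific membrane capacitance
#' @param cm_region `"all"` (whole cell) or `"sprx"` (soma + proximal
#'   dendrites, see [proximal_mask()])
#' @param g_factors named numeric vector/list: mechanism -> conductance
#'   factor, each in \[0.3, 10\]
#' @param e_shifts named numeric: ion (`"na"`, `"k"`, `"leak"`, `"ca"`) ->
#'   additive reversal shift in mV, each in \[-20, 20\] except calcium (see
#'   `ca_out_factor`); a shift on `"k"` applies to every potassium-carrying
#'   mechanism, on `"leak"` to every leak mechanism
#' @param ca_out_factor multiplier on the fixed extracellular calcium
#'   concentration; this shifts the initial calcium reversal by
#'   `(RT/2F) ln(factor)` while leaving the dynamics otherwise unchanged.
#'   A `"ca"` entry in `e_shifts` is translated to the equivalent factor
#'   `exp(2 F dE / (R T))`.
#' @param label optional label
#' @return a `pnn_perturbation`
#' @export
pnn_perturbation <- function(cm_factor = 1, cm_region = c("all", "sprx"),
                             g_factors = NULL, e_shifts = NULL,
                             ca_out_factor = 1, label = NULL) {
  cm_region <- match.arg(cm_region)
  if (cm_factor <= 0) stop("cm_factor must be positive")
  g_factors <- unlist(g_factors)
  if (length(g_factors)) {
    if (is.null(names(g_factors)) || any(!nzchar(names(g_factors))))
      stop("g_factors must be named by mechanism")
    if (any(g_factors < 0.3 - 1e-12 | g_factors > 10 + 1e-12))
      stop("conductance factors must lie in [0.3, 10]")
  }
  e_shifts <- unlist(e_shifts)
  if (length(e_shifts)) {
    bad <- setdiff(names(e_shifts), c("na", "k", "leak", "ca", "nonspecific"))
    if (length(bad)) stop("unknown ion(s) in e_shifts: ", paste(bad, collapse = ", "))
    fixed <- setdiff(names(e_shifts), "ca")
    if (any(abs(e_shifts[fixed]) > 20 + 1e-12))
      stop("fixed reversal shifts must lie in [-20, 20] mV")
  }
  if (ca_out_factor <= 0) stop("ca_out_factor must be positive")
  if (is.null(label)) {
    bits <- c(if (cm_factor != 1) paste0(cm_factor, "cm_", cm_region),
              if (length(g_factors)) paste0(g_factors, "x", names(g_factors)),
              if (length(e_shifts)) paste0("E", names(e_shifts),
                                           sprintf("%+g", e_shifts)),
              if (ca_out_factor != 1) paste0(ca_out_factor, "xCaout"))
    label <- if (length(bits)) paste(bits, collapse = "+") else "baseline"
  }
  structure(list(cm_factor = cm_factor, cm_region = cm_region,
                 g_factors = g_factors, e_shifts = e_shifts,
                 ca_out_factor = ca_out_factor, label = label),
            class = "pnn_perturbation")
}

#' Apply a perturbation to a model
#'
#' Returns a derived model; the input is never modified.  Capacitance is
#' scaled on the requested region mask, each named conductance is scaled,
#' fixed reversal potentials are shifted additively per ion, and calcium
#' reversal changes are expressed through the fixed extracellular calcium
#' concentration so that `E_Ca(t = 0)` shifts by exactly the requested
#' amount while remaining dynamic thereafter.
#'
#' @param model a [pnn_model()]
#' @param p a [pnn_perturbation()]
#' @return the derived [pnn_model()]
#' @export
apply_perturbation <- function(model, p) {
  out <- model
  mask <- if (p$cm_region == "all") seq_len(nrow(model$cell$segments))
          else proximal_mask(model$cell)
  out$cm[mask] <- out$cm[mask] * p$cm_factor
  for (nm in names(p$g_factors)) {
    if (!nm %in% names(model$mechs))
      stop("perturbation names absent mechanism '", nm, "'")
    out$mechs[[nm]]$gbar <- out$mechs[[nm]]$gbar * p$g_factors[[nm]]
  }
  caf <- p$ca_out_factor
  for (ion in names(p$e_shifts)) {
    if (ion == "ca") {
      np <- nernst_params(model$temperature_C, 2L)
      caf <- caf * exp(2 * np$F * p$e_shifts[[ion]] / 1000 / (np$R * np$T))
      next
    }
    hit <- FALSE
    for (nm in names(out$mechs))
      if (out$mechs[[nm]]$ion == ion) {
        out$mechs[[nm]]$erev <- out$mechs[[nm]]$erev + p$e_shifts[[ion]]
        hit <- TRUE
      }
    if (!hit) stop("no mechanism carries ion '", ion, "'")
  }
  if (caf != 1) {
    if (is.null(out$pool)) stop("calcium reversal shift on a model without calcium")
    out$pool$ca_out <- out$pool$ca_out * caf
  }
  out$perturbation <- p$label
  out
}

#' Relative f difference at the largest common sustained current
#'
#' Finds `I* = max{I : f_a(I) > 0 and f_b(I) > 0}` on the shared grid and
#' returns `(f_a(I*) - f_b(I*)) / f_a(I*)`.
#'
#' @param curve_a,curve_b [fi_curve()] results on the same current grid
#' @return signed fraction (positive when `curve_b` is lower)
#' @export
relative_difference_at_max_common <- function(curve_a, curve_b) {
  common <- merge(curve_a, curve_b, by = "I_nA", suffixes = c("_a", "_b"))
  common <- common[common$f_Hz_a > 0 & common$f_Hz_b > 0, ]
  if (!nrow(common)) stop("statistic undefined: no common sustained current")
  i <- which.max(common$I_nA)
  (common$f_Hz_a[i] - common$f_Hz_b[i]) / common$f_Hz_a[i]
}

#' Scan one parameter axis
#'
#' Builds one perturbed model per value on the requested axis (`"cm"`,
#' `"conductance:<mech>"` or `"reversal:<ion>"`), computes an f-I curve,
#' threshold and spike-width summaries at the probe currents for each, and
#' the relative f difference of each curve against baseline.
#'
#' Per-point protocol failures (e.g. no firing anywhere at an extreme
#' factor) are recorded as gaps, not errors.
#'
#' @param model a [pnn_model()] or model reference
#' @param axis scan axis
#' @param values numeric values on the axis (cm/conductance: factors;
#'   reversal: shifts in mV)
#' @param cm_region region for cm scans (`"all"` or `"sprx"`)
#' @param dI,I_cap,dt f-I protocol parameters
#' @param probes currents (nA) at which frequency and mean spike width are
#'   additionally reported
#' @param thresholds also run the rheobase search per value
#' @return a `scan_result`: list with `curves` (named list of [fi_curve()]),
#'   `stats` (data frame), `baseline` label, and `gaps`
#' @export
scan_parameter <- function(model, axis, values, cm_region = "all",
                           dI = 0.01, I_cap = 1.0, dt = 0.0078125,
                           probes = c(0.2, 0.4), thresholds = TRUE) {
  model <- resolve_model(model)
  specs <- lapply(values, function(x) {
    if (axis == "cm")
      pnn_perturbation(cm_factor = x, cm_region = cm_region,
                       label = paste0(x, "cm_", cm_region))
    else if (grepl("^conductance:", axis)) {
      mech <- sub("^conductance:", "", axis)
      pnn_perturbation(g_factors = setNames(x, mech),
                       label = paste0(x, "x", mech))
    } else if (grepl("^reversal:", axis)) {
      ion <- sub("^reversal:", "", axis)
      pnn_perturbation(e_shifts = setNames(x, ion),
                       label = sprintf("E%s%+g", ion, x))
    } else stop("unknown scan axis '", axis, "'")
  })
  run_scenarios(model, specs, dI = dI, I_cap = I_cap, dt = dt,
                probes = probes, thresholds = thresholds, axis = axis,
                values = values)
}

#' Evaluate a list of perturbation scenarios against baseline
#'
#' Computes the baseline f-I curve plus one per scenario, with threshold,
#' probe-current frequencies/widths and the relative f difference vs
#' baseline at the largest common sustained current.
#'
#' @inheritParams scan_parameter
#' @param scenarios list of [pnn_perturbation()]s
#' @param axis,values optional axis annotation carried into the tidy stats
#' @return a `scan_result`
#' @export
run_scenarios <- function(model, scenarios, dI = 0.01, I_cap = 1.0,
                          dt = 0.0078125, probes = c(0.2, 0.4),
                          thresholds = TRUE, axis = "scenario",
                          values = NULL) {
  model <- resolve_model(model)
  if (is.null(values)) values <- seq_along(scenarios)
  base_curve <- fi_curve(model, dI = dI, I_cap = I_cap, dt = dt)
  curves <- list(baseline = base_curve)
  gaps <- character()
  stats <- list()
  eval_one <- function(m, label, value) {
    curve <- fi_curve(m, dI = dI, I_cap = I_cap, dt = dt)
    thr <- if (thresholds)
      tryCatch(find_threshold(m, I_cap = I_cap, dt = dt), error = function(e) NA_real_)
    else NA_real_
    rel <- if (label == "baseline") 0 else
      tryCatch(relative_difference_at_max_common(base_curve, curve),
               error = function(e) NA_real_)
    prow <- lapply(probes, function(a) {
      tr <- simulate_model(m, a, dt = dt)
      f <- sustained_frequency(detect_spikes(tr), c(0, m$stim_dur), m$rate_window)
      w <- if (f > 0) mean_spike_width(tr) else NA_real_
      c(f, w)
    })
    row <- data.frame(model = model$name, axis = axis, value = value,
                      label = label, threshold_nA = thr, rel_diff = rel,
                      termination = attr(curve, "termination"),
                      stringsAsFactors = FALSE)
    for (k in seq_along(probes)) {
      row[[paste0("f_", probes[k], "nA")]] <- prow[[k]][1]
      row[[paste0("width_", probes[k], "nA_ms")]] <- prow[[k]][2]
    }
    list(curve = curve, row = row)
  }
  b <- eval_one(model, "baseline", NA_real_)
  stats[["baseline"]] <- b$row
  for (i in seq_along(scenarios)) {
    p <- scenarios[[i]]
    res <- tryCatch({
      m <- apply_perturbation(model, p)
      eval_one(m, p$label, values[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      gaps <- c(gaps, paste0(p$label, ": ", conditionMessage(res)))
      next
    }
    curves[[p$label]] <- res$curve
    stats[[p$label]] <- res$row
  }
  if (length(gaps)) message("scan gaps: ", paste(gaps, collapse = "; "))
  structure(list(curves = curves, stats = do.call(rbind, stats),
                 baseline = model$name, gaps = gaps),
            class = "scan_result")
}

#' Tidy long-format view of a scan
#'
#' @param x a `scan_result`
#' @param ... unused
#' @return data frame with `model`, `label`, `I_nA`, `f_Hz`
#' @export
as.data.frame.scan_result <- function(x, ...) {
  do.call(rbind, lapply(names(x$curves), function(nm) {
    data.frame(model = x$baseline, label = nm,
               I_nA = x$curves[[nm]]$I_nA, f_Hz = x$curves[[nm]]$f_Hz,
               stringsAsFactors = FALSE)
  }))
}

#' Load a scan/scenario configuration file
#'
#' Config files are JSON with `kind` either `"scan"` (fields `axis`,
#' `values`, optional `cm_region`, `probes`) or `"scenarios"` (field
#' `scenarios`: list of [pnn_perturbation()] argument lists).  The bundled
#' configs `fig2` ... `fig6` encode the study design: cm scans (everywhere
#' and soma+proximal), reversal-potential scans, conductance scans, and the
#' combinatorial candidate-mechanism scenarios.
#'
#' @param path file path or a bundled name (`"fig2"` ... `"fig6"`)
#' @return parsed config list
#' @export
load_scan_config <- function(path) {
  if (grepl("^fig[2-6]$", path))
    path <- system.file("extdata", "config", paste0(path, ".json"),
                        package = "pnnsim", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(cfg$kind) || !cfg$kind %in% c("scan", "scenarios"))
    stop("config schema violation in ", path, ": 'kind' must be 'scan' or 'scenarios'")
  if (cfg$kind == "scan" && (is.null(cfg$axis) || is.null(cfg$values)))
    stop("config schema violation in ", path, ": scan needs 'axis' and 'values'")
  if (cfg$kind == "scenarios" && is.null(cfg$scenarios))
    stop("config schema violation in ", path, ": missing 'scenarios'")
  cfg
}

#' Run a configuration against a model
#'
#' Scan axes naming mechanisms or ions absent from the model are skipped
#' with a recorded gap (e.g. calcium scans on the calcium-free HH models).
#'
#' @param model a [pnn_model()] or model reference
#' @param cfg a [load_scan_config()] result or bundled config name
#' @param dI,I_cap,dt,probes protocol overrides (defaults from the config,
#'   falling back to the protocol defaults)
#' @return a `scan_result`, or a named list of them for multi-axis configs
#' @export
run_scan_config <- function(model, cfg, dI = NULL, I_cap = NULL,
                            dt = 0.0078125, probes = NULL, thresholds = NULL) {
  model <- resolve_model(model)
  if (is.character(cfg)) cfg <- load_scan_config(cfg)
  dI <- dI %||% cfg$dI %||% 0.01
  I_cap <- I_cap %||% cfg$I_cap %||% 1.0
  probes <- probes %||% cfg$probes %||% c(0.2, 0.4)
  thresholds <- thresholds %||% cfg$thresholds %||% TRUE
  if (cfg$kind == "scenarios") {
    specs <- lapply(cfg$scenarios, function(s) do.call(pnn_perturbation, s))
    return(run_scenarios(model, specs, dI = dI, I_cap = I_cap, dt = dt,
                         probes = probes, thresholds = thresholds))
  }
  axes <- cfg$axis
  if (identical(axes, "conductance:*"))
    axes <- paste0("conductance:", names(model$mechs))
  if (identical(axes, "reversal:*")) {
    ions <- intersect(unique(vapply(model$mechs, function(m) m$ion, character(1))),
                      c("na", "k", "leak"))
    if (!is.null(model$pool)) ions <- c(ions, "ca")
    axes <- paste0("reversal:", ions)
  }
  out <- list()
  for (ax in axes) {
    res <- tryCatch(
      scan_parameter(model, ax, cfg$values,
                     cm_region = cfg$cm_region %||% "all",
                     dI = dI, I_cap = I_cap, dt = dt, probes = probes,
                     thresholds = thresholds),
      error = function(e) e)
    if (inherits(res, "error")) {
      message("axis ", ax, " skipped: ", conditionMessage(res))
      next
    }
    out[[ax]] <- res
  }
  if (length(out) == 1) out[[1]] else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
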