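# The model library: the study's one-compartment and ball-and-stick
# Hodgkin-Huxley models, the perisomatic Allen-style model builder, and the
# pnn_model container shared by all of them.

#' Construct a runnable neuron model
#'
#' Binds a discretized cell to a mechanism set, a placement map, per-segment
#' specific capacitance and the stimulation/recording rules used by the f-I
#' protocols.
#'
#' @param name model label
#' @param cell a [discretize()]d `compartmental_cell`
#' @param mechs named list of [mechanism_spec()] objects
#' @param placement named list: mechanism name -> integer segment indices
#' @param cm specific membrane capacitance, uF/cm^2; scalar or per segment
#' @param temperature_C simulation temperature
#' @param v_init initial potential, mV
#' @param stim_dur stimulus duration, ms (1000 for HH models, 2000 for
#'   Allen-style models)
#' @param rate_window window (ms relative to stimulus onset) over which the
#'   sustained firing rate is measured
#' @param pool optional [calcium_pool()]; attached to every segment carrying
#'   a calcium-writing mechanism
#' @return a `pnn_model` object
#' @export
pnn_model <- function(name, cell, mechs, placement, cm = 1,
                      temperature_C = 6.3, v_init = -65,
                      stim_dur = 1000, rate_window = NULL, pool = NULL) {
  nseg <- nrow(cell$segments)
  unknown <- setdiff(names(placement), names(mechs))
  if (length(unknown))
    stop("placement names mechanism(s) not in the set: ", paste(unknown, collapse = ", "))
  for (nm in names(placement)) {
    s <- placement[[nm]]
    if (any(s < 1 | s > nseg)) stop("placement of '", nm, "' outside the cell")
  }
  covered <- sort(unique(unlist(placement)))
  if (!identical(covered, seq_len(nseg)))
    stop("placement must cover every segment (leak everywhere); missing: ",
         paste(utils::head(setdiff(seq_len(nseg), covered), 5), collapse = ", "))
  if (length(cm) == 1) cm <- rep(cm, nseg)
  if (length(cm) != nseg) stop("cm must be scalar or one value per segment")
  if (is.null(rate_window)) rate_window <- c(0, stim_dur)
  pool_segs <- integer()
  ca_mechs <- names(mechs)[vapply(mechs, function(m) isTRUE(m$writes_ca), logical(1))]
  ca_mechs <- intersect(ca_mechs, names(placement))
  if (length(ca_mechs)) {
    pool_segs <- sort(unique(unlist(placement[ca_mechs])))
    if (is.null(pool)) pool <- calcium_pool()
  }
  structure(list(name = name, cell = cell, mechs = mechs, placement = placement,
                 cm = cm, temperature_C = temperature_C, v_init = v_init,
                 stim_dur = stim_dur, rate_window = rate_window,
                 sustain_window = c(stim_dur / 2, stim_dur),
                 pool = pool, pool_segs = pool_segs),
            class = "pnn_model")
}

#' @export
print.pnn_model <- function(x, ...) {
  cat("<pnn_model> ", x$name, ": ", nrow(x$cell$segments), " segments, ",
      length(x$mechs), " mechanisms, cm0 = ", signif(mean(x$cm), 3),
      " uF/cm^2, ", x$temperature_C, " C, stimulus ", x$stim_dur, " ms\n", sep = "")
  invisible(x)
}

#' One-compartment Hodgkin-Huxley model
#'
#' A 10 um x 10 um cylindrical soma carrying the classic sodium, potassium
#' and leak conductances at 6.3 C.
#'
#' @return a [pnn_model()]
#' @export
build_oc <- function() {
  morph <- morphology(data.frame(
    id = 1L, type = "soma", parent = 0L, parent_pos = 0.5,
    length = 10, diameter = 10, stringsAsFactors = FALSE), source = "OC")
  cell <- discretize(morph)
  mechs <- load_mechanism_set("hh")
  pnn_model("OC", cell, mechs,
            placement = list(na_hh = 1L, k_hh = 1L, leak = 1L),
            cm = 1, temperature_C = 6.3, v_init = -65,
            stim_dur = 1000, rate_window = c(0, 1000))
}

#' Ball-and-stick Hodgkin-Huxley model
#'
#' A 10 um soma with the HH trio plus a passive dendrite of 1000 um length
#' and 1 um diameter in 5 um segments; dendritic leak 0.0003 S/cm^2 reversing
#' at -65 mV (the somatic resting potential) and axial resistivity 100 Ohm cm.
#'
#' @param dendrite_active if `FALSE` (default) the soma carries the active
#'   conductances and the dendrite only leak
#' @return a [pnn_model()]
#' @export
build_bas <- function(dendrite_active = FALSE) {
  morph <- morphology(data.frame(
    id = c(1L, 2L), type = c("soma", "dendrite"), parent = c(0L, 1L),
    parent_pos = c(0.5, 0.5), length = c(10, 1000), diameter = c(10, 1),
    stringsAsFactors = FALSE), source = "BAS")
  cell <- discretize(morph, max_seg_len = 5, Ra = 100)
  mechs <- load_mechanism_set("hh")
  mechs$leak_dend <- mechanism_spec("leak_dend", "leak", gbar = 3e-4,
                                    erev = -65, ion = "leak")
  soma <- which(cell$segments$type == "soma")
  dend <- which(cell$segments$type == "dendrite")
  active <- if (dendrite_active) c(soma, dend) else soma
  pnn_model("BAS", cell, mechs,
            placement = list(na_hh = active, k_hh = active,
                             leak = soma, leak_dend = dend),
            cm = 1, temperature_C = 6.3, v_init = -65,
            stim_dur = 1000, rate_window = c(0, 1000))
}

#' Build a perisomatic Allen-style model from a parameter bundle
#'
#' The bundle mirrors the structure of the Allen Cell Types Database fit
#' output: an SWC morphology, a mechanism-definition set, fitted maximal
#' conductances for the eleven perisomatic mechanisms, and passive
#' parameters.  All native axon sections are removed and replaced by a
#' 60 um x 1 um initial-segment stub of two sections with two segments each.
#' Active mechanisms are placed on the soma only; leak covers the whole cell.
#'
#' @param bundle either a path to a bundle JSON file (with `swc` given as a
#'   sibling file name) or a list with fields `name`, `swc` (SWC text),
#'   `mechanisms` (set name or path for [load_mechanism_set()]), `gbar`
#'   (named list, S/cm^2, one entry per non-leak mechanism), `passive`
#'   (`cm`, `Ra`, `g_pas`, `e_pas`), `v_init`, `temperature_C`, and
#'   optionally `ca_pool`
#' @param max_seg_len dendritic segment length, um
#' @return a [pnn_model()]
#' @export
build_allen_style <- function(bundle, max_seg_len = 5) {
  if (is.character(bundle)) {
    dir <- dirname(bundle)
    bundle <- jsonlite::read_json(bundle, simplifyVector = TRUE)
    if (length(bundle$swc) == 1 && !grepl("\n", bundle$swc))
      bundle$swc <- paste(readLines(file.path(dir, bundle$swc)), collapse = "\n")
  }
  mechs <- load_mechanism_set(bundle$mechanisms)
  needed <- setdiff(names(mechs), "leak")
  missing <- setdiff(needed, names(bundle$gbar))
  if (length(missing))
    stop("bundle missing conductance(s): ", paste(missing, collapse = ", "))
  for (nm in needed) mechs[[nm]]$gbar <- bundle$gbar[[nm]]
  pas <- bundle$passive
  mechs$leak$gbar <- pas$g_pas
  mechs$leak$erev <- pas$e_pas

  morph <- load_swc(bundle$swc)
  secs <- morph$sections[morph$sections$type != "axon", , drop = FALSE]
  # replace the axon with a 60 um x 1 um stub: two sections, two segments each
  ax_ids <- max(secs$id) + 1:2
  secs <- rbind(secs, data.frame(
    id = ax_ids, type = "axon", parent = c(1L, ax_ids[1]),
    parent_pos = c(0.5, 1.0), length = 30, diameter = 1,
    stringsAsFactors = FALSE))
  morph <- morphology(secs, source = paste0(bundle$name, "-perisomatic"))
  nseg <- setNames(rep(2L, 2), as.character(ax_ids))
  cell <- discretize(morph, max_seg_len = max_seg_len, nseg = nseg, Ra = pas$Ra)

  soma <- which(cell$segments$type == "soma")
  allseg <- seq_len(nrow(cell$segments))
  placement <- c(setNames(lapply(needed, function(nm) soma), needed),
                 list(leak = allseg))
  pool <- if (!is.null(bundle$ca_pool)) do.call(calcium_pool, as.list(bundle$ca_pool))
          else attr(mechs, "ca_pool")
  temp <- if (!is.null(bundle$temperature_C)) bundle$temperature_C
          else if (!is.null(attr(mechs, "temperature_C"))) attr(mechs, "temperature_C")
          else 34
  pnn_model(bundle$name, cell, mechs, placement,
            cm = pas$cm, temperature_C = temp,
            v_init = if (is.null(bundle$v_init)) -70 else bundle$v_init,
            stim_dur = 2000, rate_window = c(1000, 2000), pool = pool)
}

#' Enumerate the nine study configurations
#'
#' The study design pairs each model with the region on which the specific
#' capacitance is perturbed: the one-compartment model (OC), the
#' ball-and-stick model with cm changed everywhere or on the soma + proximal
#' dendrites (BAS all/sprx), and three Allen-style perisomatic models, each
#' in both region variants.  When no parameter bundles are supplied,
#' synthetic stand-in cells take the place of the three database models.
#'
#' @param bundles optional list of three Allen-style parameter bundles (or
#'   bundle paths); synthetic stand-ins are generated otherwise
#' @param seeds seeds for the synthetic stand-ins
#' @param ... passed to [generate_synthetic_cell()]
#' @return data frame with `name`, `cm_region` and a `model` list column
#' @export
study_configurations <- function(bundles = NULL, seeds = c(101L, 102L, 103L),
                                 ...) {
  a_models <- if (!is.null(bundles)) {
    stopifnot(length(bundles) == 3)
    lapply(bundles, build_allen_style)
  } else {
    lapply(seeds, function(s) generate_synthetic_cell(s, ...)$model)
  }
  bas <- build_bas()
  cfg <- data.frame(
    name = c("OC", "BAS,all", "BAS,sprx",
             paste0("A", 1:3, ",all"), paste0("A", 1:3, ",sprx")),
    cm_region = c("all", "all", "sprx", rep("all", 3), rep("sprx", 3)),
    stringsAsFactors = FALSE)
  cfg$model <- c(list(build_oc(), bas, bas), a_models, a_models)
  cfg
}

#' Resolve a model reference
#'
#' Accepts the built-in names `"OC"` and `"BAS"`, a path to a parameter
#' bundle JSON, or `"synthetic:<seed>"` for a generated fixture cell.
#'
#' @param ref model reference string (or an already-built model, returned
#'   unchanged)
#' @return a [pnn_model()]
#' @export
resolve_model <- function(ref) {
  if (inherits(ref, "pnn_model")) return(ref)
  if (identical(ref, "OC")) return(build_oc())
  if (identical(ref, "BAS")) return(build_bas())
  if (grepl("^synthetic:", ref)) {
    seed <- as.integer(sub("^synthetic:", "", ref))
    return(generate_synthetic_cell(seed)$model)
  }
  if (file.exists(ref)) return(build_allen_style(ref))
  stop("cannot resolve model reference '", ref, "'")
}
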