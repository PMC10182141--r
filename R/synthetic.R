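# Synthetic fixture cells: reproducible random branched morphologies with
# randomized channel-density sets in the Allen-style bundle schema, so the
# whole pipeline (SWC -> model -> protocols -> scans) runs with no downloads.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

rand_unit <- function() {
  v <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, 0.2, 1))
  v / sqrt(sum(v^2))
}

#' Generate a synthetic Allen-like fixture cell
#'
#' Builds a reproducible random branched morphology (binary dendritic tree;
#' section lengths 20-200 um, diameters 0.5-2 um, soma 10-20 um) plus a
#' randomized channel-density set drawn uniformly from 0.5-1.5 times the
#' toy mechanism-set defaults, emits valid SWC text and a parameter bundle,
#' and assembles the perisomatic model via [build_allen_style()].
#'
#' @param seed integer seed; the same seed always yields byte-identical SWC
#' @param n_dendrites number of primary dendrites
#' @param depth branching depth (each non-terminal section forks in two)
#' @param dir optional directory: writes `synthetic_<seed>.swc` and
#'   `synthetic_<seed>.json` (bundle) there
#' @param ensure_firing if `TRUE`, advance the seed (seed, seed+1, ...) until
#'   the generated cell fires sustainedly for some current in a coarse
#'   0-0.5 nA sweep
#' @param max_tries seed advance limit for `ensure_firing`
#' @return list with `model` ([pnn_model()]), `swc` (text), `bundle` (list)
#'   and `seed` (the seed actually used)
#' @export
generate_synthetic_cell <- function(seed, n_dendrites = 3, depth = 2,
                                    dir = NULL, ensure_firing = FALSE,
                                    max_tries = 20) {
  stopifnot(n_dendrites >= 1, depth >= 1)
  make <- function(s) with_seed(s, {
    soma_r <- runif(1, 5, 10)
    lines <- sprintf("%d 1 %.4f %.4f %.4f %.4f %d", 1L, 0, 0, 0, soma_r, -1L)
    nid <- 1L
    emit <- function(x, y, z, r, parent, type = 3L) {
      nid <<- nid + 1L
      lines <<- c(lines, sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                                 nid, type, x, y, z, r, parent))
      nid
    }
    grow <- function(parent_id, pos, level) {
      len <- runif(1, 20, 200); r <- runif(1, 0.25, 1); d <- rand_unit()
      if (parent_id == 1L) {
        # primary dendrite: two samples so the section has intrinsic length
        a <- emit(pos[1], pos[2], pos[3], r, parent_id)
        end <- pos + d * len
        b <- emit(end[1], end[2], end[3], r, a)
      } else {
        end <- pos + d * len
        b <- emit(end[1], end[2], end[3], r, parent_id)
      }
      if (level < depth) for (i in 1:2) grow(b, end, level + 1)
    }
    for (i in seq_len(n_dendrites)) grow(1L, c(0, 0, 0), 1L)
    swc <- paste(lines, collapse = "\n")

    defaults <- load_mechanism_set("toy_allen")
    gbar <- lapply(defaults[setdiff(names(defaults), "leak")],
                   function(m) m$gbar * runif(1, 0.5, 1.5))
    bundle <- list(
      name = paste0("synthetic_", s), synthetic = TRUE, seed = s,
      swc = swc, mechanisms = "toy_allen", gbar = gbar,
      passive = list(cm = 1, Ra = 100,
                     g_pas = defaults$leak$gbar * runif(1, 0.5, 1.5),
                     e_pas = -65),
      v_init = -65, temperature_C = 34)
    list(model = build_allen_style(bundle), swc = swc, bundle = bundle, seed = s)
  })
  out <- make(seed)
  if (ensure_firing) {
    tries <- 0
    while (!fires_somewhere(out$model) && tries < max_tries) {
      tries <- tries + 1
      out <- make(seed + tries)
    }
    if (tries == max_tries) stop("no firing synthetic cell within max_tries seeds")
  }
  if (!is.null(dir)) {
    writeLines(out$swc, file.path(dir, paste0("synthetic_", out$seed, ".swc")))
    b <- out$bundle
    b$swc <- paste0("synthetic_", out$seed, ".swc")
    jsonlite::write_json(b, file.path(dir, paste0("synthetic_", out$seed, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# Coarse check that a model fires sustainedly for some current <= 0.5 nA.
fires_somewhere <- function(model, amps = seq(0.1, 0.5, by = 0.1)) {
  for (a in amps) {
    tr <- simulate_model(model, a)
    if (sustained_frequency(detect_spikes(tr), c(0, model$stim_dur),
                            model$rate_window) > 0)
      return(TRUE)
  }
  FALSE
}
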