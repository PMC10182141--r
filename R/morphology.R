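# Neuron morphologies: SWC reading, parametric construction, and
# discretization into the compartment tree used by the cable solver.

#' Construct a morphology from a section table
#'
#' A morphology is a tree of unbranched neurite sections.  Exactly one root
#' (parent 0) is allowed; lengths and diameters must be strictly positive.
#'
#' @param sections data frame with columns `id` (integer), `type` (one of
#'   `"soma"`, `"dendrite"`, `"axon"`), `parent` (id of parent section, 0 for
#'   the root), `parent_pos` (attachment position on the parent, 0-1),
#'   `length` and `diameter` (um)
#' @param source label recorded in the metadata
#' @return a `morphology` object
#' @export
morphology <- function(sections, source = "parametric") {
  req <- c("id", "type", "parent", "parent_pos", "length", "diameter")
  if (!all(req %in% names(sections))) stop("sections must have columns ", paste(req, collapse = ", "))
  if (any(sections$length <= 0) || any(sections$diameter <= 0))
    stop("section lengths and diameters must be strictly positive")
  if (sum(sections$parent == 0) != 1) stop("exactly one root section required")
  if (anyDuplicated(sections$id)) stop("duplicate section ids")
  miss <- setdiff(setdiff(sections$parent, 0), sections$id)
  if (length(miss)) stop("dangling parent section id(s): ", paste(miss, collapse = ", "))
  # cycle check: every section must reach the root
  idx <- setNames(seq_len(nrow(sections)), sections$id)
  for (i in seq_len(nrow(sections))) {
    seen <- integer(); j <- i
    while (sections$parent[j] != 0) {
      if (j %in% seen) stop("parent references form a cycle")
      seen <- c(seen, j)
      j <- idx[[as.character(sections$parent[j])]]
    }
  }
  structure(list(sections = sections, source = source), class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  cat("<morphology> ", x$source, ": ", nrow(x$sections), " sections (",
      sum(x$sections$type == "soma"), " soma, ",
      sum(x$sections$type == "dendrite"), " dendrite, ",
      sum(x$sections$type == "axon"), " axon), total length ",
      round(sum(x$sections$length), 1), " um\n", sep = "")
  invisible(x)
}

.swc_type <- function(code) {
  out <- rep("dendrite", length(code))
  out[code == 1] <- "soma"
  out[code == 2] <- "axon"
  unknown <- !(code %in% c(1, 2, 3, 4))
  if (any(unknown))
    warning("unknown SWC type code(s) ", paste(unique(code[unknown]), collapse = ", "),
            " mapped to dendrite")
  out
}

#' Read an SWC morphology
#'
#' Parses standard 7-column SWC text (id, type, x, y, z, radius, parent).
#' All soma samples are merged into one soma section whose length is the
#' path span of the soma samples (one sample: length = diameter).  Non-soma
#' samples are grouped into unbranched sections; section lengths accumulate
#' consecutive 3D point-to-point distances.  Type codes: 1 soma, 2 axon,
#' 3/4 dendrite; unknown codes map to dendrite with a warning.
#'
#' @param swc_text SWC file content as a single string or character vector of
#'   lines; a path to an existing file is also accepted
#' @return a [morphology()]
#' @export
load_swc <- function(swc_text) {
  if (length(swc_text) == 1 && !grepl("\n", swc_text) && file.exists(swc_text))
    swc_text <- readLines(swc_text)
  lines <- unlist(strsplit(swc_text, "\n"))
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("SWC parse error: no sample lines")
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  if (any(lengths(fields) != 7))
    stop("SWC parse error at line ", keep[which(lengths(fields) != 7)[1]],
         ": expected 7 columns")
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (any(is.na(m))) stop("SWC parse error: non-numeric field")
  id <- as.integer(m[, 1]); type <- as.integer(m[, 2])
  xyz <- m[, 3:5, drop = FALSE]; radius <- m[, 6]; parent <- as.integer(m[, 7])
  if (any(radius <= 0))
    stop("SWC validation error at line ", keep[which(radius <= 0)[1]],
         ": zero or negative radius")
  dangling <- parent != -1 & !(parent %in% id)
  if (any(dangling))
    stop("SWC parse error at line ", keep[which(dangling)[1]],
         ": parent id ", parent[which(dangling)[1]], " not in file")
  row <- setNames(seq_along(id), id)
  pidx <- ifelse(parent == -1, NA_integer_, row[as.character(parent)])
  dist_to_parent <- rep(0, length(id))
  has_p <- !is.na(pidx)
  dist_to_parent[has_p] <- sqrt(rowSums((xyz[has_p, , drop = FALSE] -
                                         xyz[pidx[has_p], , drop = FALSE])^2))
  tname <- .swc_type(type)

  is_soma <- tname == "soma"
  if (!any(is_soma)) stop("SWC parse error: no soma sample")
  soma_rows <- which(is_soma)
  soma_len <- sum(dist_to_parent[soma_rows][has_p[soma_rows] &
                                            is_soma[pmax(pidx[soma_rows], 1)]])
  soma_diam <- 2 * mean(radius[soma_rows])
  if (soma_len <= 0) soma_len <- soma_diam

  sections <- data.frame(id = 1L, type = "soma", parent = 0L, parent_pos = 0.5,
                         length = soma_len, diameter = soma_diam,
                         stringsAsFactors = FALSE)
  # children per row among non-soma samples
  nonsoma <- which(!is_soma)
  kids <- split(nonsoma, factor(pidx[nonsoma], levels = seq_along(id)))
  n_kids <- lengths(kids)
  # a sample starts a new section if its parent is soma, missing, or a branch point
  sec_of_row <- rep(NA_integer_, length(id))
  next_id <- 2L
  starts <- nonsoma[is.na(pidx[nonsoma]) | is_soma[pmax(pidx[nonsoma], 1)] |
                    n_kids[pidx[nonsoma]] > 1]
  for (s in starts) {
    chain <- s
    repeat {
      ch <- kids[[chain[length(chain)]]]
      if (length(ch) != 1) break
      chain <- c(chain, ch)
    }
    p <- pidx[s]
    from_soma <- is.na(p) || is_soma[p]
    len <- sum(dist_to_parent[chain[-1]]) + if (from_soma) 0 else dist_to_parent[s]
    if (len <= 0) len <- 2 * mean(radius[chain])  # degenerate zero-length chain
    parent_sec <- if (from_soma) 1L else sec_of_row[p]
    sections <- rbind(sections, data.frame(
      id = next_id, type = tname[s], parent = parent_sec,
      parent_pos = if (from_soma) 0.5 else 1.0,
      length = len, diameter = 2 * mean(radius[chain]),
      stringsAsFactors = FALSE))
    sec_of_row[chain] <- next_id
    next_id <- next_id + 1L
  }
  morphology(sections, source = "swc")
}

#' Discretize a morphology into a compartment tree
#'
#' Splits every section into `ceiling(length / max_seg_len)` equal segments
#' (overridable per section), computes cylinder side areas `pi * d * l`
#' (no end caps), midpoint path distances from the soma attachment point,
#' and the parent linkage of the segment tree.  The soma is kept as a single
#' cylindrical segment by default.
#'
#' @param morph a [morphology()]
#' @param max_seg_len maximal segment length, um
#' @param nseg optional named vector (`section id` -> segment count) taking
#'   precedence over `max_seg_len`
#' @param Ra axial resistivity, Ohm cm
#' @return a `compartmental_cell`: list with `segments` data frame (section,
#'   type, length, diameter, `area` in um^2, `path_mid` in um), `parent`
#'   index vector (0 for the root segment), `Ra`, and metadata
#' @export
discretize <- function(morph, max_seg_len = 5, nseg = NULL, Ra = 100) {
  if (max_seg_len <= 0) stop("max_seg_len must be positive")
  secs <- morph$sections
  # topological order: parents before children
  ord <- integer(); done <- rep(FALSE, nrow(secs))
  while (length(ord) < nrow(secs)) {
    ready <- which(!done & (secs$parent == 0 | done[match(secs$parent, secs$id)]))
    ord <- c(ord, ready); done[ready] <- TRUE
  }
  seg_section <- integer(); seg_type <- character()
  seg_len <- seg_diam <- seg_path0 <- numeric()
  parent <- integer()
  sec_first <- sec_last <- integer(length(ord))  # segment range per section row
  sec_start_dist <- numeric(nrow(secs))
  for (r in ord) {
    n <- if (!is.null(nseg) && as.character(secs$id[r]) %in% names(nseg))
      as.integer(nseg[[as.character(secs$id[r])]])
    else if (secs$type[r] == "soma") 1L
    else as.integer(ceiling(secs$length[r] / max_seg_len))
    l <- secs$length[r] / n
    if (secs$parent[r] == 0) {
      pseg <- 0L
      sec_start_dist[r] <- 0
    } else {
      pr <- match(secs$parent[r], secs$id)
      # attach to the parent segment containing parent_pos
      if (secs$type[pr] == "soma") {
        pseg <- sec_last[pr]
        sec_start_dist[r] <- 0   # measured from the cell body surface
      } else {
        pn <- sec_last[pr] - sec_first[pr] + 1L
        pseg <- sec_first[pr] + min(pn - 1L, floor(secs$parent_pos[r] * pn))
        sec_start_dist[r] <- sec_start_dist[pr] + secs$parent_pos[r] * secs$length[pr]
      }
    }
    base <- length(seg_len)
    seg_section <- c(seg_section, rep(secs$id[r], n))
    seg_type <- c(seg_type, rep(secs$type[r], n))
    seg_len <- c(seg_len, rep(l, n))
    seg_diam <- c(seg_diam, rep(secs$diameter[r], n))
    seg_path0 <- c(seg_path0, sec_start_dist[r] + (seq_len(n) - 0.5) * l)
    parent <- c(parent, pseg, base + seq_len(n - 1L))
    sec_first[r] <- base + 1L; sec_last[r] <- base + n
  }
  segments <- data.frame(
    section = seg_section, type = seg_type, length = seg_len,
    diameter = seg_diam, area = pi * seg_diam * seg_len,
    path_mid = ifelse(seg_type == "soma", 0, seg_path0),
    stringsAsFactors = FALSE)
  soma_rows <- which(secs$type == "soma")
  structure(list(segments = segments, parent = parent, Ra = Ra,
                 soma_seg = sec_first[soma_rows[1]],
                 soma_length = secs$length[soma_rows[1]],
                 source = morph$source),
            class = "compartmental_cell")
}

#' @export
print.compartmental_cell <- function(x, ...) {
  cat("<compartmental_cell> ", nrow(x$segments), " segments (",
      sum(x$segments$type == "soma"), " soma, ",
      sum(x$segments$type == "dendrite"), " dendrite, ",
      sum(x$segments$type == "axon"), " axon), Ra = ", x$Ra, " Ohm cm\n", sep = "")
  invisible(x)
}

#' Path distance from the cell body to a segment midpoint
#'
#' Distances are accumulated along the neurites from the soma attachment
#' point to the segment midpoint; soma segments return 0.
#'
#' @param cell a [discretize()]d cell
#' @param segment segment index (1-based)
#' @return distance in um
#' @export
path_distance <- function(cell, segment) {
  if (any(segment < 1 | segment > nrow(cell$segments)))
    stop("unknown segment index")
  cell$segments$path_mid[segment]
}

#' Soma + proximal-dendrite ("sprx") region mask
#'
#' Returns the soma segments plus every dendrite segment whose midpoint lies
#' less than `factor` soma lengths (path distance) from the cell body.  Axon
#' segments are never included.  This is the territory assumed to be covered
#' by perineuronal nets.
#'
#' @param cell a [discretize()]d cell
#' @param soma_length soma length in um (default: from the cell metadata)
#' @param factor multiple of the soma length delimiting "proximal"
#' @return integer vector of segment indices
#' @export
proximal_mask <- function(cell, soma_length = cell$soma_length, factor = 3.5) {
  if (soma_length <= 0) stop("soma_length must be positive")
  segs <- cell$segments
  which(segs$type == "soma" |
        (segs$type == "dendrite" & segs$path_mid < factor * soma_length))
}

#' Write a morphology summary as JSON
#'
#' @param morph a [morphology()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_morphology_summary <- function(morph, path) {
  jsonlite::write_json(
    list(source = morph$source, sections = morph$sections),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
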