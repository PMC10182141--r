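# File interfaces: voltage-trace CSV, f-I curve CSV, tidy scan CSV, and the
# JSON run manifests that make every output reproducible.

#' Write a voltage trace as two-column CSV with a JSON sidecar
#'
#' @param trace a `voltage_trace`
#' @param path output CSV (`time_ms`, `v_mV`); the sidecar is `<path>.json`
#' @param meta extra fields merged into the sidecar
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path, meta = list()) {
  write.csv(data.frame(time_ms = trace$t, v_mV = trace$v), path, row.names = FALSE)
  jsonlite::write_json(
    c(list(model = trace$model, amp_nA = trace$amp_nA, dt = trace$dt), meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voltage trace written by [write_trace()]
#'
#' @param path CSV path
#' @return a `voltage_trace`
#' @export
read_trace <- function(path) {
  d <- read.csv(path)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE) else list()
  structure(list(t = d$time_ms, v = d$v_mV,
                 dt = meta$dt %||% (d$time_ms[2] - d$time_ms[1]),
                 amp_nA = meta$amp_nA, model = meta$model),
            class = "voltage_trace")
}

#' Write an f-I curve as CSV plus JSON metadata
#'
#' @param curve an [fi_curve()]
#' @param path output CSV (`I_nA`, `f_Hz`)
#' @return `path`, invisibly
#' @export
write_fi_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  jsonlite::write_json(
    list(model = attr(curve, "model"), dI = attr(curve, "dI"),
         termination = attr(curve, "termination")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an f-I curve written by [write_fi_curve()]
#' @param path CSV path
#' @return an `fi_curve`
#' @export
read_fi_curve <- function(path) {
  d <- read.csv(path)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE) else list()
  structure(d, class = c("fi_curve", "data.frame"),
            model = meta$model, dI = meta$dI, termination = meta$termination)
}

#' Write a scan result: tidy CSV plus statistics JSON
#'
#' @param scan a `scan_result`
#' @param prefix output prefix; writes `<prefix>_curves.csv` and
#'   `<prefix>_stats.json`
#' @return the file paths, invisibly
#' @export
write_scan_result <- function(scan, prefix) {
  curves <- file.path(paste0(prefix, "_curves.csv"))
  stats <- file.path(paste0(prefix, "_stats.json"))
  write.csv(as.data.frame(scan), curves, row.names = FALSE)
  jsonlite::write_json(list(stats = scan$stats, gaps = scan$gaps),
                       stats, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(curves = curves, stats = stats))
}

#' Emit a run manifest
#'
#' Every command-line run is paired with a manifest recording the command,
#' a hash of the configuration, the model reference, numerical parameters,
#' seed (for synthetic fixtures), package version and output file list, so
#' deterministic runs reproduce byte-for-byte.
#'
#' @param path manifest path
#' @param command command name
#' @param model_ref model reference string
#' @param outputs character vector of output files
#' @param ... extra fields (dt, dI, seed, config, ...)
#' @return `path`, invisibly
#' @export
write_manifest <- function(path, command, model_ref, outputs, ...) {
  extra <- list(...)
  payload <- c(list(command = command, model = model_ref), extra)
  payload$config_hash <- manifest_hash(payload)
  payload$package <- "pnnsim"
  payload$version <- as.character(utils::packageVersion("pnnsim"))
  payload$outputs <- basename(outputs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Stable content hash (djb2 over the serialized payload); avoids external
# digest dependencies while staying reproducible across runs.
manifest_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
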