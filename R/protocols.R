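# Measurement protocols: spike detection, sustained firing rate, f-I curves
# with depolarization-block termination, threshold (rheobase) search, and
# spike width.

#' Detect spikes in a voltage trace
#'
#' A spike is a sample strictly greater than both its neighbours and greater
#' than the detection level.  The first and last samples are never spikes;
#' flat-topped peaks (exact ties) are not spikes under the strict rule.
#'
#' @param trace a `voltage_trace` (or list with `t`, `v`)
#' @param level detection level, mV
#' @return a `spike_train`: list with `times` (ms) and `level`
#' @export
detect_spikes <- function(trace, level = -20) {
  v <- trace$v
  if (length(v) < 3) stop("trace must have at least 3 samples")
  core <- v[2:(length(v) - 1)]
  hit <- which(core > v[1:(length(v) - 2)] & core > v[3:length(v)] & core > level) + 1
  structure(list(times = trace$t[hit], level = level), class = "spike_train")
}

#' Sustained firing frequency
#'
#' Spikes count only if at least one falls in the latter half of the
#' stimulation interval; otherwise the rate is 0.  The rate is the spike
#' count inside `rate_window` divided by the window length (1000 ms full
#' stimulus for the HH models; the last 1000 ms of the 2000 ms stimulus for
#' Allen-style models).
#'
#' @param spikes a [detect_spikes()] result
#' @param stim_window `c(start, end)` of the stimulus, ms
#' @param rate_window `c(start, end)` over which the rate is measured, ms
#' @return firing rate, Hz
#' @export
sustained_frequency <- function(spikes, stim_window, rate_window = stim_window) {
  if (rate_window[1] < stim_window[1] - 1e-9 || rate_window[2] > stim_window[2] + 1e-9)
    stop("rate_window must lie inside stim_window")
  half <- (stim_window[1] + stim_window[2]) / 2
  if (!any(spikes$times > half)) return(0)
  n <- sum(spikes$times > rate_window[1] & spikes$times <= rate_window[2])
  1000 * n / (rate_window[2] - rate_window[1])
}

# One protocol evaluation: sustained frequency of a model at a current.
measure_frequency <- function(model, amp_nA, dt = 0.0078125) {
  tr <- simulate_model(model, amp_nA, dt = dt)
  sustained_frequency(detect_spikes(tr), c(0, model$stim_dur), model$rate_window)
}

#' Frequency-input (f-I) curve
#'
#' Sweeps the injected somatic current from 0 in increments of `dI`,
#' recording the sustained firing rate at each amplitude.  The sweep
#' terminates when the rate returns to 0 after having been positive
#' (depolarization block; confirmed at one further grid point to avoid
#' single-point dropouts) or at the current cap.
#'
#' @param model a [pnn_model()] or model reference for [resolve_model()]
#' @param dI current increment, nA
#' @param I_cap maximal current, nA
#' @param dt time step, ms
#' @return an `fi_curve`: data frame with columns `I_nA`, `f_Hz`, plus
#'   attributes `termination` (`"depolarization_block"` or `"current_cap"`),
#'   `dI` and `model`
#' @export
fi_curve <- function(model, dI = 0.01, I_cap = 1.0, dt = 0.0078125) {
  model <- resolve_model(model)
  I <- f <- numeric()
  fired <- FALSE
  zeros_after <- 0L
  term <- "current_cap"
  amp <- 0
  while (amp <= I_cap + 1e-12) {
    fi <- measure_frequency(model, amp, dt = dt)
    I <- c(I, amp); f <- c(f, fi)
    if (fi > 0) { fired <- TRUE; zeros_after <- 0L }
    else if (fired) {
      zeros_after <- zeros_after + 1L
      if (zeros_after >= 2L) { term <- "depolarization_block"; break }
    }
    amp <- amp + dI
  }
  structure(data.frame(I_nA = I, f_Hz = f),
            class = c("fi_curve", "data.frame"),
            termination = term, dI = dI, model = model$name)
}

#' Threshold (rheobase) current
#'
#' Smallest current on the resolution grid giving sustained firing, located
#' by a coarse 0.01 nA sweep followed by bisection on the fine grid.  The
#' result satisfies `f(threshold) > 0` and `f(threshold - resolution) = 0`.
#'
#' @param model a [pnn_model()] or model reference
#' @param resolution fine grid, nA
#' @param coarse coarse sweep increment, nA
#' @param I_cap sweep cap, nA
#' @param dt time step, ms
#' @return threshold current, nA
#' @export
find_threshold <- function(model, resolution = 0.001, coarse = 0.01,
                           I_cap = 1.0, dt = 0.0078125) {
  model <- resolve_model(model)
  hi <- NA_real_
  amp <- 0
  while (amp <= I_cap + 1e-12) {
    if (measure_frequency(model, amp, dt = dt) > 0) { hi <- amp; break }
    amp <- amp + coarse
  }
  if (is.na(hi)) stop("no sustained firing up to ", I_cap, " nA: no threshold")
  lo <- max(0, hi - coarse)  # f(lo) known to be 0 (or lo == 0)
  # bisect on the fine grid
  nlo <- round(lo / resolution); nhi <- round(hi / resolution)
  while (nhi - nlo > 1) {
    mid <- (nlo + nhi) %/% 2
    if (measure_frequency(model, mid * resolution, dt = dt) > 0) nhi <- mid
    else nlo <- mid
  }
  nhi * resolution
}

#' Spike width at a fixed level
#'
#' Time between the upward and downward crossings of `level` bracketing the
#' spike apex, each located by linear interpolation between samples.
#'
#' @param trace a `voltage_trace`
#' @param spike_time apex time of one spike (ms, from [detect_spikes()])
#' @param level measurement level, mV
#' @return width in ms
#' @export
spike_width <- function(trace, spike_time, level = -40) {
  i <- which.min(abs(trace$t - spike_time))
  if (trace$v[i] <= level)
    stop("width undefined: spike apex (", round(trace$v[i], 2),
         " mV) not above level ", level, " mV")
  v <- trace$v; t <- trace$t
  up <- i
  while (up > 1 && v[up - 1] > level) up <- up - 1
  if (up == 1) stop("width undefined: no upward crossing before apex")
  dn <- i
  while (dn < length(v) && v[dn + 1] > level) dn <- dn + 1
  if (dn == length(v)) stop("width undefined: no downward crossing after apex")
  t_up <- t[up - 1] + (level - v[up - 1]) / (v[up] - v[up - 1]) * (t[up] - t[up - 1])
  t_dn <- t[dn] + (level - v[dn]) / (v[dn + 1] - v[dn]) * (t[dn + 1] - t[dn])
  t_dn - t_up
}

#' Mean spike width of a trace
#'
#' @param trace a `voltage_trace`
#' @param level measurement level, mV
#' @param detect_level spike-detection level, mV
#' @param first_only return the first spike's width instead of the mean
#' @return width in ms, or `NA` if the trace has no spikes
#' @export
mean_spike_width <- function(trace, level = -40, detect_level = -20,
                             first_only = FALSE) {
  sp <- detect_spikes(trace, detect_level)
  apex <- as.integer(round(sp$times / trace$dt))
  ok <- sp$times[trace$v[apex] > level]
  if (!length(ok)) return(NA_real_)
  # spikes truncated by the trace edges have no bracketing crossings; skip them
  w <- vapply(ok, function(ts)
    tryCatch(spike_width(trace, ts, level), error = function(e) NA_real_),
    numeric(1))
  w <- w[!is.na(w)]
  if (!length(w)) return(NA_real_)
  if (first_only) w[1] else mean(w)
}
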