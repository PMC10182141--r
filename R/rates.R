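# Voltage-dependent rate expressions for channel gating.
#
# Channel kinetics are data, not code: mechanism definition files describe
# every alpha/beta (or inf/tau) curve as one of a small set of canonical
# parametric forms.  The engine only ever sees the evaluated curves, so new
# kinetics never require touching the solver.

.RATE_FORMS <- c("exp_linear", "exponential", "sigmoid", "constant", "bell")

#' Evaluate a canonical rate expression
#'
#' Supported forms (all voltages in mV, rates in 1/ms unless the expression
#' is used as an `inf` curve, which is dimensionless):
#' * `exp_linear`: `rate * (v - vhalf) / (1 - exp(-(v - vhalf)/scale))`
#'   (the singularity at `v == vhalf` is filled with its limit `rate*scale`)
#' * `exponential`: `rate * exp((v - vhalf)/scale)`
#' * `sigmoid`: `rate / (1 + exp(-(v - vhalf)/scale))`
#' * `constant`: `rate`
#' * `bell`: `base + rate / (exp(-(v - vhalf)/scale) + exp((v - vhalf)/scale2))`
#'
#' @param expr list with `form` and its parameters (`rate`, `vhalf`, `scale`,
#'   optionally `scale2`, `base`)
#' @param v voltage vector (mV)
#' @return numeric vector, same length as `v`
#' @export
rate_eval <- function(expr, v) {
  form <- match.arg(expr$form, .RATE_FORMS)
  a <- expr$rate
  vh <- if (is.null(expr$vhalf)) 0 else expr$vhalf
  k <- if (is.null(expr$scale)) 1 else expr$scale
  switch(form,
    exp_linear = {
      x <- v - vh
      out <- a * x / (1 - exp(-x / k))
      near <- abs(x) < 1e-7
      out[near] <- a * k
      out
    },
    exponential = a * exp((v - vh) / k),
    sigmoid = a / (1 + exp(-(v - vh) / k)),
    constant = rep(a, length(v)),
    bell = {
      k2 <- if (is.null(expr$scale2)) k else expr$scale2
      base <- if (is.null(expr$base)) 0 else expr$base
      base + a / (exp(-(v - vh) / k) + exp((v - vh) / k2))
    })
}

# Evaluate (inf, tau) curves of a gate over a voltage vector, applying the
# q10 temperature factor to tau.  A gate is specified either by alpha/beta
# rate functions or directly by inf/tau curves.
gate_curves <- function(gate, v, temperature_C, q10 = NULL, tref_C = NULL) {
  qfac <- 1
  if (!is.null(q10) && !is.null(tref_C))
    qfac <- q10^((temperature_C - tref_C) / 10)
  if (!is.null(gate$alpha)) {
    a <- rate_eval(gate$alpha, v)
    b <- rate_eval(gate$beta, v)
    inf <- a / (a + b)
    tau <- 1 / (a + b) / qfac
  } else {
    inf <- rate_eval(gate$inf, v)
    tau <- rate_eval(gate$tau, v) / qfac
  }
  if (isTRUE(gate$instantaneous))
    tau <- rep(1e-4, length(v))  # gate tracks inf(V) within one step
  if (any(!is.finite(inf)) || any(!is.finite(tau)) || any(tau <= 0))
    stop("invalid gate kinetics: tau must be positive and curves finite on [",
         min(v), ", ", max(v), "] mV")
  list(inf = inf, tau = tau)
}

# Standard voltage grid used for tabulated kinetics inside the solver.
.VGRID <- list(vmin = -120, vmax = 60, dv = 0.05)

vgrid <- function() seq(.VGRID$vmin, .VGRID$vmax, by = .VGRID$dv)
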