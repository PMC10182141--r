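# Markov-scheme channel kinetics: exact-exponential single-step update of
# the state-occupancy distribution at frozen voltage.

# Build the generator matrix Q (columns = from-state) for a Markov scheme at
# voltage v.  Q[i, j] is the rate from state j to state i (i != j); columns
# sum to zero, so d p/dt = Q p conserves total occupancy.
markov_generator <- function(markov, v, temperature_C = 6.3,
                             q10 = NULL, tref_C = NULL) {
  n <- length(markov$states)
  qfac <- if (!is.null(q10) && !is.null(tref_C))
    q10^((temperature_C - tref_C) / 10) else 1
  Q <- matrix(0, n, n)
  for (tr in markov$transitions) {
    r <- rate_eval(tr$rate, v) * qfac
    if (r < 0) stop("negative Markov transition rate at V = ", v, " mV")
    Q[tr$to, tr$from] <- Q[tr$to, tr$from] + r
    Q[tr$from, tr$from] <- Q[tr$from, tr$from] - r
  }
  Q
}

#' Advance Markov state occupancies by one exact-exponential step
#'
#' Computes `p(t + dt) = expm(Q(V) dt) p(t)` with the generator frozen at the
#' current voltage.  The matrix exponential is evaluated by scaling and
#' squaring with a Taylor core, adequate for the small (2-4 state) schemes
#' used by channel models.
#'
#' @param p occupancy vector (sums to 1)
#' @param markov scheme as in [mechanism_spec()]
#' @param v voltage, mV
#' @param dt step, ms
#' @param temperature_C,q10,tref_C temperature scaling of all rates
#' @return new occupancy vector
#' @export
markov_step <- function(p, markov, v, dt, temperature_C = 6.3,
                        q10 = NULL, tref_C = NULL) {
  Q <- markov_generator(markov, v, temperature_C, q10, tref_C)
  drop(expm_small(Q * dt) %*% p)
}

# Dense matrix exponential via scaling-and-squaring on a truncated Taylor
# series; fine for the tiny, well-scaled generators used here.
expm_small <- function(A) {
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1, norm(A, "1")))))
  A <- A / 2^s
  E <- diag(n); term <- diag(n)
  for (k in 1:16) {
    term <- term %*% A / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# Stationary occupancy of a Markov scheme at voltage v (solves Q p = 0 with
# sum(p) = 1); used to initialize channels at the resting potential.
markov_stationary <- function(markov, v, temperature_C = 6.3,
                              q10 = NULL, tref_C = NULL) {
  Q <- markov_generator(markov, v, temperature_C, q10, tref_C)
  n <- nrow(Q)
  M <- rbind(Q, rep(1, n))
  p <- qr.solve(M, c(rep(0, n), 1))
  pmax(p, 0) / sum(pmax(p, 0))
}
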