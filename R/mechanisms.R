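# Membrane mechanisms: leak, Hodgkin-Huxley-style gated channels,
# Markov-scheme channels, calcium-activated (SK-type) channels, and the
# intracellular calcium pool feeding the dynamic calcium reversal potential.

#' Construct a mechanism specification
#'
#' A mechanism is a channel population on the membrane described by its
#' maximal conductance density, its reversal potential (fixed, or dynamically
#' tied to the calcium pool), and its kinetics: a list of gates (for
#' Hodgkin-Huxley-type channels), a Markov scheme, or a calcium-activation
#' (Hill) function for SK-type channels.
#'
#' @param name mechanism name
#' @param kind one of `"leak"`, `"gated"`, `"sk"`, `"markov"`
#' @param gbar maximal conductance density, S/cm^2
#' @param erev fixed reversal potential, mV (ignored when `ion == "ca"` and
#'   the model carries a calcium pool)
#' @param ion ion carried: `"na"`, `"k"`, `"ca"`, `"leak"` or `"nonspecific"`;
#'   reversal-potential perturbations address mechanisms by ion
#' @param gates list of gates, each `list(name, exponent, alpha=, beta=)` or
#'   `list(name, exponent, inf=, tau=)` using [rate_eval()] forms
#' @param markov Markov scheme: `list(states, conducting, transitions)` where
#'   `transitions` is a list of `list(from, to, rate = <rate expr>)`
#' @param sk Hill activation of the calcium pool: `list(kd, hill)` (kd in mM)
#' @param q10,tref_C temperature scaling of gate time constants
#' @param writes_ca whether the channel's current feeds the calcium pool
#' @return a `mechanism_spec` object
#' @export
mechanism_spec <- function(name, kind = c("gated", "leak", "sk", "markov"),
                           gbar, erev = NA_real_, ion = "nonspecific",
                           gates = NULL, markov = NULL, sk = NULL,
                           q10 = NULL, tref_C = NULL, writes_ca = FALSE) {
  kind <- match.arg(kind)
  if (gbar < 0) stop("gbar must be non-negative for mechanism '", name, "'")
  if (kind == "gated" && (is.null(gates) || !length(gates)))
    stop("gated mechanism '", name, "' needs at least one gate")
  if (kind == "markov" && is.null(markov))
    stop("markov mechanism '", name, "' needs a transition scheme")
  if (kind == "sk" && is.null(sk))
    stop("sk mechanism '", name, "' needs a calcium-activation definition")
  if (kind == "leak" && (!is.null(gates) || !is.null(markov)))
    stop("leak mechanism '", name, "' cannot carry gates")
  if (ion != "ca" && is.na(erev))
    stop("mechanism '", name, "' needs a reversal potential or ion = 'ca'")
  if (!is.null(gates))
    for (g in gates)
      if (is.null(g$exponent) || g$exponent < 0 || g$exponent != round(g$exponent))
        stop("gate exponents must be non-negative integers ('", name, "')")
  structure(list(name = name, kind = kind, gbar = gbar, erev = erev,
                 ion = ion, gates = gates, markov = markov, sk = sk,
                 q10 = q10, tref_C = tref_C,
                 writes_ca = isTRUE(writes_ca) || (ion == "ca")),
            class = "mechanism_spec")
}

#' Intracellular calcium pool (Destexhe-style first-order shell model)
#'
#' The submembrane calcium concentration obeys
#' `d[Ca]/dt = -k * i_Ca - ([Ca] - ca_rest) / tau`, where the influx factor
#' `k = 1e4 * gamma / (2 F depth)` converts a calcium current density
#' (mA/cm^2) into mM/ms for a shell of the given depth, and the pool relaxes
#' back to its resting concentration with time constant `tau`.
#'
#' @param gamma fraction of the calcium current reaching the shell
#' @param depth shell depth, um
#' @param tau decay time constant, ms
#' @param ca_rest resting/minimum intracellular concentration, mM
#' @param ca_out fixed extracellular concentration, mM
#' @param ca_min numerical floor keeping the Nernst argument defined, mM
#' @return a `calcium_pool` object (field `k` holds the influx factor in
#'   mM cm^2 / (mA ms))
#' @export
calcium_pool <- function(gamma = 0.05, depth = 0.1, tau = 80,
                         ca_rest = 1e-4, ca_out = 2, ca_min = 1e-10) {
  if (tau <= 0 || depth <= 0 || ca_rest <= 0 || ca_out <= 0)
    stop("calcium pool parameters must be positive")
  structure(list(k = 1e4 * gamma / (2 * .FARADAY * depth),
                 gamma = gamma, depth = depth, tau = tau,
                 ca_rest = ca_rest, ca_out = ca_out, ca_min = ca_min),
            class = "calcium_pool")
}

#' Rate of change of the intracellular calcium concentration
#'
#' @param pool a [calcium_pool()]
#' @param i_ca calcium current density, mA/cm^2 (inward currents are negative
#'   and raise the concentration)
#' @param ca_in current intracellular concentration, mM
#' @return d\[Ca\]/dt in mM/ms
#' @export
calcium_derivative <- function(pool, i_ca, ca_in = pool$ca_rest) {
  -pool$k * i_ca - (ca_in - pool$ca_rest) / pool$tau
}

#' Time derivative of a gating variable
#'
#' `dx/dt = (inf(V) - x) / tau(V)` with `(inf, tau)` derived from alpha/beta
#' rates (`inf = a/(a+b)`, `tau = 1/(a+b)`) when the gate is specified that
#' way, and q10 temperature scaling applied to `tau`.
#'
#' @param gate a gate definition (see [mechanism_spec()])
#' @param x current gate value in \[0, 1\]
#' @param v membrane potential, mV
#' @param temperature_C simulation temperature
#' @param q10,tref_C temperature scaling (defaults: none)
#' @return dx/dt in 1/ms
#' @export
gate_derivative <- function(gate, x, v, temperature_C = 6.3,
                            q10 = NULL, tref_C = NULL) {
  if (any(x < -1e-9) || any(x > 1 + 1e-9)) stop("gate value outside [0, 1]")
  cv <- gate_curves(gate, v, temperature_C, q10, tref_C)
  (cv$inf - x) / cv$tau
}

#' Ohmic current density through a channel population
#'
#' `i = gbar * prod(x_i^e_i) * (V - E)`; for Markov channels the open-state
#' occupancy replaces the gate product, and for SK-type channels the
#' calcium-dependent Hill activation does.
#'
#' @param mech a [mechanism_spec()]
#' @param gate_values numeric vector of gate values (gated), Markov state
#'   occupancies (markov), or the intracellular calcium concentration in mM
#'   (sk); ignored for leak
#' @param v membrane potential, mV
#' @param erev reversal potential to use, mV
#' @return current density, mA/cm^2 (outward positive)
#' @export
channel_current <- function(mech, gate_values, v, erev) {
  open <- switch(mech$kind,
    leak = 1,
    gated = {
      if (any(gate_values < -1e-6) || any(gate_values > 1 + 1e-6))
        stop("corrupted state: gate value outside [0, 1]")
      x <- pmin(pmax(gate_values, 0), 1)
      prod(x^vapply(mech$gates, function(g) g$exponent, numeric(1)))
    },
    markov = {
      if (abs(sum(gate_values) - 1) > 1e-6 || any(gate_values < -1e-6))
        stop("corrupted state: Markov occupancies must be a distribution")
      sum(gate_values[mech$markov$conducting])
    },
    sk = sk_activation(mech, gate_values))
  mech$gbar * open * (v - erev)
}

# Hill activation of an SK-type channel by intracellular calcium.
sk_activation <- function(mech, ca) {
  1 / (1 + (mech$sk$kd / pmax(ca, 1e-12))^mech$sk$hill)
}

#' Load a mechanism-definition file
#'
#' Mechanism sets are JSON documents listing each mechanism's kind,
#' conductance, reversal (or ion binding) and kinetics as canonical rate
#' expressions (see [rate_eval()]).  Two sets ship with the package:
#' `"hh"`, the classic squid-axon sodium/potassium/leak trio in the modern
#' -65 mV resting convention, and `"toy_allen"`, a synthetic fast-spiking
#' interneuron set exposing the full eleven-mechanism inventory of
#' perisomatic PV-cell models (Ih, NaV, Kd, Kv2like, K_T, Kv3_1, Im_v2, SK,
#' Ca_HVA, Ca_LVA, leak) with stand-in kinetics.
#'
#' @param path path to a JSON definition file, or one of the bundled set
#'   names `"hh"`, `"toy_allen"`
#' @return named list of [mechanism_spec()] objects; a bundled
#'   [calcium_pool()] is attached as attribute `"ca_pool"` when defined
#' @export
load_mechanism_set <- function(path) {
  if (path %in% c("hh", "toy_allen"))
    path <- system.file("extdata", "mechanisms", paste0(path, ".json"),
                        package = "pnnsim", mustWork = TRUE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$mechanisms)) stop("schema error: no 'mechanisms' array in ", path)
  bad <- character()
  specs <- list()
  for (m in doc$mechanisms) {
    miss <- setdiff(c("name", "kind", "gbar"), names(m))
    if (length(miss)) { bad <- c(bad, paste0(m$name, ": missing ", paste(miss, collapse = ", "))); next }
    if (m$gbar < 0) { bad <- c(bad, paste0(m$name, ": negative gbar")); next }
    if (is.null(m$erev) && !identical(m$ion, "ca")) {
      bad <- c(bad, paste0(m$name, ": missing reversal or ion binding")); next
    }
    spec <- try(mechanism_spec(
      name = m$name, kind = m$kind, gbar = m$gbar,
      erev = if (is.null(m$erev)) NA_real_ else m$erev,
      ion = if (is.null(m$ion)) "nonspecific" else m$ion,
      gates = m$gates, markov = normalize_markov(m$markov), sk = m$sk,
      q10 = m$q10, tref_C = m$tref_C,
      writes_ca = isTRUE(m$writes_ca)), silent = TRUE)
    if (inherits(spec, "try-error")) {
      bad <- c(bad, paste0(m$name, ": ", attr(spec, "condition")$message)); next
    }
    specs[[m$name]] <- spec
  }
  if (length(bad))
    stop("schema error in ", path, ":\n  ", paste(bad, collapse = "\n  "))
  if (!is.null(doc$ca_pool))
    attr(specs, "ca_pool") <- do.call(calcium_pool, doc$ca_pool)
  if (!is.null(doc$temperature_C))
    attr(specs, "temperature_C") <- doc$temperature_C
  specs
}

normalize_markov <- function(mk) {
  if (is.null(mk)) return(NULL)
  states <- unlist(mk$states)
  list(states = states,
       conducting = match(unlist(mk$conducting), states),
       transitions = lapply(mk$transitions, function(tr)
         list(from = match(tr$from, states), to = match(tr$to, states),
              rate = tr$rate)))
}
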