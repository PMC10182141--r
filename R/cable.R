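# Branched-cable integration.  The membrane equation per compartment j,
#   cm_j dV_j/dt = -i_L,j - sum_X i_X,j + I_stim,j/A_j + axial terms,
# is advanced with a staggered scheme: gating variables, Markov occupancies
# and calcium pools take an exact-exponential step at the current voltage,
# then the voltage takes a backward-Euler step with a direct tree-structured
# (Hines) solve.  Units: mV, ms, S/cm^2, mA/cm^2, uF/cm^2, nA for injected
# currents.

#' Axial coupling conductances of a compartment tree
#'
#' For adjacent segments the coupling conductance is
#' `g = 1 / (r_child/2 + r_parent/2)` where `r = 4 Ra l / (pi d^2)` is the
#' full axial resistance of a segment.  The table is symmetric by
#' construction and has exactly one row per (child, parent) edge, i.e.
#' `nseg - 1` rows.
#'
#' @param cell a [discretize()]d cell
#' @return data frame with `seg`, `parent`, `g_S` (absolute conductance, S)
#' @export
assemble_axial_conductances <- function(cell) {
  segs <- cell$segments
  # full axial resistance per segment, Ohm (lengths/diameters in um)
  r <- 4 * cell$Ra * segs$length * 1e4 / (pi * segs$diameter^2)
  child <- which(cell$parent > 0)
  data.frame(seg = child, parent = cell$parent[child],
             g_S = 1 / (r[child] / 2 + r[cell$parent[child]] / 2))
}

# Flatten a pnn_model into the numeric structure consumed by both the
# compiled solver and the R reference stepper.  Gate/rate kinetics are
# tabulated on the standard voltage grid (q10 folded in).
compile_model <- function(model) {
  cell <- model$cell
  nseg <- nrow(cell$segments)
  ax <- assemble_axial_conductances(cell)
  gax <- numeric(nseg)
  gax[ax$seg] <- ax$g_S
  v <- vgrid()
  inf_tab <- tau_tab <- list()
  mrate_tab <- list()
  tab_key <- character(); mtab_key <- character()
  get_gate_tab <- function(mech, gi) {
    key <- paste0(mech$name, "#", gi)
    hit <- match(key, tab_key)
    if (!is.na(hit)) return(hit)
    cv <- gate_curves(mech$gates[[gi]], v, model$temperature_C, mech$q10, mech$tref_C)
    inf_tab[[length(inf_tab) + 1]] <<- cv$inf
    tau_tab[[length(tau_tab) + 1]] <<- cv$tau
    tab_key <<- c(tab_key, key)
    length(tab_key)
  }
  get_mrate_tab <- function(mech, ti) {
    key <- paste0(mech$name, "@", ti)
    hit <- match(key, mtab_key)
    if (!is.na(hit)) return(hit)
    qfac <- if (!is.null(mech$q10) && !is.null(mech$tref_C))
      mech$q10^((model$temperature_C - mech$tref_C) / 10) else 1
    r <- rate_eval(mech$markov$transitions[[ti]]$rate, v) * qfac
    if (any(r < 0)) stop("negative Markov rate in ", mech$name)
    mrate_tab[[length(mrate_tab) + 1]] <<- r
    mtab_key <<- c(mtab_key, key)
    length(mtab_key)
  }
  kinds <- c(leak = 0L, gated = 1L, sk = 2L, markov = 3L)
  ch <- list()
  for (nm in names(model$placement)) {
    mech <- model$mechs[[nm]]
    dynca <- mech$ion == "ca" && !is.null(model$pool)
    gate_tab <- gate_exp <- integer()
    if (mech$kind == "gated") {
      gate_tab <- vapply(seq_along(mech$gates), function(gi) get_gate_tab(mech, gi), integer(1))
      gate_exp <- vapply(mech$gates, function(g) as.integer(g$exponent), integer(1))
    }
    mk <- NULL
    if (mech$kind == "markov") {
      mk <- list(nstates = length(mech$markov$states),
                 conducting = as.integer(mech$markov$conducting),
                 from = vapply(mech$markov$transitions, function(tr) as.integer(tr$from), integer(1)),
                 to = vapply(mech$markov$transitions, function(tr) as.integer(tr$to), integer(1)),
                 tab = vapply(seq_along(mech$markov$transitions),
                              function(ti) get_mrate_tab(mech, ti), integer(1)))
    }
    for (s in model$placement[[nm]]) {
      ch[[length(ch) + 1]] <- list(
        seg = as.integer(s), kind = kinds[[mech$kind]], name = mech$name,
        gbar = mech$gbar, erev = if (is.na(mech$erev)) 0 else mech$erev,
        dynca = as.integer(dynca), isca = as.integer(mech$writes_ca),
        gate_tab = gate_tab, gate_exp = gate_exp,
        sk_kd = if (mech$kind == "sk") mech$sk$kd else 0,
        sk_hill = if (mech$kind == "sk") mech$sk$hill else 0,
        markov = mk)
    }
  }
  pool_has <- integer(nseg)
  pool_has[model$pool_segs] <- 1L
  np <- nernst_params(model$temperature_C, 2L)
  list(nseg = nseg, parent = as.integer(cell$parent), gax = gax,
       area_cm2 = cell$segments$area * 1e-8, cm = model$cm,
       v_init = model$v_init, soma_seg = cell$soma_seg,
       channels = ch,
       vmin = .VGRID$vmin, dv = .VGRID$dv,
       inf = do.call(cbind, c(inf_tab, list(matrix(0, length(v), 0)))),
       tau = do.call(cbind, c(tau_tab, list(matrix(1, length(v), 0)))),
       mrate = do.call(cbind, c(mrate_tab, list(matrix(0, length(v), 0)))),
       pool_has = pool_has,
       pool = if (is.null(model$pool))
         list(k = 0, tau = 1, rest = 1e-4, camin = 1e-10, ca_out = 2, ecoef = 1)
       else c(model$pool[c("k", "tau", "ca_rest", "ca_min", "ca_out")],
              list(ecoef = 1000 * np$R * np$T / (2 * np$F))) |>
         setNames(c("k", "tau", "rest", "camin", "ca_out", "ecoef")))
}

# table lookup with linear interpolation (R reference path)
tab_lookup <- function(tab, col, v, vmin, dv) {
  n <- nrow(tab)
  x <- (v - vmin) / dv
  x <- min(max(x, 0), n - 1 - 1e-9)
  i <- floor(x); w <- x - i
  (1 - w) * tab[i + 1, col] + w * tab[i + 2, col]
}

#' Initial simulation state of a model
#'
#' Voltage at `v_init` everywhere, gates at their steady-state values for
#' `v_init`, Markov schemes at their stationary distribution, calcium pools
#' at rest.
#'
#' @param model a [pnn_model()]
#' @return a `sim_state` list (`t`, `v`, `gates`, `ca`)
#' @export
cable_init_state <- function(model) {
  cm <- compile_model(model)
  gates <- lapply(cm$channels, function(c) {
    if (c$kind == 1L)
      vapply(c$gate_tab, function(tb) tab_lookup(cm$inf, tb, cm$v_init, cm$vmin, cm$dv),
             numeric(1))
    else if (c$kind == 3L) {
      mech <- model$mechs[[c$name]]
      markov_stationary(mech$markov, cm$v_init, model$temperature_C,
                        mech$q10, mech$tref_C)
    } else numeric(0)
  })
  structure(list(t = 0, v = rep(cm$v_init, cm$nseg), gates = gates,
                 ca = rep(cm$pool$rest, cm$nseg), compiled = cm),
            class = "sim_state")
}

# open fraction of a channel given its state (R reference path)
channel_open <- function(c, g, ca) {
  if (c$kind == 0L) 1
  else if (c$kind == 1L) prod(g^c$gate_exp)
  else if (c$kind == 2L) 1 / (1 + (c$sk_kd / max(ca, 1e-12))^c$sk_hill)
  else sum(g[c$markov$conducting])
}

#' Advance a simulation state by one step (reference implementation)
#'
#' Plain-R mirror of the compiled solver, used for verification: (i) gates,
#' Markov occupancies and calcium pools advance by exact-exponential updates
#' at the current voltage; (ii) the calcium reversal is recomputed from the
#' Nernst equation; (iii) the voltage advances by a backward-Euler solve of
#' the linearized membrane + axial system (direct tree elimination).  The
#' residual of the linear solve is attached as attribute `"residual"`.
#'
#' @param model a [pnn_model()]
#' @param state a `sim_state` from [cable_init_state()] or a previous step
#' @param dt time step, ms
#' @param stim_nA injected current at `stim_seg`, nA
#' @param stim_seg target segment (default soma)
#' @return the advanced `sim_state`
#' @export
cable_step <- function(model, state, dt, stim_nA = 0, stim_seg = NULL) {
  cm <- state$compiled
  if (is.null(stim_seg)) stim_seg <- cm$soma_seg
  v <- state$v; gates <- state$gates; ca <- state$ca
  eca <- cm$pool$ecoef * log(cm$pool$ca_out / pmax(ca, cm$pool$camin))
  # calcium influx at current V and gates
  ica <- numeric(cm$nseg)
  for (i in seq_along(cm$channels)) {
    c <- cm$channels[[i]]
    if (c$isca) {
      e <- if (c$dynca) eca[c$seg] else c$erev
      ica[c$seg] <- ica[c$seg] +
        c$gbar * channel_open(c, gates[[i]], ca[c$seg]) * (v[c$seg] - e)
    }
  }
  # (i) gate / Markov / calcium updates at current V
  for (i in seq_along(cm$channels)) {
    c <- cm$channels[[i]]
    if (c$kind == 1L) {
      for (k in seq_along(c$gate_tab)) {
        inf <- tab_lookup(cm$inf, c$gate_tab[k], v[c$seg], cm$vmin, cm$dv)
        tau <- tab_lookup(cm$tau, c$gate_tab[k], v[c$seg], cm$vmin, cm$dv)
        gates[[i]][k] <- inf + (gates[[i]][k] - inf) * exp(-dt / tau)
      }
    } else if (c$kind == 3L) {
      mk <- c$markov
      Q <- matrix(0, mk$nstates, mk$nstates)
      for (ti in seq_along(mk$tab)) {
        r <- tab_lookup(cm$mrate, mk$tab[ti], v[c$seg], cm$vmin, cm$dv)
        Q[mk$to[ti], mk$from[ti]] <- Q[mk$to[ti], mk$from[ti]] + r
        Q[mk$from[ti], mk$from[ti]] <- Q[mk$from[ti], mk$from[ti]] - r
      }
      gates[[i]] <- drop(expm_small(Q * dt) %*% gates[[i]])
    }
  }
  haspool <- cm$pool_has == 1L
  target <- cm$pool$rest - cm$pool$k * cm$pool$tau * ica
  ca[haspool] <- target[haspool] + (ca[haspool] - target[haspool]) * exp(-dt / cm$pool$tau)
  ca <- pmax(ca, cm$pool$camin)
  # (ii) dynamic calcium reversal from the updated pool
  eca <- cm$pool$ecoef * log(cm$pool$ca_out / pmax(ca, cm$pool$camin))
  # (iii) backward-Euler voltage solve on the tree
  cmF <- cm$cm * 1e-3  # uF/cm^2 -> mF/cm^2 so that mA/cm^2 / (mF/cm^2) = mV/ms
  d <- cmF / dt
  b <- d * v
  b[stim_seg] <- b[stim_seg] + stim_nA * 1e-6 / cm$area_cm2[stim_seg]
  for (i in seq_along(cm$channels)) {
    c <- cm$channels[[i]]
    g <- cm$channels[[i]]$gbar * channel_open(c, gates[[i]], ca[c$seg])
    e <- if (c$dynca) eca[c$seg] else c$erev
    d[c$seg] <- d[c$seg] + g
    b[c$seg] <- b[c$seg] + g * e
  }
  # axial terms in density units: off-diagonal a[j, p] = -gax_j / area_j
  off_child <- -cm$gax / cm$area_cm2          # row j, column parent(j)
  off_parent <- numeric(cm$nseg)              # row parent(j), column j
  for (j in which(cm$parent > 0)) {
    p <- cm$parent[j]
    d[j] <- d[j] + cm$gax[j] / cm$area_cm2[j]
    d[p] <- d[p] + cm$gax[j] / cm$area_cm2[p]
    off_parent[j] <- -cm$gax[j] / cm$area_cm2[p]
  }
  dd <- d; bb <- b
  for (j in seq(cm$nseg, 2, length.out = max(0, cm$nseg - 1))) {
    p <- cm$parent[j]
    f <- off_parent[j] / dd[j]
    dd[p] <- dd[p] - f * off_child[j]
    bb[p] <- bb[p] - f * bb[j]
  }
  vn <- numeric(cm$nseg)
  vn[1] <- bb[1] / dd[1]
  for (j in seq(2, length.out = cm$nseg - 1)) {
    p <- cm$parent[j]
    vn[j] <- (bb[j] - off_child[j] * vn[p]) / dd[j]
  }
  # residual of the solved linear system
  res <- d * vn - b
  for (j in which(cm$parent > 0)) {
    p <- cm$parent[j]
    res[j] <- res[j] + off_child[j] * vn[p]
    res[p] <- res[p] + off_parent[j] * vn[j]
  }
  if (any(!is.finite(vn)))
    stop("numerical blow-up at t = ", state$t + dt, " ms")
  structure(list(t = state$t + dt, v = vn, gates = gates, ca = ca,
                 compiled = cm),
            class = "sim_state", residual = max(abs(res)))
}

#' Run a stimulation protocol
#'
#' Simulates the settling window (no stimulus) followed by a constant
#' somatic current injection, and returns the somatic voltage trace covering
#' the stimulus window only.  Uses the compiled backward-Euler engine.
#'
#' @param model a [pnn_model()]
#' @param amp_nA stimulus amplitude, nA
#' @param dur stimulus duration, ms (default: the model's protocol duration)
#' @param settle settling time before recording, ms
#' @param dt time step, ms
#' @param record_ca also record the somatic calcium concentration
#' @return a `voltage_trace`: list with `t` (ms from stimulus onset), `v`
#'   (mV), `dt`, `amp_nA`, and `ca` when requested
#' @export
simulate_model <- function(model, amp_nA, dur = model$stim_dur, settle = 600,
                           dt = 0.0078125, record_ca = FALSE) {
  cmod <- compile_model(model)
  init <- cable_init_state(model)
  out <- .Call(`_pnnsim_simulate_cpp`, cmod, init$gates, dt, settle, dur,
               amp_nA, as.integer(cmod$soma_seg), as.integer(record_ca))
  if (!all(is.finite(out$v)))
    stop("numerical blow-up during simulation of ", model$name,
         " at ", amp_nA, " nA")
  structure(list(t = seq_len(length(out$v)) * dt, v = out$v, dt = dt,
                 amp_nA = amp_nA, model = model$name,
                 ca = if (record_ca) out$ca else NULL),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat("<voltage_trace> ", x$model, " at ", x$amp_nA, " nA: ",
      length(x$v), " samples, dt = ", x$dt, " ms, V in [",
      round(min(x$v), 1), ", ", round(max(x$v), 1), "] mV\n", sep = "")
  invisible(x)
}
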