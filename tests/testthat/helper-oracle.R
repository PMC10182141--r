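# Independent oracles.
#
# ode_oracle() integrates the membrane equations of a single-compartment
# gated/leak model with an adaptive embedded Runge-Kutta (Cash-Karp 4(5))
# at tight tolerance.  It evaluates the mechanism rate expressions directly
# (no voltage tables, no backward Euler, no staggering), so it shares no
# numerical path with the solver it checks.

# rhs builder: state y = (V, gates...) for a single-compartment model
single_compartment_rhs <- function(model, amp_nA) {
  cmod <- pnnsim:::compile_model(model)
  stopifnot(cmod$nseg == 1)
  mechs <- model$mechs[names(model$placement)]
  gate_of <- list(); off <- 0L
  for (nm in names(mechs)) {
    n <- length(mechs[[nm]]$gates)
    gate_of[[nm]] <- if (n) off + seq_len(n) else integer()
    off <- off + n
  }
  area <- cmod$area_cm2[1]
  cm_mF <- cmod$cm[1] * 1e-3
  stim <- amp_nA * 1e-6 / area
  function(t, y) {
    v <- y[1]
    i_tot <- 0
    dy <- numeric(length(y))
    for (nm in names(mechs)) {
      mech <- mechs[[nm]]
      open <- 1
      for (k in seq_along(mech$gates)) {
        g <- mech$gates[[k]]
        cv <- pnnsim:::gate_curves(g, v, model$temperature_C, mech$q10, mech$tref_C)
        idx <- 1 + gate_of[[nm]][k]
        x <- if (isTRUE(g$instantaneous)) cv$inf else y[idx]
        dy[idx] <- if (isTRUE(g$instantaneous)) 0 else (cv$inf - x) / cv$tau
        open <- open * x^g$exponent
      }
      i_tot <- i_tot + mech$gbar * open * (v - mech$erev)
    }
    dy[1] <- (-i_tot + stim) / cm_mF
    dy
  }
}

oracle_init <- function(model) {
  v0 <- model$v_init
  y <- v0
  for (nm in names(model$placement)) {
    mech <- model$mechs[[nm]]
    for (g in mech$gates) {
      cv <- pnnsim:::gate_curves(g, v0, model$temperature_C, mech$q10, mech$tref_C)
      y <- c(y, cv$inf)
    }
  }
  y
}

# Cash-Karp embedded RK45 with dense output onto t_eval
rk45 <- function(rhs, y0, t0, t1, t_eval, rtol = 1e-8, atol = 1e-9) {
  a <- list(c(), 1/5, c(3/40, 9/40), c(3/10, -9/10, 6/5),
            c(-11/54, 5/2, -70/27, 35/27),
            c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
  b5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  b4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  cs <- c(0, 1/5, 3/10, 3/5, 1, 7/8)
  t <- t0; y <- y0; h <- 1e-3
  out <- matrix(NA_real_, length(t_eval), length(y0))
  nexti <- 1L
  k <- vector("list", 6)
  while (t < t1 - 1e-12) {
    h <- min(h, t1 - t)
    repeat {
      k[[1]] <- rhs(t, y)
      for (s in 2:6) {
        ys <- y + h * colSums(matrix(unlist(k[1:(s-1)]), nrow = s - 1, byrow = TRUE) * a[[s]])
        k[[s]] <- rhs(t + cs[s] * h, ys)
      }
      K <- matrix(unlist(k), nrow = 6, byrow = TRUE)
      y5 <- y + h * colSums(K * b5)
      y4 <- y + h * colSums(K * b4)
      err <- max(abs(y5 - y4) / (atol + rtol * pmax(abs(y), abs(y5))))
      if (!is.finite(err)) { h <- h / 10; next }
      if (err <= 1) break
      h <- max(h * max(0.2, 0.9 * err^(-0.25)), 1e-9)
    }
    tn <- t + h
    # cubic Hermite dense output onto the requested grid
    if (nexti <= length(t_eval) && t_eval[nexti] <= tn + 1e-12) {
      f0 <- k[[1]]; f1 <- rhs(tn, y5)
      while (nexti <= length(t_eval) && t_eval[nexti] <= tn + 1e-12) {
        w <- (t_eval[nexti] - t) / h
        h00 <- (1 + 2 * w) * (1 - w)^2; h10 <- w * (1 - w)^2
        h01 <- w^2 * (3 - 2 * w); h11 <- w^2 * (w - 1)
        out[nexti, ] <- h00 * y + h10 * h * f0 + h01 * y5 + h11 * h * f1
        nexti <- nexti + 1L
      }
    }
    t <- tn; y <- y5
    h <- min(h * min(5, 0.9 * max(err, 1e-10)^(-0.2)), 0.05)
  }
  out
}

# Somatic oracle trace: settle (no stimulus) then stimulus, sampled on the
# solver grid of the stimulus window.
ode_oracle <- function(model, amp_nA, dur, settle = 100, dt = 0.0078125,
                       rtol = 1e-8) {
  key <- paste0("oracle_", model$name, "_", amp_nA, "_", dur, "_", settle, "_", rtol)
  memo(key, {
    y0 <- oracle_init(model)
    rest <- rk45(single_compartment_rhs(model, 0), y0, 0, settle, settle,
                 rtol = rtol)
    y1 <- rest[1, ]
    tev <- seq_len(round(dur / dt)) * dt
    out <- rk45(single_compartment_rhs(model, amp_nA), y1, 0, dur, tev,
                rtol = rtol)
    structure(list(t = tev, v = out[, 1], dt = dt, amp_nA = amp_nA,
                   model = paste0(model$name, "-oracle")),
              class = "voltage_trace")
  })
}
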