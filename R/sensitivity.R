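sens_parameters <- c("km", "dm", "kp", "dp", "r", "S", "theta", "tau1", "tau2")

#' Forward sensitivity trajectory of the model
#'
#' Integrates the sensitivity system `(R_M, R_P) = (dM/dp, dP/dp)` along a
#' state trajectory. Differentiating the delay model in the parameter `p`
#' gives a linear, non-autonomous delay system
#' \deqn{R_M' = -dm R_M - beta R_M(t - tau1) + g_M(t), \quad
#'       R_P' = kp R_M(t - tau2) - dp R_P + g_P(t)}
#' whose forcing depends on the parameter: `g_M = 1` for `km`, `-M(t)` for
#' `dm`, `-(beta/r) M(t - tau1)` for `r`, the Hill-derivative analogues for
#' `S` and `theta` (and, behind `allow_n`, a continuous relaxation in `n`
#' via the logarithmic derivative of the Hill form), and for `tau1` the term
#' `beta * (km - dm*M(t - tau1) - beta*M(t - 2*tau1))` — note the lookback of
#' two delays. For `kp` the protein forcing is `M(t - tau2)`, for `dp` it is
#' `-P(t)`, and for `tau2` it is `-kp * M'(t - tau2)`. The pre-history of the
#' sensitivities is identically zero since the initial history does not
#' depend on the model parameters.
#'
#' @param params an [rnai_params()] object.
#' @param init an [initial_condition()] object.
#' @param wrt parameter name, one of `km, dm, kp, dp, r, S, theta, tau1,
#'   tau2` (plus `n` when `allow_n = TRUE`).
#' @param horizon,dt integration range and step (defaults as in
#'   [simulate_model()]).
#' @param delayed logical; `FALSE` uses the zero-delay reduction (delay
#'   sensitivities are then unavailable).
#' @param state optional precomputed companion `rnai_trajectory` on the same
#'   grid; simulated if omitted.
#' @param allow_n permit the continuous-`n` relaxation.
#' @return An object of class `rnai_sensitivity` with `times`, `R_M`, `R_P`
#'   on the state grid, plus the companion `state` trajectory.
#' @export
solve_sensitivity <- function(params, init = initial_condition(), wrt,
                              horizon, dt = NULL, delayed = TRUE,
                              state = NULL, allow_n = FALSE) {
  validate_params(params)
  valid <- c(sens_parameters, if (allow_n) "n")
  if (!is.character(wrt) || length(wrt) != 1L || !(wrt %in% valid))
    stop("unknown sensitivity parameter '", wrt, "'", call. = FALSE)
  if (!delayed && wrt %in% c("tau1", "tau2"))
    stop("delay sensitivities are undefined for the zero-delay model",
         call. = FALSE)
  if (is.null(state))
    state <- simulate_model(params, init, horizon = horizon, dt = dt,
                            delayed = delayed)
  dt <- state$dt
  nstep <- length(state$times) - 1L

  km <- params$km; dm <- params$dm; kp <- params$kp; dp <- params$dp
  tau1 <- if (delayed) params$tau1 else 0
  tau2 <- if (delayed) params$tau2 else 0
  b <- effective_beta(params)
  M0 <- init$M0; P0 <- init$P0

  mlook <- function(s) {
    if (s <= 0) return(M0)
    interp_series(state$times, state$M, state$dM, dt, s, M0)
  }
  plook <- function(s) {
    if (s <= 0) return(P0)
    interp_series(state$times, state$P, state$dP, dt, s, P0)
  }
  mprime <- function(s) {
    if (s <= 0) return(0)  # constant pre-history
    km - dm * mlook(s) - b * mlook(s - tau1)
  }

  dbdS <- hill_beta_dS(params$r, params$theta, params$n, params$S)
  dbdtheta <- if (params$S > 0)
    -params$n * b * (1 - b / params$r) / params$theta else 0
  dbdn <- if (params$S > 0)
    b * (1 - b / params$r) * (log(params$S) - log(params$theta)) else 0

  gM <- switch(wrt,
    km = function(t) 1,
    dm = function(t) -mlook(t),
    r = function(t) -(b / params$r) * mlook(t - tau1),
    S = function(t) -dbdS * mlook(t - tau1),
    theta = function(t) -dbdtheta * mlook(t - tau1),
    n = function(t) -dbdn * mlook(t - tau1),
    # b * (km - dm*M(t - tau1) - b*M(t - 2*tau1)) while the argument is past
    # the start; the constant pre-history has zero slope, so the forcing
    # vanishes for t < tau1
    tau1 = function(t) b * mprime(t - tau1),
    function(t) 0)
  gP <- switch(wrt,
    kp = function(t) mlook(t - tau2),
    dp = function(t) -plook(t),
    tau2 = function(t) -kp * mprime(t - tau2),
    function(t) 0)

  n1 <- nstep + 1L
  RM <- numeric(n1); RP <- numeric(n1); dRM <- numeric(n1); dRP <- numeric(n1)
  half <- dt / 2

  if (delayed && (tau1 > 0 || tau2 > 0)) {
    rl <- function(s, last) {
      if (s <= 0) return(0)
      i <- as.integer(s / dt) + 1L
      if (i >= last) i <- last - 1L
      if (i < 1L) return(s * dRM[1L])
      u <- s / dt - (i - 1L)
      u2 <- u * u; um <- u - 1; um2 <- um * um
      (1 + 2 * u) * um2 * RM[i] + u * um2 * dt * dRM[i] +
        u2 * (3 - 2 * u) * RM[i + 1L] + u2 * um * dt * dRM[i + 1L]
    }
    dRM[1L] <- -dm * 0 - b * rl(-tau1, 1L) + gM(0)
    dRP[1L] <- kp * rl(-tau2, 1L) - dp * 0 + gP(0)
    for (k in seq_len(nstep)) {
      t <- (k - 1L) * dt
      l2 <- rl(t + half - tau1, k); q2 <- rl(t + half - tau2, k)
      l3 <- rl(t + dt - tau1, k);   q3 <- rl(t + dt - tau2, k)
      gM2 <- gM(t + half); gM3 <- gM(t + dt)
      gP2 <- gP(t + half); gP3 <- gP(t + dt)
      m <- RM[k]; p <- RP[k]
      k1M <- dRM[k]; k1P <- dRP[k]
      k2M <- -dm * (m + half * k1M) - b * l2 + gM2
      k2P <- kp * q2 - dp * (p + half * k1P) + gP2
      k3M <- -dm * (m + half * k2M) - b * l2 + gM2
      k3P <- kp * q2 - dp * (p + half * k2P) + gP2
      k4M <- -dm * (m + dt * k3M) - b * l3 + gM3
      k4P <- kp * q3 - dp * (p + dt * k3P) + gP3
      RM[k + 1L] <- m + dt * (k1M + 2 * k2M + 2 * k3M + k4M) / 6
      RP[k + 1L] <- p + dt * (k1P + 2 * k2P + 2 * k3P + k4P) / 6
      dRM[k + 1L] <- -dm * RM[k + 1L] - b * l3 + gM3
      dRP[k + 1L] <- kp * q3 - dp * RP[k + 1L] + gP3
    }
  } else {
    # zero-delay reduction: R_M enters its own stage state
    for (k in seq_len(nstep)) {
      t <- (k - 1L) * dt
      gM1 <- gM(t); gM2 <- gM(t + half); gM3 <- gM(t + dt)
      gP1 <- gP(t); gP2 <- gP(t + half); gP3 <- gP(t + dt)
      m <- RM[k]; p <- RP[k]
      k1M <- -(dm + b) * m + gM1
      k1P <- kp * m - dp * p + gP1
      k2M <- -(dm + b) * (m + half * k1M) + gM2
      k2P <- kp * (m + half * k1M) - dp * (p + half * k1P) + gP2
      k3M <- -(dm + b) * (m + half * k2M) + gM2
      k3P <- kp * (m + half * k2M) - dp * (p + half * k2P) + gP2
      k4M <- -(dm + b) * (m + dt * k3M) + gM3
      k4P <- kp * (m + dt * k3M) - dp * (p + dt * k3P) + gP3
      dRM[k] <- k1M; dRP[k] <- k1P
      RM[k + 1L] <- m + dt * (k1M + 2 * k2M + 2 * k3M + k4M) / 6
      RP[k + 1L] <- p + dt * (k1P + 2 * k2P + 2 * k3P + k4P) / 6
    }
    dRM[n1] <- -(dm + b) * RM[n1] + gM(nstep * dt)
    dRP[n1] <- kp * RM[n1] - dp * RP[n1] + gP(nstep * dt)
  }

  structure(list(parameter = wrt, times = state$times, R_M = RM, R_P = RP,
                 dR_M = dRM, dR_P = dRP, dt = dt, state = state),
            class = "rnai_sensitivity")
}

#' @export
print.rnai_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity trajectory d(M,P)/d%s on [0, %g] (%d nodes); final R_M = %.5g, R_P = %.5g\n",
              x$parameter, x$times[length(x$times)], length(x$times),
              x$R_M[length(x$R_M)], x$R_P[length(x$R_P)]))
  invisible(x)
}

#' Relative sensitivities of the limit cycle's amplitude and period
#'
#' For each parameter `p`, the dimensionless quantities
#' `(p/X) * dX/dp` for `X` the protein-oscillation amplitude and the period.
#' The primary estimator is a central finite difference of the features
#' measured by [measure_limit_cycle()] at `p*(1 +/- h_rel)`, with a
#' half-step replicate (`h_rel/2`) retained as a Richardson-style
#' self-consistency diagnostic. Optionally, an estimate extracted from the
#' forward sensitivity trajectory is reported alongside: on a near-sinusoidal
#' attractor `P = A cos(omega t + phi)`, the sensitivity obeys
#' `R_P = (A_p/A)(P - offset) + ((omega_p/omega) t + c) P'`, so regressing
#' `R_P` on `P - mean`, `P'` and `t * P'` over the attractor window recovers
#' `A_p/A` and `omega_p/omega` directly.
#'
#' Feature differences use the raw measured features, which remain defined
#' when a perturbation steps just across the bifurcation boundary into the
#' weakly damped regime.
#'
#' @param params an [rnai_params()] object in an oscillatory regime.
#' @param parameters character vector of parameters to perturb (default all
#'   nine model constants except `n`).
#' @param init an [initial_condition()] object.
#' @param horizon,dt simulation range and step used for every run.
#' @param h_rel relative finite-difference step (default 1e-3).
#' @param transient_fraction passed to [measure_limit_cycle()].
#' @param method `"fd"` (finite differences only) or `"both"` (adds the
#'   sensitivity-trajectory regression estimates).
#' @return A data frame of class `rnai_rel_sens` with one row per parameter:
#'   `rel_amplitude`, `rel_period`, half-step replicates, the consistency
#'   flag, and (for `method = "both"`) `rel_amplitude_traj`,
#'   `rel_period_traj`. Parameters whose nominal value is zero have zero
#'   relative sensitivity by definition. If the nominal trajectory shows no
#'   measurable oscillation, a zero-row data frame with attribute
#'   `reason = "no limit cycle"` is returned.
#' @export
limit_cycle_relative_sensitivities <- function(params,
                                               parameters = sens_parameters,
                                               init = initial_condition(),
                                               horizon = 900, dt = NULL,
                                               h_rel = 1e-3,
                                               transient_fraction = 0.5,
                                               method = c("fd", "both")) {
  method <- match.arg(method)
  validate_params(params)
  parameters <- match.arg(parameters, sens_parameters, several.ok = TRUE)

  base_traj <- simulate_model(params, init, horizon = horizon, dt = dt,
                              delayed = TRUE)
  base <- measure_limit_cycle(base_traj, transient_fraction)
  reg <- classify_regime(params)
  if (!base$oscillating && reg$regime != "hopf" &&
      !is.finite(base$raw_period)) {
    out <- data.frame(parameter = character(0), rel_amplitude = numeric(0),
                      rel_period = numeric(0))
    attr(out, "reason") <- "no limit cycle"
    return(out)
  }

  features <- function(p2) {
    tr <- simulate_model(p2, init, horizon = horizon, dt = base_traj$dt,
                         delayed = TRUE)
    f <- measure_limit_cycle(tr, transient_fraction)
    c(amp = f$raw_amplitude_P, per = f$raw_period)
  }
  A0 <- base$raw_amplitude_P; T0 <- base$raw_period

  fd_pair <- function(pname, h) {
    p0 <- params[[pname]]
    if (p0 == 0) return(c(amp = 0, per = 0))
    up <- params; up[[pname]] <- p0 * (1 + h)
    dn <- params; dn[[pname]] <- p0 * (1 - h)
    fu <- features(up); fd <- features(dn)
    c(amp = (fu[["amp"]] - fd[["amp"]]) / (2 * h * A0),
      per = (fu[["per"]] - fd[["per"]]) / (2 * h * T0))
  }

  rows <- lapply(parameters, function(pn) {
    full <- fd_pair(pn, h_rel)
    halfs <- fd_pair(pn, h_rel / 2)
    # near-zero entries are compared on an absolute floor
    floor_ <- 0.01
    consist <- function(a, b) {
      if (max(abs(a), abs(b)) < floor_) abs(a - b) < floor_
      else abs(a - b) <= 0.05 * max(abs(a), abs(b))
    }
    data.frame(parameter = pn,
               rel_amplitude = full[["amp"]], rel_period = full[["per"]],
               rel_amplitude_h2 = halfs[["amp"]], rel_period_h2 = halfs[["per"]],
               consistent = consist(full[["per"]], halfs[["per"]]) &&
                 consist(full[["amp"]], halfs[["amp"]]),
               method = "finite-difference", h_rel = h_rel)
  })
  out <- do.call(rbind, rows)

  if (method == "both") {
    win <- trajectory_window(base_traj, transient_fraction)
    out$rel_amplitude_traj <- NA_real_
    out$rel_period_traj <- NA_real_
    for (i in seq_len(nrow(out))) {
      pn <- out$parameter[i]
      if (params[[pn]] == 0) { out$rel_amplitude_traj[i] <- 0; out$rel_period_traj[i] <- 0; next }
      sens <- solve_sensitivity(params, init, wrt = pn, state = base_traj)
      est <- attractor_regression(base_traj, sens, win)
      out$rel_amplitude_traj[i] <- params[[pn]] * est[["amp_ratio"]]
      out$rel_period_traj[i] <- -params[[pn]] * est[["omega_ratio"]]
    }
  }
  class(out) <- c("rnai_rel_sens", class(out))
  attr(out, "amplitude") <- A0
  attr(out, "period") <- T0
  out
}

trajectory_window <- function(traj, transient_fraction) {
  n <- length(traj$times)
  max(2L, as.integer(floor(n * transient_fraction))):n
}

# Least-squares decomposition of R_P over the attractor window into the
# in-phase (amplitude) and secularly growing quadrature (frequency) parts.
attractor_regression <- function(traj, sens, win) {
  t <- traj$times[win]
  Pc <- traj$P[win] - mean(traj$P[win])
  Pd <- traj$dP[win]
  tc <- t - mean(t)          # center to decorrelate the secular column
  X <- cbind(1, Pc, Pd, tc * Pd)
  beta <- qr.coef(qr(X), sens$R_P[win])
  c(amp_ratio = unname(beta[2]), omega_ratio = unname(beta[4]))
}
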