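#' Simulate the RNAi model (delayed or undelayed)
#'
#' Integrates the two-stage mRNA/protein system with classical fixed-step
#' 4th-order Runge-Kutta. In the delayed case the method of steps is used:
#' the delayed mRNA arguments `M(t - tau1)` and `M(t - tau2)` are read from
#' the already-computed solution by piecewise-cubic Hermite interpolation
#' (value and derivative stored at every grid node), with the constant
#' pre-history `M0` for arguments at or before the start time. A delayed
#' argument that falls inside the step currently being taken (possible only
#' when a delay is shorter than the step, i.e. in the vanishing-delay limit)
#' is evaluated by cubic extrapolation of the newest completed interval.
#'
#' The step is not required to divide the delays: interpolation handles
#' off-grid lookups, so delay sweeps need no grid re-tuning. A warning is
#' issued when a positive delay is resolved by fewer than 10 steps.
#'
#' @param params an [rnai_params()] object.
#' @param init an [initial_condition()] object.
#' @param horizon end time of the integration (> 0); the grid covers
#'   `[0, horizon]`.
#' @param dt step size; defaults to `min(tau1, tau2, 1)/50` over the positive
#'   delays for a delayed run and `0.01` for an undelayed run.
#' @param delayed logical; `FALSE` integrates the zero-delay (ODE) reduction.
#' @return An object of class `rnai_trajectory`: uniform `times` grid,
#'   `M`/`P` series, nodal derivatives `dM`/`dP`, and the inputs. Query it at
#'   arbitrary times with [trajectory_state()].
#' @examples
#' p <- rnai_params(r = 0.5062, S = 30, tau1 = 2.5, tau2 = 1)
#' tr <- simulate_model(p, initial_condition(160, 10000), horizon = 200)
#' tail(as.data.frame(tr))
#' @export
simulate_model <- function(params, init = initial_condition(),
                           horizon, dt = NULL, delayed = TRUE) {
  validate_params(params)
  if (!inherits(init, "rnai_init")) stop("'init' must be an initial_condition()")
  if (!is.numeric(horizon) || horizon <= 0) stop("'horizon' must be > 0")
  if (is.null(dt)) {
    dt <- if (delayed) {
      pos <- c(params$tau1, params$tau2, 1)
      min(pos[pos > 0]) / 50
    } else 0.01
  }
  if (dt <= 0) stop("'dt' must be > 0")
  nstep <- as.integer(ceiling(horizon / dt - 1e-9))
  if (delayed) {
    for (tau in c(params$tau1, params$tau2))
      if (tau > dt && tau < 10 * dt)
        warning("delay ", tau, " is resolved by fewer than 10 steps of ", dt)
  }

  km <- params$km; dm <- params$dm; kp <- params$kp; dp <- params$dp
  b <- effective_beta(params)
  M0 <- init$M0; P0 <- init$P0
  n1 <- nstep + 1L
  M <- numeric(n1); P <- numeric(n1); dM <- numeric(n1); dP <- numeric(n1)
  M[1L] <- M0; P[1L] <- P0
  half <- dt / 2

  if (!delayed || (params$tau1 == 0 && params$tau2 == 0)) {
    # plain RK4 on the ODE reduction
    a <- dm + b
    for (k in seq_len(nstep)) {
      m <- M[k]; p <- P[k]
      k1M <- km - a * m;             k1P <- kp * m - dp * p
      k2M <- km - a * (m + half * k1M); k2P <- kp * (m + half * k1M) - dp * (p + half * k1P)
      k3M <- km - a * (m + half * k2M); k3P <- kp * (m + half * k2M) - dp * (p + half * k2P)
      k4M <- km - a * (m + dt * k3M);   k4P <- kp * (m + dt * k3M) - dp * (p + dt * k3P)
      dM[k] <- k1M; dP[k] <- k1P
      M[k + 1L] <- m + dt * (k1M + 2 * k2M + 2 * k3M + k4M) / 6
      P[k + 1L] <- p + dt * (k1P + 2 * k2P + 2 * k3P + k4P) / 6
    }
    dM[n1] <- km - a * M[n1]; dP[n1] <- kp * M[n1] - dp * P[n1]
  } else {
    tau1 <- params$tau1; tau2 <- params$tau2
    # Hermite lookup into the in-progress M history; `last` is the index of
    # the most recently completed node.
    hm <- function(s, last) {
      if (s <= 0) return(M0)
      i <- as.integer(s / dt) + 1L
      if (i >= last) i <- last - 1L
      if (i < 1L) return(M0 + s * dM[1L])  # first step, sub-step delay
      u <- s / dt - (i - 1L)
      u2 <- u * u; um <- u - 1; um2 <- um * um
      (1 + 2 * u) * um2 * M[i] + u * um2 * dt * dM[i] +
        u2 * (3 - 2 * u) * M[i + 1L] + u2 * um * dt * dM[i + 1L]
    }
    dM[1L] <- km - dm * M0 - b * hm(-tau1, 1L)
    dP[1L] <- kp * hm(-tau2, 1L) - dp * P0
    bad <- 0L
    for (k in seq_len(nstep)) {
      t <- (k - 1L) * dt
      a2 <- hm(t + half - tau1, k); b2 <- hm(t + half - tau2, k)
      a3 <- hm(t + dt - tau1, k);   b3 <- hm(t + dt - tau2, k)
      m <- M[k]; p <- P[k]
      k1M <- dM[k]; k1P <- dP[k]
      k2M <- km - dm * (m + half * k1M) - b * a2; k2P <- kp * b2 - dp * (p + half * k1P)
      k3M <- km - dm * (m + half * k2M) - b * a2; k3P <- kp * b2 - dp * (p + half * k2P)
      k4M <- km - dm * (m + dt * k3M) - b * a3;   k4P <- kp * b3 - dp * (p + dt * k3P)
      mn <- m + dt * (k1M + 2 * k2M + 2 * k3M + k4M) / 6
      pn <- p + dt * (k1P + 2 * k2P + 2 * k3P + k4P) / 6
      if (!is.finite(mn) || !is.finite(pn)) { bad <- k; break }
      M[k + 1L] <- mn; P[k + 1L] <- pn
      dM[k + 1L] <- km - dm * mn - b * a3
      dP[k + 1L] <- kp * b3 - dp * pn
    }
    if (bad > 0L)
      stop("non-finite state at t = ", format(bad * dt),
           "; the trajectory has overflowed", call. = FALSE)
  }

  structure(list(times = (0:nstep) * dt, M = M, P = P, dM = dM, dP = dP,
                 t0 = 0, t_end = nstep * dt, dt = dt,
                 params = params, init = init, delayed = delayed),
            class = "rnai_trajectory")
}

#' Continue a trajectory over a longer horizon
#'
#' Restarts the integrator from the end of `traj`, reusing the stored solution
#' as delay history, and returns the concatenated trajectory. With matching
#' steps this reproduces a single longer run to integrator tolerance.
#'
#' @param traj an `rnai_trajectory`.
#' @param horizon additional integration time (> 0).
#' @return An `rnai_trajectory` covering `[0, t_end + horizon]`.
#' @export
extend_trajectory <- function(traj, horizon) {
  stopifnot(inherits(traj, "rnai_trajectory"), horizon > 0)
  p <- traj$params
  dt <- traj$dt
  extra <- as.integer(ceiling(horizon / dt - 1e-9))
  n0 <- length(traj$times)
  n1 <- n0 + extra
  M <- c(traj$M, numeric(extra)); P <- c(traj$P, numeric(extra))
  dM <- c(traj$dM, numeric(extra)); dP <- c(traj$dP, numeric(extra))
  km <- p$km; dm <- p$dm; kp <- p$kp; dp <- p$dp
  b <- effective_beta(p)
  M0 <- traj$init$M0
  half <- dt / 2
  delayed <- traj$delayed && (p$tau1 > 0 || p$tau2 > 0)
  hm <- function(s, last) {
    if (s <= 0) return(M0)
    i <- as.integer(s / dt) + 1L
    if (i >= last) i <- last - 1L
    if (i < 1L) return(M0 + s * dM[1L])
    u <- s / dt - (i - 1L)
    u2 <- u * u; um <- u - 1; um2 <- um * um
    (1 + 2 * u) * um2 * M[i] + u * um2 * dt * dM[i] +
      u2 * (3 - 2 * u) * M[i + 1L] + u2 * um * dt * dM[i + 1L]
  }
  for (k in n0:(n1 - 1L)) {
    t <- (k - 1L) * dt
    if (delayed) {
      a2 <- hm(t + half - p$tau1, k); b2 <- hm(t + half - p$tau2, k)
      a3 <- hm(t + dt - p$tau1, k);   b3 <- hm(t + dt - p$tau2, k)
    }
    m <- M[k]; pp <- P[k]
    k1M <- dM[k]; k1P <- dP[k]
    if (delayed) {
      k2M <- km - dm * (m + half * k1M) - b * a2; k2P <- kp * b2 - dp * (pp + half * k1P)
      k3M <- km - dm * (m + half * k2M) - b * a2; k3P <- kp * b2 - dp * (pp + half * k2P)
      k4M <- km - dm * (m + dt * k3M) - b * a3;   k4P <- kp * b3 - dp * (pp + dt * k3P)
    } else {
      a <- dm + b
      k2M <- km - a * (m + half * k1M); k2P <- kp * (m + half * k1M) - dp * (pp + half * k1P)
      k3M <- km - a * (m + half * k2M); k3P <- kp * (m + half * k2M) - dp * (pp + half * k2P)
      k4M <- km - a * (m + dt * k3M);   k4P <- kp * (m + dt * k3M) - dp * (pp + dt * k3P)
    }
    M[k + 1L] <- m + dt * (k1M + 2 * k2M + 2 * k3M + k4M) / 6
    P[k + 1L] <- pp + dt * (k1P + 2 * k2P + 2 * k3P + k4P) / 6
    if (delayed) {
      dM[k + 1L] <- km - dm * M[k + 1L] - b * a3
      dP[k + 1L] <- kp * b3 - dp * P[k + 1L]
    } else {
      a <- dm + b
      dM[k + 1L] <- km - a * M[k + 1L]
      dP[k + 1L] <- kp * M[k + 1L] - dp * P[k + 1L]
    }
  }
  out <- traj
  out$times <- (0:(n1 - 1L)) * dt
  out$M <- M; out$P <- P; out$dM <- dM; out$dP <- dP
  out$t_end <- (n1 - 1L) * dt
  out
}

#' Query a trajectory at arbitrary times
#'
#' Piecewise-cubic Hermite interpolation on the stored grid. Times at or
#' before the start return the constant pre-history; times outside
#' `[-max(tau1, tau2), t_end]` are an error.
#'
#' @param traj an `rnai_trajectory`.
#' @param t numeric vector of query times.
#' @return A data frame with columns `t`, `M`, `P`.
#' @export
trajectory_state <- function(traj, t) {
  stopifnot(inherits(traj, "rnai_trajectory"))
  lo <- traj$t0 - max(traj$params$tau1, traj$params$tau2)
  if (any(t < lo - 1e-12) || any(t > traj$t_end + 1e-9))
    stop("query time outside [", lo, ", ", traj$t_end, "]", call. = FALSE)
  M <- interp_series(traj$times, traj$M, traj$dM, traj$dt, t, traj$init$M0)
  P <- interp_series(traj$times, traj$P, traj$dP, traj$dt, t, traj$init$P0)
  data.frame(t = t, M = M, P = P)
}

# Hermite interpolation of a completed series; constant `pre` before time 0.
interp_series <- function(times, y, dy, dt, t, pre) {
  n <- length(times)
  out <- numeric(length(t))
  for (j in seq_along(t)) {
    s <- t[j]
    if (s <= 0) { out[j] <- pre; next }
    i <- as.integer(s / dt) + 1L
    if (i >= n) i <- n - 1L
    u <- s / dt - (i - 1L)
    u2 <- u * u; um <- u - 1; um2 <- um * um
    out[j] <- (1 + 2 * u) * um2 * y[i] + u * um2 * dt * dy[i] +
      u2 * (3 - 2 * u) * y[i + 1L] + u2 * um * dt * dy[i + 1L]
  }
  out
}

#' @export
as.data.frame.rnai_trajectory <- function(x, ...) {
  data.frame(t = x$times, M = x$M, P = x$P)
}

#' @export
print.rnai_trajectory <- function(x, ...) {
  cat(sprintf("RNAi %s trajectory on [0, %g], dt = %g (%d nodes)\n",
              if (x$delayed) "delay-model" else "ODE-model",
              x$t_end, x$dt, length(x$times)))
  cat(sprintf("  final state: M = %.6g, P = %.6g\n",
              x$M[length(x$M)], x$P[length(x$P)]))
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Writes `t,M,P` rows at full double precision, one per grid node.
#'
#' @param traj an `rnai_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "rnai_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t,M,P", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", traj$times, traj$M, traj$P), con)
  invisible(path)
}
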