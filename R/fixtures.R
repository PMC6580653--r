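#' Synthetic sinusoidal trajectory
#'
#' Builds a trajectory-shaped object `offset + amplitude * sin(2*pi*t /
#' period)` on a uniform grid (same series in both channels), for exercising
#' [measure_limit_cycle()] against constructed ground truth.
#'
#' @param offset,amplitude,period sinusoid parameters; `period > 0`.
#' @param t_end,dt grid range and spacing.
#' @return An `rnai_trajectory`.
#' @export
fixture_sinusoid <- function(offset = 5, amplitude = 2, period = 7,
                             t_end = 100, dt = 0.01) {
  stopifnot(period > 0, dt > 0, t_end > 0)
  times <- seq(0, t_end, by = dt)
  w <- 2 * pi / period
  x <- offset + amplitude * sin(w * times)
  dx <- amplitude * w * cos(w * times)
  structure(list(times = times, M = x, P = x, dM = dx, dP = dx,
                 t0 = 0, t_end = times[length(times)], dt = dt,
                 params = rnai_params(), init = initial_condition(x[1], x[1]),
                 delayed = FALSE),
            class = "rnai_trajectory")
}

#' Closed-form trajectory of the silencing-free linear model
#'
#' With `r = 0` the model is linear with constant coefficients and solvable
#' in closed form: `M(t) = km/dm + (M0 - km/dm) * exp(-dm*t)`, and the
#' protein channel follows by variation of constants (piecewise in `t` when
#' the export delay `tau2` is positive, since the pre-history holds `M` at
#' `M0` until `t = tau2`). Used as an exact oracle for the integrator and
#' for quadrature of the protein accumulation.
#'
#' @param params an [rnai_params()] object; its `r`/`S` are ignored (the
#'   silencing term is absent), `tau2` is honoured.
#' @param init an [initial_condition()] object.
#' @param t_end,dt grid range and spacing.
#' @return An `rnai_trajectory` holding the exact solution on the grid.
#' @export
fixture_linear_system <- function(params, init = initial_condition(),
                                  t_end = 100, dt = 0.01) {
  validate_params(params)
  times <- seq(0, t_end, by = dt)
  sol <- linear_system_solution(params, init)
  M <- sol$M(times); P <- sol$P(times)
  dM <- params$km - params$dm * M
  Mlag <- sol$M(times - params$tau2)
  dP <- params$kp * Mlag - params$dp * P
  structure(list(times = times, M = M, P = P, dM = dM, dP = dP,
                 t0 = 0, t_end = times[length(times)], dt = dt,
                 params = params, init = init, delayed = params$tau2 > 0),
            class = "rnai_trajectory")
}

# Exact solution functions (vectorized) of the r = 0 model.
linear_system_solution <- function(params, init) {
  km <- params$km; dm <- params$dm; kp <- params$kp; dp <- params$dp
  tau2 <- params$tau2
  M0 <- init$M0; P0 <- init$P0
  Mt <- km / dm
  A <- M0 - Mt
  Mfun <- function(t) ifelse(t <= 0, M0, Mt + A * exp(-dm * t))
  # On [0, tau2] the protein sees the constant pre-history M0.
  P_at_tau2 <- NULL
  Pearly <- function(t) kp * M0 / dp + (P0 - kp * M0 / dp) * exp(-dp * t)
  Pfun <- function(t) {
    out <- numeric(length(t))
    early <- t <= tau2
    out[early] <- Pearly(pmax(t[early], 0))
    late <- !early
    if (any(late)) {
      Pt2 <- Pearly(tau2)
      s <- t[late] - tau2
      # P' = kp*(Mt + A*exp(-dm*(t - tau2))) - dp*P beyond tau2
      Pp <- kp * Mt / dp
      C <- kp * A / (dp - dm)
      out[late] <- Pp + C * exp(-dm * s) + (Pt2 - Pp - C) * exp(-dp * s)
    }
    out
  }
  list(M = Mfun, P = Pfun)
}

#' Exact protein accumulation for the silencing-free model
#'
#' Analytic value of `PA = int_0^T P(t) dt` for the closed-form solution of
#' [fixture_linear_system()] with `tau2 = 0`; serves as the quadrature
#' oracle for [accumulate_cost()].
#'
#' @param params an [rnai_params()] object (`tau2` must be 0).
#' @param init an [initial_condition()] object.
#' @param T upper integration limit.
#' @return The exact integral.
#' @export
linear_system_PA <- function(params, init, T) {
  stopifnot(params$tau2 == 0)
  km <- params$km; dm <- params$dm; kp <- params$kp; dp <- params$dp
  Mt <- km / dm
  A <- init$M0 - Mt
  Pp <- kp * Mt / dp
  C <- kp * A / (dp - dm)
  D <- init$P0 - Pp - C
  Pp * T + C * (1 - exp(-dm * T)) / dm + D * (1 - exp(-dp * T)) / dp
}
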