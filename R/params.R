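#' Model parameters for the delayed RNAi dose-effect model
#'
#' Bundles the ten constants of the two-stage gene-expression model with
#' RNAi-mediated mRNA degradation. mRNA is transcribed at rate `km` and
#' degraded at rate `dm`; protein is translated at rate `kp` and degraded at
#' rate `dp`. RNA interference adds a Hill-saturating degradation term
#' `r * S^n / (theta^n + S^n)` acting on mRNA, where `S` is the siRNA dosage,
#' `theta` the half-saturation dosage, `n` the Hill coefficient (number of
#' siRNA target sites) and `r` the maximal extra degradation rate. `tau1` is
#' the silencing (RNAi-processing) delay, `tau2` the nuclear-export /
#' translation delay.
#'
#' Defaults are the nominal oscillatory operating point used throughout the
#' package's examples (high-potency silencing, `tau1` at the Hopf value).
#'
#' @param km mRNA transcription rate (amount/time), > 0.
#' @param dm mRNA degradation rate (1/time), > 0.
#' @param kp translation rate (1/time), > 0.
#' @param dp protein degradation rate (1/time), > 0.
#' @param r maximal RNAi-induced mRNA degradation rate (1/time), > 0.
#' @param theta half-saturation siRNA dosage, > 0.
#' @param n Hill coefficient, integer >= 1.
#' @param S siRNA dosage, >= 0.
#' @param tau1 RNAi degradation delay (time), >= 0.
#' @param tau2 nuclear-export delay (time), >= 0.
#' @return An object of class `rnai_params` (a validated named list).
#' @examples
#' p <- rnai_params()
#' effective_beta(p)
#' @export
rnai_params <- function(km = 10, dm = 0.05, kp = 1, dp = 0.01,
                        r = 0.5062, theta = 10, n = 4, S = 30,
                        tau1 = 3.3594, tau2 = 1) {
  p <- list(km = km, dm = dm, kp = kp, dp = dp, r = r, theta = theta,
            n = n, S = S, tau1 = tau1, tau2 = tau2)
  validate_params(p)
  p$n <- as.integer(p$n)
  class(p) <- "rnai_params"
  p
}

validate_params <- function(p) {
  for (nm in c("km", "dm", "kp", "dp", "r", "theta", "n", "S", "tau1", "tau2")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in c("km", "dm", "kp", "dp", "r", "theta"))
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  for (nm in c("S", "tau1", "tau2"))
    if (p[[nm]] < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  if (p$n < 1 || abs(p$n - round(p$n)) > 1e-8)
    stop("parameter 'n' must be an integer >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.rnai_params <- function(x, ...) {
  cat("RNAi model parameters\n")
  cat(sprintf("  transcription/translation: km = %g, kp = %g\n", x$km, x$kp))
  cat(sprintf("  degradation:               dm = %g, dp = %g\n", x$dm, x$dp))
  cat(sprintf("  silencing (Hill):          r = %g, theta = %g, n = %d, S = %g\n",
              x$r, x$theta, x$n, x$S))
  cat(sprintf("  delays:                    tau1 = %g, tau2 = %g\n", x$tau1, x$tau2))
  cat(sprintf("  effective beta(S):         %g\n", effective_beta(x)))
  invisible(x)
}

#' Constant-history initial condition
#'
#' The model's pre-history on `[-max(tau1, tau2), 0]` is the constant
#' extension of the initial state `(M0, P0)`.
#'
#' @param M0 initial mRNA amount, >= 0.
#' @param P0 initial protein amount, >= 0.
#' @return An object of class `rnai_init`.
#' @export
initial_condition <- function(M0 = 160, P0 = 10000) {
  if (!is.numeric(M0) || length(M0) != 1L || !is.finite(M0) || M0 < 0)
    stop("'M0' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(P0) || length(P0) != 1L || !is.finite(P0) || P0 < 0)
    stop("'P0' must be a single non-negative number", call. = FALSE)
  structure(list(M0 = M0, P0 = P0), class = "rnai_init")
}

# Hill silencing rate, computed through logs so that S^n / theta^n never
# overflow during wide dose sweeps.  Vectorized in S.
hill_beta <- function(r, theta, n, S) {
  b <- numeric(length(S))
  pos <- S > 0
  b[pos] <- r / (1 + exp(n * (log(theta) - log(S[pos]))))
  b
}

# Inverse of hill_beta in S for beta in (0, r).
hill_inverse <- function(r, theta, n, beta) {
  stopifnot(beta >= 0, beta < r)
  if (beta == 0) return(0)
  theta * (beta / (r - beta))^(1 / n)
}

# d beta / d S; the n*b*(1 - b/r)/S form is exact and overflow-safe.
hill_beta_dS <- function(r, theta, n, S) {
  if (S <= 0) {
    if (n >= 2) return(0)
    return(r / theta)  # n = 1: slope r/theta at the origin
  }
  b <- hill_beta(r, theta, n, S)
  n * b * (1 - b / r) / S
}

#' Effective RNAi silencing rate
#'
#' The extra mRNA degradation rate induced by the siRNA dosage carried in
#' `params`: `beta = r * S^n / (theta^n + S^n)`. It is the bifurcation
#' parameter of the stability analysis; `beta(0) = 0`, `beta(theta) = r/2`,
#' and `beta` increases monotonically towards `r` as `S` grows.
#'
#' @param params an [rnai_params()] object.
#' @return The silencing rate (1/time), a single number in `[0, r)`.
#' @export
effective_beta <- function(params) {
  validate_params(params)
  hill_beta(params$r, params$theta, params$n, params$S)
}

#' Positive equilibrium of the model
#'
#' The unique positive fixed point: `M = km / (dm + beta)` and
#' `P = (kp / dp) * M`. The delays do not enter the fixed-point equations.
#'
#' @param params an [rnai_params()] object.
#' @return A list with components `M` and `P`.
#' @export
equilibrium_point <- function(params) {
  b <- effective_beta(params)
  M <- params$km / (params$dm + b)
  list(M = M, P = params$kp / params$dp * M)
}

#' Right-hand sides of the delayed and undelayed model
#'
#' `rhs_dde()` evaluates the delay system's derivatives given the current
#' state and the two delayed mRNA values; `rhs_ode()` is the zero-delay
#' special case (both delayed arguments equal to the current mRNA level).
#' Transiently negative states arising from integration error are passed
#' through unchanged: the delayed terms are linear in the state, so no
#' clipping is applied.
#'
#' @param state numeric vector `c(M, P)`.
#' @param M_tau1 mRNA level at `t - tau1`.
#' @param M_tau2 mRNA level at `t - tau2`.
#' @param params an [rnai_params()] object.
#' @return Numeric vector `c(dM, dP)`.
#' @export
rhs_dde <- function(state, M_tau1, M_tau2, params) {
  b <- effective_beta(params)
  c(params$km - params$dm * state[[1]] - b * M_tau1,
    params$kp * M_tau2 - params$dp * state[[2]])
}

#' @rdname rhs_dde
#' @export
rhs_ode <- function(state, params) {
  rhs_dde(state, state[[1]], state[[1]], params)
}
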