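#' Real-root / complex-root boundary of the characteristic factor
#'
#' For the transcendental factor `f(lambda) = dm + beta*exp(-lambda*tau1) +
#' lambda`, the silencing rate below which `f` has two real negative roots:
#' `beta0 = exp(-dm*tau1 - 1) / tau1`. At `beta = beta0` the two roots merge
#' into the double root `log(beta*tau1)/tau1`; above it they turn complex.
#'
#' @param tau1 silencing delay, > 0 (the delay-free branch is handled by
#'   [classify_regime()]).
#' @param dm mRNA degradation rate, > 0.
#' @return The threshold rate (1/time); strictly decreasing in `tau1`.
#' @export
beta0_threshold <- function(tau1, dm) {
  if (any(tau1 <= 0)) stop("'tau1' must be > 0", call. = FALSE)
  exp(-dm * tau1 - 1) / tau1
}

#' Imaginary-axis crossing frequency
#'
#' The frequency at which a conjugate root pair of the characteristic factor
#' sits on the imaginary axis: `omega0 = sqrt(beta^2 - dm^2)`, defined for
#' `beta > dm` (no crossing exists otherwise; `beta = dm` is the degenerate
#' zero-frequency boundary).
#'
#' @param beta effective silencing rate.
#' @param dm mRNA degradation rate.
#' @return The crossing frequency (1/time).
#' @export
omega0_frequency <- function(beta, dm) {
  if (beta < dm)
    stop("no imaginary-axis crossing exists: beta <= dm", call. = FALSE)
  sqrt(beta^2 - dm^2)
}

#' Critical silencing delay (Hopf point in the delay)
#'
#' The delay at which the equilibrium loses stability for the silencing rate
#' implied by `params`: `tau1* = arccos(-dm/beta) / omega0` on the principal
#' branch, so `omega0 * tau1*` lies in `(pi/2, pi)`. When `beta <= dm` the
#' equilibrium is stable for every delay and `Inf` is returned.
#'
#' @param params an [rnai_params()] object.
#' @return The critical delay (time units), or `Inf` when no finite critical
#'   delay exists.
#' @examples
#' critical_delay(rnai_params(r = 0.5062, S = 30))  # ~3.3586
#' @export
critical_delay <- function(params) {
  b <- effective_beta(params)
  if (b <= params$dm) return(Inf)
  acos(-params$dm / b) / sqrt(b^2 - params$dm^2)
}

#' Hopf boundary in the silencing rate at a given delay
#'
#' Solves the simultaneous crossing conditions `cos(omega*tau1) = -dm/beta`
#' and `omega = sqrt(beta^2 - dm^2)` for `beta` by a bracketed root search in
#' `omega` over the open interval `(pi/(2*tau1), pi/tau1)` (the cosine
#' vanishes at the left endpoint, so it is excluded). The result inverts
#' [critical_delay()]: the critical delay at `beta1(tau1)` equals `tau1`.
#'
#' @param tau1 silencing delay, > 0.
#' @param dm mRNA degradation rate, > 0.
#' @param tol root tolerance in `omega` (default 1e-12).
#' @return The Hopf-boundary silencing rate (1/time).
#' @export
beta1_threshold <- function(tau1, dm, tol = 1e-12) {
  if (tau1 <= 0) stop("'tau1' must be > 0", call. = FALSE)
  g <- function(w) cos(w * tau1) + dm / sqrt(w^2 + dm^2)
  lo <- pi / (2 * tau1) * (1 + 1e-14)
  hi <- pi / tau1 * (1 - 1e-14)
  if (g(lo) <= 0 || g(hi) >= 0)
    stop("no Hopf boundary at this delay: crossing bracket is empty",
         call. = FALSE)
  w <- stats::uniroot(g, c(lo, hi), tol = tol)$root
  sqrt(w^2 + dm^2)
}

#' Critical siRNA dosage switching on oscillations
#'
#' The dosage at which the Hill silencing rate reaches the Hopf boundary at
#' delay `tau1`: `S_n = theta * (beta1 / (r - beta1))^(1/n)`. Because the
#' Hill rate saturates at `r`, no finite dosage reaches the boundary when
#' `beta1 >= r`; in that case `NA` is returned with a `reason` attribute
#' ("no oscillation at any dosage"). The dosage carried in `params` is
#' ignored.
#'
#' @param params an [rnai_params()] object (its `S` is not used).
#' @param tau1 silencing delay at which the boundary is evaluated; defaults
#'   to `params$tau1`.
#' @return The critical dosage, or `NA` when the boundary is unreachable.
#' @export
critical_dosage <- function(params, tau1 = params$tau1) {
  validate_params(params)
  b1 <- beta1_threshold(tau1, params$dm)
  if (b1 >= params$r)
    return(structure(NA_real_, reason = "no oscillation at any dosage"))
  hill_inverse(params$r, params$theta, params$n, b1)
}

#' Classify the stability regime of the equilibrium
#'
#' Orders the effective silencing rate against the two thresholds at the
#' model's own delay: `stable` for `beta <= beta0` (two real negative
#' characteristic roots), `damped_oscillations` for `beta0 < beta < beta1`
#' (decaying complex pair), `hopf` within a relative tolerance of `beta1`
#' (neutral pair, bifurcating limit cycle), and `unstable` beyond. The
#' delay-free model (`tau1 = 0`) is always `stable`.
#'
#' @param params an [rnai_params()] object.
#' @param tol relative half-width of the Hopf classification band
#'   (default 1e-3; the Hopf set has measure zero in exact arithmetic).
#' @return An object of class `rnai_stability` carrying `beta`, `beta0`,
#'   `beta1`, `omega0`, `tau1_star`, `S_critical`, `regime` and
#'   `transversality_sign`.
#' @examples
#' classify_regime(rnai_params(r = 0.5062, S = 30, tau1 = 2.5))$regime
#' @export
classify_regime <- function(params, tol = 1e-3) {
  b <- effective_beta(params)
  dm <- params$dm
  if (params$tau1 == 0) {
    rep <- list(beta = b, beta0 = NA_real_, beta1 = NA_real_,
                omega0 = if (b > dm) sqrt(b^2 - dm^2) else NA_real_,
                tau1_star = critical_delay(params),
                S_critical = NA_real_,
                regime = "stable", transversality_sign = NA_integer_,
                tol = tol)
    class(rep) <- "rnai_stability"
    return(rep)
  }
  b0 <- beta0_threshold(params$tau1, dm)
  b1 <- beta1_threshold(params$tau1, dm)
  regime <- if (abs(b - b1) <= tol * b1) "hopf"
  else if (b <= b0) "stable"
  else if (b < b1) "damped_oscillations"
  else "unstable"
  rep <- list(beta = b, beta0 = b0, beta1 = b1,
              omega0 = if (b > dm) sqrt(b^2 - dm^2) else NA_real_,
              tau1_star = critical_delay(params),
              S_critical = as.numeric(critical_dosage(params)),
              regime = regime,
              transversality_sign = if (b > dm) transversality(params)
              else NA_integer_,
              tol = tol)
  class(rep) <- "rnai_stability"
  rep
}

#' @export
print.rnai_stability <- function(x, ...) {
  cat("Stability report\n")
  cat(sprintf("  beta = %.6g (beta0 = %.6g, beta1 = %.6g)\n",
              x$beta, x$beta0, x$beta1))
  cat(sprintf("  omega0 = %.6g, tau1* = %.6g, S_critical = %.6g\n",
              x$omega0, x$tau1_star, x$S_critical))
  cat(sprintf("  regime: %s (transversality %s)\n", x$regime,
              format(x$transversality_sign)))
  invisible(x)
}

#' Roots of the characteristic equation
#'
#' The linearized system's characteristic equation factors as
#' `(dm + beta*exp(-lambda*tau1) + lambda) * (dp + lambda) = 0`. The protein
#' factor contributes the exact root `-dp`; roots of the transcendental mRNA
#' factor are found by damped Newton iteration started from a rectangular
#' seed grid, de-duplicated, filtered to residual below `residual_tol`, and
#' reported with non-negative imaginary part (conjugates are implied).
#'
#' @param params an [rnai_params()] object with `tau1 > 0`.
#' @param re_limits,im_limits search box; defaults
#'   `[-5*max(dm, dp, beta), 1]` and `[0, 4*pi/tau1]`.
#' @param count maximum number of roots returned (sorted by descending real
#'   part). Fewer roots than requested is reported, not an error.
#' @param seed_grid seeds per axis (default 40).
#' @param residual_tol acceptance threshold on `|f(lambda)|` (default 1e-10).
#' @return A data frame with columns `re`, `im`, `residual`, `factor`.
#' @export
characteristic_roots <- function(params, re_limits = NULL, im_limits = NULL,
                                 count = 6L, seed_grid = 40L,
                                 residual_tol = 1e-10) {
  validate_params(params)
  b <- effective_beta(params)
  dm <- params$dm; dp <- params$dp; tau1 <- params$tau1
  stopifnot(count >= 1L)
  prot <- data.frame(re = -dp, im = 0, residual = 0, factor = "protein")
  if (tau1 == 0) {
    # f reduces to the affine dm + beta + lambda
    out <- rbind(data.frame(re = -(dm + b), im = 0, residual = 0,
                            factor = "transcendental"), prot)
    out <- out[order(-out$re), , drop = FALSE]
    rownames(out) <- NULL
    return(utils::head(out, count))
  }
  if (is.null(re_limits)) re_limits <- c(-5 * max(dm, dp, b), 1)
  if (is.null(im_limits)) im_limits <- c(0, 4 * pi / tau1)
  f <- function(l) dm + b * exp(-l * tau1) + l
  seeds <- as.vector(outer(seq(re_limits[1], re_limits[2], length.out = seed_grid),
                           1i * seq(im_limits[1], im_limits[2], length.out = seed_grid),
                           "+"))
  lam <- seeds
  for (it in 1:80) {
    fv <- dm + b * exp(-lam * tau1) + lam
    fp <- 1 - b * tau1 * exp(-lam * tau1)
    step <- fv / fp
    step[!is.finite(step)] <- 0
    # damp huge steps so seeds near f' = 0 do not fly off
    big <- Mod(step) > 2
    step[big] <- 2 * step[big] / Mod(step[big])
    lam <- lam - step
  }
  res <- Mod(dm + b * exp(-lam * tau1) + lam)
  ok <- is.finite(res) & res < residual_tol
  lam <- lam[ok]
  lam <- complex(real = Re(lam), imaginary = abs(Im(lam)))  # omega >= 0
  lam[abs(Im(lam)) < 1e-9] <- complex(real = Re(lam[abs(Im(lam)) < 1e-9]),
                                      imaginary = 0)
  if (length(lam)) {
    o <- order(Re(lam), Im(lam))
    lam <- lam[o]
    keep <- c(TRUE, Mod(diff(lam)) > 1e-6)
    lam <- lam[keep]
  }
  trans <- data.frame(re = Re(lam), im = Im(lam),
                      residual = Mod(dm + b * exp(-lam * tau1) + lam),
                      factor = rep("transcendental", length(lam)))
  out <- rbind(trans, prot)
  out <- out[order(-out$re), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, count)
}

#' Transversality of the Hopf crossing
#'
#' Sign of `d Re(lambda) / d tau1` at the imaginary-axis crossing
#' `lambda = i*omega0`, from the closed-form real part of the reciprocal
#' derivative of the characteristic equation. A positive sign certifies that
#' the root pair crosses into the right half-plane as the delay grows, making
#' the bifurcation supercritical. The nuclear-export delay `tau2` does not
#' enter the crossing factor, so the sign is invariant to it.
#'
#' @param params an [rnai_params()] object with `beta > dm`.
#' @return `+1L` or `-1L`.
#' @export
transversality <- function(params) {
  b <- effective_beta(params)
  dm <- params$dm; dp <- params$dp
  if (b <= dm)
    stop("transversality undefined: no imaginary-axis crossing (beta <= dm)",
         call. = FALSE)
  w <- sqrt(b^2 - dm^2)
  denom <- ((dm + dp) * w^2)^2 + (w^3 - dm * dp * w)^2
  A <- ((dm + dp)^2 * w^2 + 2 * w * (w^3 - dm * dp * w)) / denom -
    1 / (dp^2 + w^2)
  as.integer(sign(A))
}

#' Approximate period of the bifurcating oscillation
#'
#' First-order expansion of the crossing root for a delay slightly beyond the
#' critical one, `tau1 = tau1* + epsilon`: the frequency correction is
#' `sigma = -((1 + dm*tau1*)*dm*epsilon*omega0 + omega0^3*tau1*epsilon) /
#' ((1 + dm*tau1*)^2 + omega0^2*tau1*^2)` and the growth-rate correction
#' `delta` solves `delta*(1 + dm*tau1*) = omega0*sigma*tau1* +
#' omega0^2*epsilon`. The period estimate is `T = 2*pi/(omega0 + sigma)`; at
#' `epsilon = 0` it reduces exactly to `2*pi/omega0`.
#'
#' @param params an [rnai_params()] object with `beta > dm`.
#' @param epsilon delay excess beyond the critical delay (>= 0); a warning is
#'   issued beyond `tau1*/10`, where the expansion degrades.
#' @return A list of class `rnai_period_estimate` with `T`, `omega0`,
#'   `epsilon`, `sigma`, `delta`, `tau1_star`.
#' @export
hopf_period_approx <- function(params, epsilon = 0) {
  b <- effective_beta(params)
  dm <- params$dm
  if (b <= dm)
    stop("no Hopf point: beta <= dm", call. = FALSE)
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  ts <- critical_delay(params)
  if (epsilon > ts / 10)
    warning("epsilon exceeds tau1*/10; the linear period expansion degrades")
  w0 <- sqrt(b^2 - dm^2)
  sigma <- -((1 + dm * ts) * dm * epsilon * w0 + w0^3 * ts * epsilon) /
    ((1 + dm * ts)^2 + w0^2 * ts^2)
  delta <- (w0 * sigma * ts + w0^2 * epsilon) / (1 + dm * ts)
  structure(list(T = 2 * pi / (w0 + sigma), omega0 = w0, epsilon = epsilon,
                 sigma = sigma, delta = delta, tau1_star = ts),
            class = "rnai_period_estimate")
}

#' @export
print.rnai_period_estimate <- function(x, ...) {
  cat(sprintf("Hopf period estimate: T = %.6g (omega0 = %.6g, epsilon = %g, sigma = %.4g, delta = %.4g)\n",
              x$T, x$omega0, x$epsilon, x$sigma, x$delta))
  invisible(x)
}

#' Hopf period over a dosage-by-Hill-coefficient grid
#'
#' Evaluates the leading-order oscillation period `2*pi/sqrt(beta^2 - dm^2)`
#' on a grid of siRNA dosages and Hill coefficients. Where the silencing rate
#' does not exceed `dm`, no crossing frequency exists and `NA` is reported.
#' Because the Hill rate saturates at `r` for large dosages, the period
#' becomes independent of `n` there, while the critical dosage (see
#' [critical_dosage()]) still shifts strongly with `n`.
#'
#' @param params an [rnai_params()] object supplying `r`, `theta`, `dm`.
#' @param S_values numeric vector of dosages.
#' @param n_values integer vector of Hill coefficients.
#' @return A data frame with columns `S`, `n`, `T`.
#' @export
period_dosage_sweep <- function(params, S_values, n_values) {
  validate_params(params)
  grid <- expand.grid(S = S_values, n = n_values)
  b <- mapply(function(S, n) hill_beta(params$r, params$theta, n, S),
              grid$S, grid$n)
  grid$T <- ifelse(b > params$dm, 2 * pi / sqrt(pmax(b^2 - params$dm^2, 0)),
                   NA_real_)
  grid
}
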