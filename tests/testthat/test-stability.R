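# dosage giving a target silencing rate under the params' Hill curve
hill_S_for_beta <- function(p, beta) p$theta * (beta / (p$r - beta))^(1 / p$n)

# number of zeros of the transcendental factor inside a rectangle, by
# numerical winding of f along its boundary
winding_zero_count <- function(p, re_lim, im_lim, n = 4000) {
  b <- effective_beta(p)
  f <- function(l) p$dm + b * exp(-l * p$tau1) + l
  corners <- c(complex(real = re_lim[1], imaginary = im_lim[1]),
               complex(real = re_lim[2], imaginary = im_lim[1]),
               complex(real = re_lim[2], imaginary = im_lim[2]),
               complex(real = re_lim[1], imaginary = im_lim[2]),
               complex(real = re_lim[1], imaginary = im_lim[1]))
  z <- unlist(lapply(1:4, function(i)
    corners[i] + (corners[i + 1] - corners[i]) * seq(0, 1, length.out = n)))
  fz <- f(z)
  round(sum(Arg(fz[-1] / fz[-length(fz)])) / (2 * pi))
}

# f(lambda) on the real axis, for bracketing-scan oracles.
f_char <- function(lam, dm, beta, tau1) dm + beta * exp(-lam * tau1) + lam

count_real_roots <- function(dm, beta, tau1, lo = -20, hi = 0, n = 40001) {
  x <- seq(lo, hi, length.out = n)
  fx <- f_char(x, dm, beta, tau1)
  sum(diff(sign(fx)) != 0)
}

test_that("beta0 marks the double real root of the characteristic factor", {
  expect_equal(beta0_threshold(2.5, 0.05), exp(-0.05 * 2.5 - 1) / 2.5,
               tolerance = 1e-12)
  expect_equal(beta0_threshold(2.5, 0.05), 0.129861, tolerance = 1e-5)
  expect_equal(beta0_threshold(1, 0.05), 0.349938, tolerance = 1e-5)
  expect_error(beta0_threshold(0, 0.05), "tau1")

  # at beta = beta0 the stationary point of f is a root (double root);
  # below/above, two/zero real roots in a bracketing scan
  for (tau1 in c(1, 2.5, 6)) {
    dm <- 0.05
    b0 <- beta0_threshold(tau1, dm)
    lam_star <- log(b0 * tau1) / tau1
    expect_equal(f_char(lam_star, dm, b0, tau1), 0, tolerance = 1e-12)
    expect_equal(count_real_roots(dm, 0.9 * b0, tau1), 2)
    expect_equal(count_real_roots(dm, 1.1 * b0, tau1), 0)
  }
  # monotone decrease towards 0
  grid <- beta0_threshold(seq(0.5, 50, by = 0.5), 0.05)
  expect_true(all(diff(grid) < 0))
  expect_lt(grid[length(grid)], 1e-2)
})

test_that("crossing frequency satisfies the characteristic equation on the axis", {
  w0 <- omega0_frequency(0.500027, 0.05)
  expect_equal(w0, sqrt(0.500027^2 - 0.05^2), tolerance = 1e-12)
  expect_equal(w0, 0.497521, tolerance = 1e-6)
  expect_identical(omega0_frequency(0.05, 0.05), 0)
  expect_error(omega0_frequency(0.03, 0.05), "no imaginary-axis crossing")
  expect_equal(omega0_frequency(0.3, 0), 0.3)

  # residual of f at i*omega0 with the matching critical delay
  p <- fig1_params()
  b <- effective_beta(p)
  ts <- critical_delay(p)
  expect_lt(Mod(f_char(1i * omega0_frequency(b, p$dm), p$dm, b, ts)), 1e-12)
})

test_that("critical delay matches closed forms and blows up as beta drops to dm", {
  expect_equal(critical_delay(fig1_params()), 3.3586, tolerance = 5e-5)
  p <- rnai_params(dm = 0.05, r = 0.2, theta = 1, n = 1, S = 1)  # beta = 0.1
  expect_equal(critical_delay(p), acos(-1 / 2) / (0.05 * sqrt(3)),
               tolerance = 1e-12)
  # omega0 * tau1* on the principal branch
  b <- effective_beta(fig1_params())
  expect_true(omega0_frequency(b, 0.05) * critical_delay(fig1_params()) > pi / 2)
  expect_true(omega0_frequency(b, 0.05) * critical_delay(fig1_params()) < pi)
  # monotone blow-up towards beta = dm
  p <- fig1_params()
  taus <- vapply(c(0.4, 0.2, 0.1, 0.07, 0.051), function(b_target) {
    p$S <- hill_S_for_beta(p, b_target)
    critical_delay(p)
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
  p$S <- 0.1  # beta far below dm
  expect_identical(critical_delay(p), Inf)
})

test_that("beta1 inverts the critical delay and dominates beta0", {
  b1 <- beta1_threshold(3.3586, 0.05)
  expect_equal(b1, 0.500027, tolerance = 1e-4)
  p <- fig1_params()
  p$S <- hill_S_for_beta(p, b1)
  expect_equal(critical_delay(p), 3.3586, tolerance = 1e-9)
  for (tau1 in c(0.5, 1, 2.5, 5, 20))
    expect_gt(beta1_threshold(tau1, 0.05), beta0_threshold(tau1, 0.05))
})

test_that("critical dosage is the Hill inverse of the Hopf boundary", {
  expect_equal(critical_dosage(fig1_params(), tau1 = 3.3586), 30,
               tolerance = 1e-3)
  # saturation ceiling: the boundary is unreachable at low potency
  out <- critical_dosage(q_params(), tau1 = 2.5)   # beta1(2.5) >> r = 0.02
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "no oscillation")
  # larger n reaches the boundary at smaller dosage...
  p <- fig1_params()
  Sn <- vapply(2:6, function(n) { p$n <- n; critical_dosage(p, tau1 = 3.3586) },
               numeric(1))
  expect_true(all(diff(Sn) < 0))
  # ...while the limiting period at large dosage does not depend on n
  sw <- period_dosage_sweep(p, S_values = 150, n_values = 2:6)
  expect_lt(diff(range(sw$T)) / mean(sw$T), 0.01)
})

test_that("regime classification follows the threshold ordering", {
  expect_identical(classify_regime(fig1_params(tau1 = 2.5))$regime,
                   "damped_oscillations")
  rep <- classify_regime(fig1_params(tau1 = 3.3594))
  expect_identical(rep$regime, "hopf")
  expect_identical(rep$transversality_sign, 1L)
  p <- fig1_params(); p$S <- 0.01      # beta ~ 0: below every threshold
  expect_identical(classify_regime(p)$regime, "stable")
  expect_identical(classify_regime(fig1_params(tau1 = 5))$regime, "unstable")
  expect_identical(classify_regime(fig1_params(tau1 = 0))$regime, "stable")
})

test_that("characteristic roots carry small residuals and the exact -dp root", {
  p <- fig1_params(tau1 = 2.5)
  roots <- characteristic_roots(p, count = 6)
  expect_true(any(roots$re == -p$dp & roots$im == 0))
  trans <- roots[roots$factor == "transcendental", ]
  expect_true(all(trans$residual < 1e-10))
  # damped regime: leading transcendental root strictly stable and oscillatory
  lead <- trans[1, ]
  expect_lt(lead$re, 0)
  expect_gt(lead$im, 0)
  # count of zeros in a strip around the leading root via the argument principle
  expect_equal(winding_zero_count(p, lead$re + c(-0.05, 0.05),
                                  lead$im + c(-0.2, 0.2)), 1)

  # at the critical delay the leading pair sits on the imaginary axis
  ps <- fig1_params(tau1 = critical_delay(fig1_params()))
  r2 <- characteristic_roots(ps, count = 4)
  lead2 <- r2[r2$factor == "transcendental", ][1, ]
  expect_lt(abs(lead2$re), 1e-6)
  expect_equal(lead2$im, 0.497521, tolerance = 1e-5)
})

test_that("the crossing is transversal with positive speed, independent of tau2", {
  p <- fig1_params()
  expect_identical(transversality(p), 1L)
  p2 <- p; p2$tau2 <- 17
  expect_identical(transversality(p2), transversality(p))
  # finite-difference cross-check on the leading root across the crossing
  ts <- critical_delay(p)
  re_lead <- function(tau1) {
    r <- characteristic_roots(fig1_params(tau1 = tau1), count = 4)
    r[r$factor == "transcendental", ]$re[1]
  }
  h <- 1e-3
  lo <- re_lead(ts - h); hi <- re_lead(ts + h)
  expect_lt(lo, 0)
  expect_gt(hi, 0)
  expect_gt((hi - lo) / (2 * h), 0)
})

test_that("the Hopf period expansion reduces and perturbs correctly", {
  p <- fig1_params()
  pe0 <- hopf_period_approx(p, epsilon = 0)
  expect_identical(pe0$sigma, 0)
  expect_identical(pe0$delta, 0)
  expect_equal(pe0$T, 2 * pi / pe0$omega0, tolerance = 1e-15)
  expect_equal(pe0$T, 12.629, tolerance = 1e-4)

  pe <- hopf_period_approx(p, epsilon = 0.1)
  expect_equal(pe$sigma, -0.010651, tolerance = 1e-4)
  expect_equal(pe$T, 12.905, tolerance = 1e-4)
  # delta solves the simultaneous linear system it is defined by
  ts <- pe$tau1_star; w0 <- pe$omega0
  expect_equal(pe$delta * (1 + p$dm * ts),
               w0 * pe$sigma * ts + w0^2 * pe$epsilon, tolerance = 1e-12)
  expect_warning(hopf_period_approx(p, epsilon = ts / 5), "expansion degrades")
  # the measured period tracks the corrected estimate beyond the crossing
  tr <- simulate_model(fig1_params(tau1 = ts + 0.1), ref_init(), horizon = 600)
  lc <- measure_limit_cycle(tr)
  expect_equal(lc$raw_period, pe$T, tolerance = 0.02)
})

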