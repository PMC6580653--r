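test_that("cost accumulation: exact identity, pure-siRNA case, quadrature oracle", {
  # zero protein: the cost is siRNA expenditure alone
  zero <- fixture_sinusoid(offset = 0, amplitude = 0, t_end = 60, dt = 0.01)
  cb <- accumulate_cost(zero, S = 10, Ps = 1, T = 60)
  expect_identical(cb$PA, 0)
  expect_identical(cb$J, 600)

  # trapezoid quadrature against the analytic protein integral (r off)
  p <- no_rnai_params()
  tr <- fixture_linear_system(p, ref_init(), t_end = 60, dt = 0.01)
  cb <- accumulate_cost(tr, S = 0, Ps = 1, T = 60)
  exact <- linear_system_PA(p, ref_init(), T = 60)
  expect_lt(abs(cb$PA - exact) / exact, 1e-7)   # O(dt^2) for dt = 0.01

  # J = sirna_cost + PA exactly, by construction
  expect_identical(cb$J, cb$sirna_cost + cb$PA)
  expect_error(accumulate_cost(fixture_sinusoid(t_end = 10), 1, 1, 60),
               "shorter than T")
})

test_that("expenditure identity holds at the two reported optimal dosages", {
  # with and without delays, J - PA = Ps*S*T exactly for our evaluations,
  # and the expenditures at the two reported optima match their printed
  # differences (1822.2 and 2580.6) to printed rounding
  for (case in list(list(S = 30.37, delayed = TRUE),
                    list(S = 43.01, delayed = FALSE))) {
    pr <- control_problem(q_params(), delayed = case$delayed)
    cb <- rnaidose:::evaluate_cost(pr, case$S)
    expect_equal(cb$J - cb$PA, cb$sirna_cost, tolerance = 1e-12)
    expect_equal(cb$sirna_cost, case$S * 60, tolerance = 1e-12)
  }
  expect_equal(2.6381e5 - 2.6199e5, 30.37 * 60, tolerance = 2e-3)
})

test_that("the protein costate matches its closed form; terminal values vanish", {
  for (delayed in c(FALSE, TRUE)) {
    pr <- control_problem(q_params(), delayed = delayed)
    tr <- rnaidose:::forward_solve(pr, 20)
    adj <- solve_costate(pr, 20, tr)
    n <- length(adj$times)
    expect_identical(adj$lambda1[n], 0)
    expect_identical(adj$lambda2[n], 0)
    closed <- (1 - exp(-0.01 * (60 - adj$times))) / 0.01
    expect_lt(max(abs(adj$lambda2 - closed)), 1e-8)
    expect_equal(adj$lambda2[1], 45.119, tolerance = 1e-4)
  }
})

test_that("the adjoint gradient reproduces finite differences of the cost", {
  h <- 1e-3
  for (delayed in c(FALSE, TRUE)) {
    pr <- control_problem(q_params(), delayed = delayed)
    for (S in c(10, 35)) {
      tr <- rnaidose:::forward_solve(pr, S)
      g <- cost_gradient(pr, S, tr, solve_costate(pr, S, tr))
      fd <- (rnaidose:::evaluate_cost(pr, S + h)$J -
               rnaidose:::evaluate_cost(pr, S - h)$J) / (2 * h)
      expect_lt(abs(g - fd) / abs(fd), 1e-4)
    }
    # Hill derivative vanishes at S = 0 for n >= 2: gradient is Ps*T exactly
    tr0 <- rnaidose:::forward_solve(pr, 0)
    g0 <- cost_gradient(pr, 0, tr0, solve_costate(pr, 0, tr0))
    expect_identical(g0, 60)
  }
})

test_that("dosage optimization finds the interior optimum with a near-zero
           gradient, and the boundary when siRNA is prohibitive", {
  pr <- control_problem(q_params(), delayed = FALSE)
  res <- optimize_dosage(pr)
  expect_gt(res$S_opt, pr$S_bounds[1])
  expect_lt(res$S_opt, pr$S_bounds[2])
  # scan minimum brackets the refined optimum
  i <- which.min(res$scan$J)
  expect_lt(abs(res$scan$S[i] - res$S_opt), 1)
  # first-order optimality: |dJ/dS| tiny relative to the scan's J variation
  expect_lt(abs(res$gradient_at_opt),
            1e-4 * diff(range(res$scan$J)) / diff(range(res$scan$S)))
  expect_identical(res$J_opt, res$cost$J)

  # dominant siRNA price drives the dosage to the lower boundary
  prb <- control_problem(q_params(), Ps = 1e6, S_bounds = c(0, 50),
                         delayed = FALSE)
  resb <- optimize_dosage(prb, scan_step = 10)
  expect_lt(resb$S_opt, 0.01)
})

test_that("beyond the optimum the Hill rate saturates and accumulation flattens", {
  pr <- control_problem(q_params(), delayed = FALSE)
  p <- q_params()
  PA <- vapply(c(45, 60, 100), function(S)
    rnaidose:::evaluate_cost(pr, S)$PA, numeric(1))
  expect_lt(diff(range(PA)) / PA[1], 1e-3)
  for (S in c(45, 60, 100)) {
    p$S <- S
    expect_gt(effective_beta(p), 0.99 * p$r)
  }
})
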