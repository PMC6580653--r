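test_that("silencing-free run reproduces the closed-form linear solution", {
  tr <- simulate_model(no_rnai_params(), ref_init(), horizon = 20, dt = 0.01,
                       delayed = FALSE)
  expect_equal(tr$M[length(tr$M)], 200 - 40 * exp(-1), tolerance = 1e-10)
  # full-series comparison against the exact two-exponential protein channel
  ex <- fixture_linear_system(no_rnai_params(), ref_init(), t_end = 20, dt = 0.01)
  expect_lt(max(abs(tr$P - ex$P)) / max(ex$P), 1e-10)
})

test_that("vanishing delays reduce the DDE to the ODE on the same grid", {
  p <- fig1_params(tau1 = 1e-6, tau2 = 1e-6)
  tr_d <- simulate_model(p, ref_init(), horizon = 60, dt = 0.01, delayed = TRUE)
  p0 <- p; p0$tau1 <- 0; p0$tau2 <- 0
  tr_o <- simulate_model(p0, ref_init(), horizon = 60, dt = 0.01, delayed = FALSE)
  expect_lt(max(abs(tr_d$M - tr_o$M)) / max(abs(tr_o$M)), 1e-6)
  expect_lt(max(abs(tr_d$P - tr_o$P)) / max(abs(tr_o$P)), 1e-6)
})

test_that("damped regime converges to the equilibrium of the model core", {
  p <- fig1_params(tau1 = 2.5)
  tr <- simulate_model(p, ref_init(), horizon = 600)
  eq <- equilibrium_point(p)
  expect_lt(abs(tr$M[length(tr$M)] - eq$M), 1e-3 * eq$M)
})

test_that("the mRNA series does not depend on the export delay", {
  a <- simulate_model(fig1_params(tau2 = 1), ref_init(), horizon = 80, dt = 0.02)
  b <- simulate_model(fig1_params(tau2 = 3), ref_init(), horizon = 80, dt = 0.02)
  expect_identical(a$M, b$M)
  expect_gt(max(abs(a$P - b$P)), 1)  # the protein series does differ
})

test_that("the integrator converges at fourth order on the ODE system", {
  p <- q_params(tau1 = 0, tau2 = 0)
  endpoint <- function(dt)
    simulate_model(p, ref_init(), horizon = 10, dt = dt, delayed = FALSE)$M |>
      tail(1)
  ref <- endpoint(0.0125)
  e1 <- abs(endpoint(0.2) - ref)
  e2 <- abs(endpoint(0.1) - ref)
  expect_gt(e1 / e2, 8)   # ~16 for a 4th-order method
  expect_lt(e1 / e2, 32)
})

test_that("a run extended from a snapshot continues the original trajectory", {
  p <- fig1_params()
  full <- simulate_model(p, ref_init(), horizon = 120, dt = 0.02)
  part <- simulate_model(p, ref_init(), horizon = 60, dt = 0.02)
  cont <- extend_trajectory(part, 60)
  expect_equal(cont$times, full$times)
  expect_equal(cont$M, full$M, tolerance = 1e-12)
  expect_equal(cont$P, full$P, tolerance = 1e-12)
})

test_that("delayed trajectories agree with an independent DDE solver", {
  p <- fig1_params(tau1 = 2.5)
  tr <- simulate_model(p, ref_init(), horizon = 100, dt = 0.02)
  b <- effective_beta(p)
  f <- function(t, y, parms) {
    M1 <- if (t - p$tau1 <= 0) 160 else deSolve::lagvalue(t - p$tau1, 1)
    M2 <- if (t - p$tau2 <= 0) 160 else deSolve::lagvalue(t - p$tau2, 1)
    list(c(p$km - p$dm * y[1] - b * M1, p$kp * M2 - p$dp * y[2]))
  }
  ref <- deSolve::dede(c(160, 10000), times = seq(0, 100, by = 0.5), func = f,
                       parms = NULL, atol = 1e-10, rtol = 1e-10)
  ours <- trajectory_state(tr, ref[, 1])
  expect_lt(max(abs(ours$M - ref[, 2])) / max(abs(ref[, 2])), 1e-5)
  expect_lt(max(abs(ours$P - ref[, 3])) / max(abs(ref[, 3])), 1e-5)
})

test_that("trajectory queries honour the pre-history and range contract", {
  p <- fig1_params()
  tr <- simulate_model(p, ref_init(), horizon = 30, dt = 0.02)
  pre <- trajectory_state(tr, c(-p$tau1, -0.5, 0))
  expect_equal(pre$M, rep(160, 3))
  expect_equal(pre$P, rep(10000, 3))
  # mid-grid interpolation is consistent with a finer integration
  fine <- simulate_model(p, ref_init(), horizon = 30, dt = 0.005)
  at <- c(7.013, 15.507, 29.999)
  expect_equal(trajectory_state(tr, at)$M, trajectory_state(fine, at)$M,
               tolerance = 1e-5)
  expect_error(trajectory_state(tr, 31), "outside")
  expect_error(trajectory_state(tr, -10), "outside")
})

test_that("a diverging trajectory aborts with a diagnostic naming the time", {
  p <- rnai_params(km = 10, dm = 0.05, kp = 1, dp = 0.01, r = 1001,
                   theta = 10, n = 4, S = 1000, tau1 = 5, tau2 = 1)
  expect_error(simulate_model(p, ref_init(), horizon = 600, dt = 0.02),
               "non-finite state at t = ")
})

test_that("under-resolved positive delays trigger a warning", {
  p <- fig1_params(tau1 = 0.05, tau2 = 1)
  expect_warning(simulate_model(p, ref_init(), horizon = 2, dt = 0.02),
                 "fewer than 10 steps")
})

test_that("CSV export writes the documented header and full precision", {
  tr <- simulate_model(fig1_params(), ref_init(), horizon = 1, dt = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  lines <- readLines(path)
  expect_identical(lines[1], "t,M,P")
  back <- utils::read.csv(path)
  expect_equal(back$M, tr$M, tolerance = 1e-15)
})
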