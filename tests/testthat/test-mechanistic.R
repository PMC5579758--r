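test_that("thymic recovery has the right endpoints, closed form and shape", {
  expect_equal(thymic_recovery(0, 133, 9.66), 0)
  expect_equal(thymic_recovery(1e6, 133, 9.66), 1, tolerance = 1e-8)
  expect_equal(thymic_recovery(133, 133, 9.66), (1 - exp(-2)) / 2)
  t <- seq(0, 1500, by = 1)
  expect_true(all(diff(thymic_recovery(t, 133, 9.66)) >= 0))
  # earlier recovery for smaller lambda_h
  expect_true(all(thymic_recovery(t[-1], 60, 9.66) >=
                    thymic_recovery(t[-1], 133, 9.66)))
  # overflow-safe for extreme sampled rates
  expect_true(is.finite(thymic_recovery(1, 133, 5e4)))
  expect_gte(thymic_recovery(1, 133, 5e4), 0)
  expect_error(thymic_recovery(-1, 133, 9.66))
})

test_that("proliferation and loss rates match their algebraic identities", {
  cs <- consts_default
  age <- 1110
  N <- expected_total_cd4(age, cs)
  y <- ki67_fraction(age, cs)
  expect_equal(proliferation_rate(N, age, p0 = 0.207), 0.207 * y)
  expect_equal(loss_rate(N, age, d0 = 0.477), 0.477 * y)
  expect_equal(proliferation_rate(1e-9, age, p0 = 0.207), 0.207 * y * exp(1),
               tolerance = 1e-6)
  expect_equal(loss_rate(1e-9, age, d0 = 0.477), 0.477 * y / exp(1),
               tolerance = 1e-6)
  expect_equal(proliferation_rate(168, age, p0 = 0.207),
               0.207 * y * exp(1 - 168 / N))
  expect_equal(loss_rate(168, age, d0 = 0.477),
               0.477 * y * exp(168 / N - 1))
  # competition: proliferation decreasing, loss increasing in concentration
  xs <- seq(10, 3000, by = 10)
  expect_true(all(diff(proliferation_rate(xs, age, 0.207)) < 0))
  expect_true(all(diff(loss_rate(xs, age, 0.477)) > 0))
  expect_error(proliferation_rate(0, age, 0.207), "positive")
  expect_error(loss_rate(-5, age, 0.477), "positive")
})

test_that("pure decay and pure production match closed-form oracles", {
  # lambda0 = p0 = 0: X' = -d(X) X, strictly decreasing
  p <- structural_parameters(1e-12, 0.477, 1e-12, 168, 133, 9.66)
  tr <- solve_trajectory(p, 1110, grid = seq(0, 200, by = 5))
  expect_true(all(diff(tr$cd4) < 0))
  expect_true(all(tr$cd4 > 0))
  # p0 = d0 = 0: X(t) = x0 + integral of lambda, vs quadrature oracle
  p2 <- structural_parameters(0.216, 1e-12, 1e-12, 30.6, 133, 9.66)
  times <- c(50, 150, 365, 730)
  tr2 <- solve_trajectory(p2, 1110, grid = times)
  lam <- function(s) {
    0.216 * thymic_output_for_age(1110 + s, consts_default) *
      thymic_recovery(s, 133, 9.66)
  }
  for (i in seq_along(times)) {
    oracle <- 30.6 + integrate(lam, 0, times[i], rel.tol = 1e-10)$value
    expect_equal(tr2$cd4[i], oracle, tolerance = 1e-3)
  }
})

test_that("production solver agrees with independent integrators", {
  # deSolve lsoda with an R-side right-hand side, plus fixed-step RK4
  set.seed(7)
  for (rep in 1:6) {
    eta <- rnorm(6, 0, 0.4)
    th <- as.numeric(typical_parameters())[1:6] * exp(eta)
    p <- structural_parameters(th[1], th[2], th[3], th[4], th[5], th[6])
    age0 <- runif(1, 100, 4000)
    times <- sort(runif(4, 30, 600))
    tr <- solve_trajectory(p, age0, grid = times)
    ref <- rk4_cd4(p, age0, times, h = 0.05)
    expect_equal(tr$cd4, ref, tolerance = 1e-3)
    rhs <- function(t, X, parms) {
      tau <- age0 + t
      lam <- p[["lambda0"]] * thymic_output_for_age(tau, consts_default) *
        thymic_recovery(t, p[["lambda_h"]], p[["lambda_r"]])
      r <- X / expected_total_cd4(tau, consts_default)
      y <- ki67_fraction(tau, consts_default)
      list(lam - p[["d0"]] * y * exp(r - 1) * X +
             p[["p0"]] * y * exp(1 - r) * X)
    }
    lsoda <- deSolve::ode(c(X = p[["x0"]]), c(0, times), rhs, NULL,
                          rtol = 1e-10, atol = 1e-8)
    expect_equal(tr$cd4, unname(lsoda[-1, "X"]), tolerance = 1e-3)
  }
})

test_that("halving solver tolerances leaves trajectories unchanged", {
  p <- typical_parameters()
  grid <- seq(0, 2000, by = 50)[-1]
  a <- solve_trajectory(p, 1110, grid = grid, rtol = 1e-8, atol = 1e-6)
  b <- solve_trajectory(p, 1110, grid = grid, rtol = 5e-9, atol = 5e-7)
  expect_true(all(abs(a$cd4 - b$cd4) / b$cd4 < 1e-3))
})

test_that("trajectories stay positive across random parameter draws", {
  set.seed(11)
  for (rep in 1:20) {
    th <- as.numeric(typical_parameters())[1:6] * exp(rnorm(6, 0, 0.8))
    p <- structural_parameters(th[1], th[2], th[3], th[4], th[5], th[6])
    tr <- solve_trajectory(p, runif(1, 50, 5000), grid = seq(0, 2556, 40))
    expect_true(all(tr$cd4 > 0))
  }
})

test_that("threshold crossing is located to sub-day accuracy", {
  p <- typical_parameters()
  p["x0"] <- 30.6
  # crossing at start when already above a rising trajectory's threshold
  expect_equal(time_to_threshold(p, 1110, threshold = 30.6), 0)
  t500 <- time_to_threshold(p, 1110, threshold = 500)
  tr <- solve_trajectory(p, 1110, grid = seq(floor(t500) - 2, t500 + 2, 0.01))
  first <- tr$time[which(tr$cd4 >= 500)[1]]
  expect_equal(t500, first, tolerance = 0.02)
  # relative threshold crosses later than the same absolute concentration now
  t90 <- time_to_threshold(p, 1110, threshold = 0.9, relative = TRUE)
  xat <- solve_trajectory(p, 1110, grid = c(t90))$cd4
  expect_equal(xat, 0.9 * expected_total_cd4(1110 + t90), tolerance = 1e-3)
  # unreachable threshold returns the not-reached sentinel
  expect_true(is.na(time_to_threshold(p, 1110, threshold = 1e5,
                                      horizon = 365)))
  expect_error(time_to_threshold(p, 1110, threshold = -5), "positive")
})

test_that("thymic output curve is zero at transplant and unimodal", {
  p <- typical_parameters()
  oc <- thymic_output_curve(p, 1110, grid = seq(0, 2556, by = 1))
  expect_equal(oc$output[1], 0)
  peak <- which.max(oc$output)
  expect_true(all(diff(oc$output[1:peak]) >= 0))
  expect_true(all(diff(oc$output[peak:nrow(oc)]) <= 0))
  # far beyond recovery the curve tracks lambda0 * lambda_age to within 1%
  late <- oc$output[oc$time == 2000]
  expect_equal(late, 0.216 * thymic_output_for_age(1110 + 2000),
               tolerance = 0.01)
  # recovery midpoint from the closed form: Delta = 0.5 near 137 days
  mid <- uniroot(function(t) thymic_recovery(t, 133, 9.66) - 0.5,
                 c(1, 400))$root
  expect_equal(mid, 137, tolerance = 0.01)
})

test_that("mean lifespan follows the loss-rate reciprocal and grows with age", {
  y365 <- ki67_fraction(365)
  expect_equal(mean_lifespan(365, 0.477, occupancy = 1),
               1 / (0.477 * y365))
  expect_gt(mean_lifespan(3650, 0.477), mean_lifespan(365, 0.477))
  # documented occupancy convention (0.9, the long-run level) reproduces a
  # plausible infant lifespan of roughly 130 days
  expect_equal(mean_lifespan(365, 0.477, occupancy = 0.9), 130,
               tolerance = 0.03)
})

test_that("solver failure surfaces as an explicit error", {
  p <- typical_parameters()
  expect_error(solve_trajectory(p, -5, 100), "non-negative")
  expect_error(solve_trajectory(p, 100, horizon = -1), "positive")
})
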