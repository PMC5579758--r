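test_that("individual parameters combine typicals, covariates and effects", {
  pop <- default_population_parameters()
  # identity at eta = 0 with no flags
  p <- individual_parameters(pop, eta = rep(0, 6))
  expect_equal(as.numeric(p)[1:6], unname(pop$theta))
  # the published lymphodepleting-antibody example: 178 * (1 - 0.828) = 30.6
  pop2 <- pop
  pop2$theta["x0"] <- 178
  ef <- covariate_effect("alemtuzumab", "x0", -0.828)
  p2 <- individual_parameters(pop2, list(ef), flags = c(alemtuzumab = 1))
  expect_equal(p2[["x0"]], 178 * (1 - 0.828), tolerance = 1e-12)
  expect_equal(p2[["x0"]], 30.6, tolerance = 1e-3)
  # flag off leaves the typical value untouched
  p3 <- individual_parameters(pop2, list(ef), flags = c(alemtuzumab = 0))
  expect_equal(p3[["x0"]], 178)
  # two effects on one parameter compose multiplicatively, order-free
  e1 <- covariate_effect("a", "x0", -0.5)
  e2 <- covariate_effect("b", "x0", 0.28)
  fl <- c(a = 1, b = 1)
  expect_equal(individual_parameters(pop2, list(e1, e2), fl)[["x0"]],
               individual_parameters(pop2, list(e2, e1), fl)[["x0"]])
  expect_equal(individual_parameters(pop2, list(e1, e2), fl)[["x0"]],
               178 * 0.5 * 1.28)
  # random effect acts on the covariate-adjusted value
  p4 <- individual_parameters(pop2, list(ef), flags = c(alemtuzumab = 1),
                              eta = c(0, 0, 0, log(2), 0, 0))
  expect_equal(p4[["x0"]], 30.6 * 2, tolerance = 1e-3)
  expect_error(covariate_effect("a", "nope", 0.1), "unknown parameter")
  expect_error(covariate_effect("a", "x0", -1.5), "1 \\+ effect")
})

test_that("observation log likelihood matches closed forms and a brute force", {
  pop <- default_population_parameters()
  p <- typical_parameters()
  s2 <- 0.219
  times <- c(30, 90, 365, 730)
  x <- solve_trajectory(p, 1110, grid = times)$cd4
  # observations exactly on the curve: only the normalising constant remains
  sub <- subject_record("a", 1110, times, x)
  expect_equal(observation_loglik(sub, p, s2),
               -(4 / 2) * log(2 * pi * s2), tolerance = 1e-8)
  # halving sigma2 with zero residuals raises the log density by (n/2) log 2
  expect_equal(observation_loglik(sub, p, s2 / 2) -
                 observation_loglik(sub, p, s2),
               2 * log(2), tolerance = 1e-8)
  # noisy observations: per-point normal densities summed by hand
  set.seed(3)
  dv <- exp(log(x) + rnorm(4, 0, sqrt(s2)))
  sub2 <- subject_record("b", 1110, times, dv)
  brute <- sum(dnorm(log(dv), mean = log(x), sd = sqrt(s2), log = TRUE))
  expect_equal(observation_loglik(sub2, p, s2), brute, tolerance = 1e-8)
  # no observations contribute zero
  expect_equal(observation_loglik(subject_record("c", 1110), p, s2), 0)
})

test_that("importance-sampling marginal matches 2-D grid quadrature", {
  pop <- default_population_parameters()
  pop$omega <- diag(c(0, 0, 0.251, 1.31, 0, 0))  # two free random effects
  set.seed(21)
  spec <- cohort_spec(n_subjects = 3, seed = 77)
  dat <- simulate_cohort(pop, spec = spec)
  subs <- as_subject_list(dat)
  cv <- cd4recon:::consts_vector(consts_default)
  for (s in subs[1:2]) {
    is_res <- marginal_neg2ll_is(s, pop, n_samples = 4000, seed = 5)
    # quadrature oracle on a 60 x 60 grid over +/- 6 prior sd
    sds <- sqrt(c(0.251, 1.31))
    g1 <- seq(-6 * sds[1], 6 * sds[1], length.out = 60)
    g2 <- seq(-6 * sds[2], 6 * sds[2], length.out = 60)
    grid <- as.matrix(expand.grid(g1, g2))
    lb <- log(pop$theta)
    lp <- matrix(rep(lb, each = nrow(grid)), ncol = 6)
    lp[, 3] <- lp[, 3] + grid[, 1]
    lp[, 4] <- lp[, 4] + grid[, 2]
    ll <- cd4recon:::cd4_loglik_cpp(lp, s$age0, s$times, s$log_dv,
                                    pop$sigma2, cv)
    prior <- dnorm(grid[, 1], 0, sds[1], log = TRUE) +
      dnorm(grid[, 2], 0, sds[2], log = TRUE)
    lw <- ll + prior
    m <- max(lw)
    integral <- m + log(sum(exp(lw - m))) +
      log(diff(g1)[1]) + log(diff(g2)[1])
    expect_equal(is_res$objective, -2 * integral, tolerance = 0.1)
  }
})

test_that("degenerate priors and empty subjects reduce the marginal sensibly", {
  pop <- default_population_parameters()
  s <- as_subject_list(small_cohort(n = 2, seed = 55))[[1]]
  # near-point-mass prior: marginal approaches the likelihood at eta = 0
  pop0 <- pop
  pop0$omega <- diag(rep(1e-8, 6))
  res <- marginal_neg2ll_is(s, pop0, n_samples = 500, seed = 2)
  ll0 <- observation_loglik(s, individual_parameters(pop0, flags = s$flags),
                            pop0$sigma2)
  expect_equal(res$objective, -2 * ll0, tolerance = 0.05)
  # no observations: objective zero, posterior equals the prior
  empty <- subject_record("none", 1000, flags = s$flags)
  res0 <- marginal_neg2ll_is(empty, pop, n_samples = 200, seed = 3)
  expect_equal(res0$objective, 0)
  expect_equal(res0$eta_mean, rep(0, 6))
  res_eb <- empirical_bayes(empty, pop)
  expect_equal(res_eb$eta_cov, pop$omega)
  # reproducibility under a fixed seed
  a <- marginal_neg2ll_is(s, pop, n_samples = 300, seed = 9)
  b <- marginal_neg2ll_is(s, pop, n_samples = 300, seed = 9)
  expect_identical(a$objective, b$objective)
  expect_identical(a$eta_mean, b$eta_mean)
})

test_that("empirical Bayes recovers known effects and gains precision", {
  pop <- default_population_parameters()
  pop$omega <- diag(c(0.4, 0.4, 0.15, 0.4, 0.3, 0.3))
  truth_eta <- c(0.3, -0.2, 0.1, 0.4, -0.3, 0.2)
  p_true <- individual_parameters(pop, eta = truth_eta)
  times <- sort(exp(runif(30, log(20), log(2200))))
  set.seed(13)
  # essentially noise-free observations pin the random effects down
  x <- solve_trajectory(p_true, 1110, grid = times)$cd4
  dv <- exp(log(x) + rnorm(30, 0, 1e-2))
  pop_lown <- pop
  pop_lown$sigma2 <- 1e-4
  s <- subject_record("t", 1110, times, dv)
  eb <- empirical_bayes(s, pop_lown, n_samples = 800, seed = 4)
  expect_true(all(abs(eb$eta_mean - truth_eta) < 0.05))
  # posterior variance shrinks as observations accumulate
  prev <- diag(pop$omega)
  for (k in c(3, 10, 30)) {
    sk <- subject_record("t", 1110, times[1:k], dv[1:k])
    ek <- empirical_bayes(sk, pop, n_samples = 500, seed = 6)
    cur <- diag(ek$eta_cov)
    expect_true(all(cur <= prev + 0.02))
    prev <- cur
  }
})

test_that("the population objective is Monte Carlo stable at the optimum", {
  pop <- test_population()
  dat <- small_cohort(n = 8, seed = 31)
  o1 <- evaluate_objective(dat, pop, n_samples = 300, seed = 1)$objective
  o2 <- evaluate_objective(dat, pop, n_samples = 600, seed = 2)$objective
  reps <- vapply(1:8, function(k) {
    evaluate_objective(dat, pop, n_samples = 300, seed = 10 + k)$objective
  }, numeric(1))
  # doubling the sample count moves the objective by less than the
  # replicate-to-replicate Monte Carlo spread
  expect_lt(abs(o1 - o2), 3 * sd(reps) + 0.5)
})

test_that("population containers validate their invariants", {
  expect_error(population_parameters(setNames(rep(-1, 6),
    c("lambda0","d0","p0","x0","lambda_h","lambda_r")),
    rep(1, 6), 0.2), "positive")
  th <- setNames(c(0.2, 0.5, 0.2, 150, 130, 10),
                 c("lambda0","d0","p0","x0","lambda_h","lambda_r"))
  om <- diag(6); om[1, 2] <- om[2, 1] <- 2  # not PSD
  expect_error(population_parameters(th, om, 0.2), "semidefinite")
  expect_error(population_parameters(th, rep(1, 6), -0.1), "sigma2")
  pop <- population_parameters(th, rep(1, 6), 0.2)
  expect_s3_class(pop, "cd4_population")
})
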