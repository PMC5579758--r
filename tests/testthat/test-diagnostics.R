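make_cheap_fit <- function(dat, pop) {
  # a "fit" object at known parameters with EB-style individual estimates,
  # avoiding a full EM run where the test only needs diagnostics machinery
  subs <- as_subject_list(dat)
  est <- lapply(seq_along(subs), function(i) {
    empirical_bayes(subs[[i]], pop, n_samples = 200, seed = 400 + i)
  })
  list(pop = pop, effects = list(), individual = est,
       subject_ids = vapply(subs, `[[`, character(1), "id"))
}

test_that("cwres are standard-normal-like on well-specified data", {
  pop <- test_population()
  spec <- cohort_spec(n_subjects = 120, seed = 201)
  dat <- simulate_cohort(pop, spec = spec)
  fit <- make_cheap_fit(dat, pop)
  cw <- cwres(dat, fit)
  expect_gt(nrow(cw), 700)
  expect_true(all(is.finite(cw$cwres)))
  expect_lt(abs(mean(cw$cwres)), 0.1)
  expect_gt(var(cw$cwres), 0.85)
  expect_lt(var(cw$cwres), 1.15)
  # and independent of time: negligible rank correlation
  expect_lt(abs(cor(cw$TIME_DAYS, cw$cwres, method = "spearman")), 0.1)
})

test_that("cwres vanish for noise-free typical-curve data", {
  pop_sim <- test_population()
  pop_sim$omega <- diag(rep(0, 6))
  pop_sim$sigma2 <- 1e-20        # observations exactly on the typical curve
  spec <- cohort_spec(n_subjects = 4, seed = 202)
  skel <- sample_demographics(spec)
  sched <- sample_schedule(spec)
  dat <- simulate_dataset(pop_sim, skeletons = skel, schedules = sched,
                          seed = 1)
  pop_eval <- pop_sim
  pop_eval$sigma2 <- 0.219       # evaluated under the usual residual model
  fit <- make_cheap_fit(dat, pop_eval)
  cw <- cwres(dat, fit)
  expect_true(all(abs(cw$cwres) < 0.05))
})

test_that("cwres whitening matches a dense per-subject factorisation", {
  pop <- test_population()
  dat <- small_cohort(n = 3, seed = 203)
  fit <- make_cheap_fit(dat, pop)
  cw <- cwres(dat, fit)
  s <- as_subject_list(dat)[[1]]
  i <- match(s$id, fit$subject_ids)
  eta_hat <- fit$individual[[i]]$eta_mean
  # brute-force: numeric Jacobian, dense covariance, explicit inverse sqrt
  base_lp <- log(pop$theta) + eta_hat
  f <- function(lp) {
    log(solve_trajectory(structural_parameters(exp(lp[1]), exp(lp[2]),
                                               exp(lp[3]), exp(lp[4]),
                                               exp(lp[5]), exp(lp[6])),
                         s$age0, grid = s$times)$cd4)
  }
  J <- sapply(1:6, function(k) {
    h <- 1e-4
    lp_p <- base_lp; lp_p[k] <- lp_p[k] + h
    lp_m <- base_lp; lp_m[k] <- lp_m[k] - h
    (f(lp_p) - f(lp_m)) / (2 * h)
  })
  V <- J %*% pop$omega %*% t(J) + diag(pop$sigma2, length(s$times))
  r <- s$log_dv - f(base_lp) + J %*% eta_hat
  w_ref <- backsolve(chol(V), r, transpose = TRUE)
  expect_equal(cw$cwres[cw$SUBJID == s$id], as.numeric(w_ref),
               tolerance = 1e-6)
  expect_equal(as.numeric(crossprod(w_ref)),
               as.numeric(t(r) %*% solve(V) %*% r), tolerance = 1e-6)
})

test_that("vpc is deterministic, ordered, self-consistent and widens with IIV", {
  pop <- test_population()
  spec <- cohort_spec(n_subjects = 40, seed = 204)
  dat <- simulate_cohort(pop, spec = spec)
  fit <- list(pop = pop, effects = list())
  v1 <- vpc(fit, dat, n_replicates = 120, seed = 31)
  v2 <- vpc(fit, dat, n_replicates = 120, seed = 31)
  expect_identical(v1$bins, v2$bins)  # bit-identical under a fixed seed
  b <- v1$bins
  expect_true(all(b$n_obs >= 5))
  expect_true(all(b$sim_p2.5_lo <= b$sim_p2.5_hi))
  expect_true(all(b$sim_median_lo <= b$sim_median_hi))
  expect_true(all(b$sim_p97.5_lo <= b$sim_p97.5_hi))
  # data simulated from the same model: observed medians inside their band
  inside <- b$obs_median >= b$sim_median_lo & b$obs_median <= b$sim_median_hi
  expect_gte(mean(inside), 0.9)
  # inflating the random-effect covariance widens the outer percentile bands
  pop_wide <- pop
  pop_wide$omega <- pop$omega * 4
  v3 <- vpc(list(pop = pop_wide, effects = list()), dat,
            n_replicates = 120, seed = 31)
  expect_true(mean(v3$bins$sim_p97.5_hi >= b$sim_p97.5_hi) >= 0.8)
  expect_true(mean(v3$bins$sim_p2.5_lo <= b$sim_p2.5_lo) >= 0.8)
})
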