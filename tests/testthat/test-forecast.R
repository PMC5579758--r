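test_that("degenerate posterior sampling collapses the band to one curve", {
  pop <- test_population()
  pop$omega <- diag(rep(0, 6))  # posterior covariance forced to zero
  s <- as_subject_list(small_cohort(n = 2, seed = 91))[[1]]
  fc <- forecast(s, pop, cutoff_days = 183, n_samples = 100, seed = 2)
  expect_true(all(abs(fc$upper - fc$lower) / fc$median < 1e-9))
  expect_true(all(abs(fc$median -
                        solve_trajectory(individual_parameters(pop,
                                                               flags = s$flags),
                                         s$age0, grid = fc$time)$cd4) /
                    fc$median < 1e-4))
})

test_that("forecasts ignore post-cutoff data and respect band ordering", {
  pop <- test_population()
  dat <- small_cohort(n = 4, seed = 92)
  subs <- as_subject_list(dat)
  s <- subs[[which.max(vapply(subs, function(x) length(x$times), numeric(1)))]]
  fc_full <- forecast(s, pop, cutoff_days = 183, seed = 5)
  # delete post-cutoff rows: bit-identical forecast
  keep <- s$times <= 183
  s_trunc <- subject_record(s$id, s$age0, s$times[keep], s$dv[keep], s$flags)
  fc_trunc <- forecast(s_trunc, pop, cutoff_days = 183, seed = 5)
  expect_identical(fc_full$median, fc_trunc$median)
  expect_identical(fc_full$lower, fc_trunc$lower)
  expect_true(all(fc_full$lower <= fc_full$median + 1e-12))
  expect_true(all(fc_full$median <= fc_full$upper + 1e-12))
  expect_true(all(fc_full$lower > 0))
})

test_that("a subject with no early data falls back to a prior forecast", {
  pop <- test_population()
  s <- subject_record("late", 1000, times = c(400, 700),
                      cd4 = c(300, 800), flags = c(alemtuzumab = 0,
                                                   fludarabine = 0, gvhd = 0))
  expect_warning(fc <- forecast(s, pop, cutoff_days = 183, n_samples = 200,
                                seed = 3), "prior-only")
  expect_true(attr(fc, "prior_only"))
  # prior forecast has a wide band
  expect_gt(median(fc$upper / fc$lower), 3)
})

test_that("more early observations narrow the band on average", {
  pop <- test_population()
  dat <- small_cohort(n = 12, seed = 93)
  subs <- as_subject_list(dat)
  widths <- vapply(subs, function(s) {
    fc92 <- forecast(s, pop, cutoff_days = 92, n_samples = 200, seed = 6)
    fc365 <- forecast(s, pop, cutoff_days = 365, n_samples = 200, seed = 6)
    n92 <- sum(s$times <= 92)
    n365 <- sum(s$times <= 365)
    if (n365 <= n92) return(NA_real_)  # no extra information gained
    late <- fc92$time > 365
    mean(log(fc92$upper[late] / fc92$lower[late])) -
      mean(log(fc365$upper[late] / fc365$lower[late]))
  }, numeric(1))
  # in expectation the 92-day band is wider than the 365-day band
  expect_gt(mean(widths, na.rm = TRUE), 0)
})

test_that("classification counts band membership and flags the boundary", {
  fake <- structure(data.frame(time = c(0, 100, 200, 300),
                               lower = c(10, 10, 10, 10),
                               median = c(50, 50, 50, 50),
                               upper = c(100, 100, 100, 100)),
                    cutoff_days = 50, class = c("cd4_forecast", "data.frame"))
  held <- data.frame(time = c(110, 150, 250, 290),
                     cd4 = c(50, 60, 99, 150))
  cl <- classify_prediction(fake, held)
  expect_equal(cl$fraction_inside, 0.75)
  # exactly 75% inside is NOT "over 75%": classified poor
  expect_equal(cl$class, "poor")
  held2 <- data.frame(time = c(110, 150, 250, 290), cd4 = c(50, 60, 99, 80))
  cl2 <- classify_prediction(fake, held2)
  expect_equal(cl2$fraction_inside, 1)
  expect_equal(cl2$class, "good")
  # brute-force fraction agrees
  inside <- mapply(function(t, v) {
    v >= approx(fake$time, fake$lower, t)$y &
      v <= approx(fake$time, fake$upper, t)$y
  }, held$time, held$cd4)
  expect_equal(cl$fraction_inside, mean(inside))
  expect_error(classify_prediction(fake, held[0, ]), "undefined")
})
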