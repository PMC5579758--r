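test_that("likelihood-ratio p-values hit the published thresholds exactly", {
  expect_equal(lrt_pvalue(qchisq(0.99, 1), 1), 0.01)
  expect_equal(lrt_pvalue(qchisq(0.995, 1), 1), 0.005)
  expect_equal(lrt_pvalue(6.635, 1), 0.01, tolerance = 1e-3)
  expect_equal(lrt_pvalue(7.879, 1), 0.005, tolerance = 1e-3)
  expect_equal(lrt_pvalue(0, 1), 1)
  expect_equal(lrt_pvalue(0, 3), 1)
  expect_equal(lrt_pvalue(-5, 2), 1)  # negative differences cannot reject
  expect_error(lrt_pvalue(3, 0), "df")
})

test_that("stepwise search respects thresholds and finds a planted effect", {
  # one strong planted effect: alemtuzumab lowering x0 by 80%
  pop <- test_population()
  planted <- covariate_effect("alemtuzumab", "x0", -0.8)
  spec <- cohort_spec(n_subjects = 40, seed = 301,
                      covariate_prevalence = c(alemtuzumab = 0.5, gvhd = 0.3))
  dat <- simulate_cohort(pop, effects = list(planted), spec = spec)
  base <- fit_population(dat, init = pop,
                         settings = fit_settings(max_iter = 8, n_samples = 150,
                                                 final_samples = 300,
                                                 seed = 301,
                                                 update = c("omega", "sigma2")))
  cands <- data.frame(covariate = c("alemtuzumab", "alemtuzumab", "gvhd"),
                      parameter = c("x0", "p0", "x0"),
                      stringsAsFactors = FALSE)
  fsb <- fit_settings(max_iter = 6, n_samples = 120, final_samples = 200,
                      polish = FALSE, seed = 301)
  res <- scm(dat, candidates = cands, base_fit = base,
             fit_settings_base = fsb,
             settings = scm_settings(scan_samples = 200, seed = 301))
  # the planted pair is selected first with a large drop in objective
  first <- res$steps[1, ]
  expect_equal(first$pair, "alemtuzumab:x0")
  expect_equal(first$decision, "included")
  expect_lt(first$p_value, 0.001)
  # the recovered effect is in the neighbourhood of the simulated -0.8
  ef <- Filter(function(e) e$covariate == "alemtuzumab" & e$parameter == "x0",
               res$final_effects)
  expect_equal(length(ef), 1)
  expect_lt(abs(ef[[1]]$effect - (-0.8)), 0.25)
  # every forward inclusion satisfied p < 0.01; backward retentions < 0.005
  fwd <- subset(res$steps, phase == "forward" & decision == "included")
  expect_true(all(fwd$p_value < 0.01))
  bwd <- subset(res$steps, phase == "backward" & decision == "retained")
  expect_true(all(bwd$p_value < 0.005))
  # determinism: identical seeds reproduce the step table
  res2 <- scm(dat, candidates = cands, base_fit = base,
              fit_settings_base = fsb,
              settings = scm_settings(scan_samples = 200, seed = 301))
  expect_identical(res$steps, res2$steps)
})

test_that("a candidate that misses the forward threshold is not included", {
  pop <- test_population()
  spec <- cohort_spec(n_subjects = 16, seed = 302)
  dat <- simulate_cohort(pop, spec = spec)  # no covariate effect simulated
  base <- fit_population(dat, init = pop,
                         settings = fit_settings(max_iter = 4, n_samples = 120,
                                                 final_samples = 200,
                                                 seed = 302,
                                                 update = c("omega", "sigma2")))
  cands <- data.frame(covariate = "gvhd", parameter = "x0",
                      stringsAsFactors = FALSE)
  # an absurdly strict threshold: nothing can qualify, search must stop
  res <- scm(dat, candidates = cands, forward_alpha = 1e-12,
             base_fit = base, settings = scm_settings(scan_samples = 150,
                                                      seed = 302))
  expect_equal(length(res$final_effects), 0)
  expect_equal(res$steps$decision[1], "stopped")
  expect_gte(res$steps$p_value[1], 1e-12)
})
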