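#' Bayesian forecast of an individual's reconstitution trajectory
#'
#' Empirical-Bayes posterior of the subject's random effects is computed from
#' the observations up to \code{cutoff_days} (later observations never
#' influence the result); \code{n_samples} random-effect vectors are then
#' drawn from a multivariate normal with the posterior mean and covariance
#' (log scale), one trajectory is solved per draw, and pointwise 5th/50th/
#' 95th percentiles form the median curve and 90\% band.
#'
#' @param subject a \code{\link{subject_record}}.
#' @param pop fitted \code{\link{population_parameters}}.
#' @param effects list of \code{\link{covariate_effect}}s.
#' @param cutoff_days only observations at or before this time inform the
#'   forecast (default 183 days, i.e. six months).
#' @param n_samples number of sampled parameter sets (default 500).
#' @param horizon_days forecast horizon (default 3 years).
#' @param grid output time grid (default: every 7 days to the horizon).
#' @param seed integer seed.
#' @param eb_samples importance samples for the empirical-Bayes step.
#' @param consts reference constants.
#' @return A \code{cd4_forecast}: data frame with columns \code{time},
#'   \code{lower}, \code{median}, \code{upper} and attributes
#'   \code{cutoff_days}, \code{n_samples}, \code{n_used} (observations at or
#'   before the cutoff), \code{prior_only}, \code{seed}, \code{subject}.
#' @export
forecast <- function(subject, pop, effects = list(), cutoff_days = 183,
                     n_samples = 500, horizon_days = 3 * 365, grid = NULL,
                     seed = 1L, eb_samples = 300,
                     consts = age_reference_constants()) {
  if (is.null(grid)) grid <- seq(0, horizon_days, by = 7)
  keep <- subject$times <= cutoff_days
  used <- subject_record(subject$id, subject$age0, subject$times[keep],
                         subject$dv[keep], subject$flags)
  prior_only <- length(used$times) == 0
  if (prior_only) {
    warning("no observations at or before the cutoff; prior-only forecast")
  }
  eb <- empirical_bayes(used, pop, effects, n_samples = eb_samples,
                        seed = derive_seed(seed, 7L), consts = consts)
  free <- which(diag(pop$omega) > 0)
  lb <- log_base_params(pop, effects, subject$flags)
  eta_draws <- with_seed(derive_seed(seed, 8L), {
    if (length(free)) {
      cov_f <- eb$eta_cov[free, free, drop = FALSE]
      draws <- MASS::mvrnorm(n_samples, eb$eta_mean[free],
                             nearest_psd(cov_f, 0))
      if (is.null(dim(draws))) draws <- matrix(draws, ncol = length(free))
      draws
    } else matrix(0, n_samples, 0)
  })
  lp <- matrix(rep(lb, each = n_samples), n_samples, 6)
  if (length(free)) lp[, free] <- lp[, free] + eta_draws
  xs <- cd4_solve_batch_cpp(lp, subject$age0, grid, consts_vector(consts))
  ok <- apply(xs, 1, function(r) all(is.finite(r)) && all(r > 0))
  if (!any(ok)) stop("all sampled trajectories failed to solve")
  qs <- apply(xs[ok, , drop = FALSE], 2, quantile,
              probs = c(0.05, 0.5, 0.95), names = FALSE)
  structure(data.frame(time = grid, lower = qs[1, ], median = qs[2, ],
                       upper = qs[3, ]),
            cutoff_days = cutoff_days, n_samples = n_samples,
            n_used = length(used$times), prior_only = prior_only,
            seed = seed, subject = subject$id,
            eta_mean = eb$eta_mean, eta_cov = eb$eta_cov,
            class = c("cd4_forecast", "data.frame"))
}

#' Classify a forecast against held-out observations
#'
#' A prediction is \code{"good"} when strictly more than 75\% of the held-out
#' observations fall inside the 90\% band at their times (bands linearly
#' interpolated between grid points).  A qualitative trend flag -- whether the
#' observed change from the cutoff to the last observation has the same sign
#' as the predicted change of the median curve -- is reported alongside but
#' does not alter the classification.
#'
#' @param pred a \code{\link{forecast}} result.
#' @param heldout data frame with columns \code{time} and \code{cd4} (>= 1
#'   row), e.g. the subject's observations after the cutoff.
#' @return List with \code{class} ("good"/"poor"), \code{fraction_inside},
#'   \code{n_heldout} and \code{trend_agrees}.
#' @export
classify_prediction <- function(pred, heldout) {
  if (is.null(heldout) || nrow(heldout) == 0) {
    stop("classification undefined without held-out observations")
  }
  lo <- approx(pred$time, pred$lower, xout = heldout$time, rule = 2)$y
  hi <- approx(pred$time, pred$upper, xout = heldout$time, rule = 2)$y
  inside <- heldout$cd4 >= lo & heldout$cd4 <= hi
  frac <- mean(inside)
  cutoff <- attr(pred, "cutoff_days")
  med_at <- function(t) approx(pred$time, pred$median, xout = t, rule = 2)$y
  t_last <- max(heldout$time)
  pred_change <- med_at(t_last) - med_at(cutoff)
  obs_change <- heldout$cd4[which.max(heldout$time)] - med_at(cutoff)
  list(class = if (frac > 0.75) "good" else "poor",
       fraction_inside = frac, n_heldout = nrow(heldout),
       trend_agrees = sign(pred_change) == sign(obs_change))
}
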