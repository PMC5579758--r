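#' Conditional weighted residuals
#'
#' For each subject the log-scale model is linearised about the conditional
#' (posterior mean) random-effect estimate \eqn{\hat\eta}:
#' \eqn{\log y \approx f(\hat\eta) + F (\eta - \hat\eta) + \epsilon} with
#' \eqn{F} the Jacobian of the log trajectory at the observation times.  The
#' population-level residual \eqn{\log y - f(\hat\eta) + F \hat\eta} has
#' approximate covariance \eqn{V = F \Omega F' + \sigma^2 I} and is whitened
#' by the Cholesky factor of \eqn{V}.  Under the true model the residuals are
#' approximately standard normal and independent of time.
#'
#' @param dataset a \code{\link{cd4_dataset}}.
#' @param fit a \code{\link{fit_population}} result (its stored per-subject
#'   posterior means are used; subjects are matched by id).
#' @param consts reference constants.
#' @param ridge relative ridge added to a numerically singular \eqn{V}.
#' @return Data frame with columns \code{SUBJID}, \code{TIME_DAYS},
#'   \code{CD4}, \code{cwres}.
#' @export
cwres <- function(dataset, fit, consts = age_reference_constants(),
                  ridge = 1e-8) {
  subjects <- as_subject_list(dataset)
  pop <- fit$pop
  free <- which(diag(pop$omega) > 0)
  cv <- consts_vector(consts)
  out <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    n <- length(s$times)
    if (n == 0) return(NULL)
    j <- match(s$id, fit$subject_ids)
    eta_hat <- if (!is.na(j)) fit$individual[[j]]$eta_mean else rep(0, 6)
    lb <- log_base_params(pop, fit$effects, s$flags)
    base_lp <- lb + eta_hat
    f0 <- log(cd4_solve_cpp(s$times, c(exp(base_lp), 1, 1), s$age0, cv))
    h <- 1e-4
    Fm <- matrix(0, n, length(free))
    for (k in seq_along(free)) {
      lp_p <- base_lp; lp_p[free[k]] <- lp_p[free[k]] + h
      lp_m <- base_lp; lp_m[free[k]] <- lp_m[free[k]] - h
      fp <- log(cd4_solve_cpp(s$times, c(exp(lp_p), 1, 1), s$age0, cv))
      fm <- log(cd4_solve_cpp(s$times, c(exp(lp_m), 1, 1), s$age0, cv))
      Fm[, k] <- (fp - fm) / (2 * h)
    }
    V <- Fm %*% pop$omega[free, free, drop = FALSE] %*% t(Fm) +
      diag(pop$sigma2, n)
    R <- tryCatch(chol(V), error = function(e) {
      chol(V + diag(ridge * mean(diag(V)), n))
    })
    r <- s$log_dv - f0 + Fm %*% eta_hat[free]
    w <- backsolve(R, r, transpose = TRUE)
    data.frame(SUBJID = rep(s$id, n), TIME_DAYS = s$times, CD4 = s$dv,
               cwres = as.numeric(w), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Visual predictive check
#'
#' Simulates \code{n_replicates} datasets from the model at the observed
#' design (same subjects, ages, covariates and sampling times), then compares
#' the observed median and 2.5/97.5 percentiles per time bin with the 95\%
#' range of the same statistics across replicates.  Bins are quantile-spaced
#' in time; bins with fewer than 5 observations are merged with their
#' neighbour.
#'
#' @param fit a \code{\link{fit_population}} result (or a list with elements
#'   \code{pop} and \code{effects}).
#' @param dataset the observed \code{\link{cd4_dataset}} serving as design
#'   template.
#' @param n_replicates simulated datasets (default 600).
#' @param n_bins target number of quantile-spaced time bins (default 8).
#' @param seed integer seed; results are bit-identical for a fixed seed.
#' @param include_parameter_uncertainty also draw the typical values for each
#'   replicate from the bootstrap covariance (requires \code{theta_cov}).
#' @param theta_cov covariance matrix of log typical values, used only when
#'   \code{include_parameter_uncertainty = TRUE}.
#' @param consts reference constants.
#' @return A \code{cd4_vpc}: list with \code{bins} (data frame: bin edges and
#'   observed/simulated statistics), \code{n_replicates}, \code{seed},
#'   \code{merged_bins}.
#' @export
vpc <- function(fit, dataset, n_replicates = 600, n_bins = 8, seed = 1L,
                include_parameter_uncertainty = FALSE, theta_cov = NULL,
                consts = age_reference_constants()) {
  pop <- fit$pop
  effects <- fit$effects
  subjects <- as_subject_list(dataset)
  cv <- consts_vector(consts)
  times_all <- dataset$TIME_DAYS
  # quantile binning with small-bin merging
  edges <- unique(quantile(times_all, probs = seq(0, 1, length.out =
                                                    n_bins + 1)))
  bin_of <- function(t) pmin(pmax(findInterval(t, edges,
                                               rightmost.closed = TRUE), 1),
                             length(edges) - 1)
  b <- bin_of(times_all)
  merged <- 0L
  repeat {
    counts <- tabulate(b, nbins = length(edges) - 1)
    small <- which(counts > 0 & counts < 5)
    if (!length(small) || length(edges) <= 2) break
    k <- small[1]
    drop_edge <- if (k == 1) 2 else k
    edges <- edges[-drop_edge]
    merged <- merged + 1L
    b <- bin_of(times_all)
  }
  nb <- length(edges) - 1
  stat3 <- function(x) {
    c(lo = unname(quantile(x, 0.025)), med = median(x),
      hi = unname(quantile(x, 0.975)))
  }
  obs_stats <- t(vapply(seq_len(nb), function(k) {
    stat3(dataset$CD4[b == k])
  }, numeric(3)))
  # per-subject true solution is deterministic; simulate eta + residual noise
  sim_stats <- array(NA_real_, c(n_replicates, nb, 3))
  with_seed(derive_seed(seed, 11L), {
    for (r in seq_len(n_replicates)) {
      sim_dv <- unlist(lapply(subjects, function(s) {
        n <- length(s$times)
        if (n == 0) return(numeric(0))
        lb <- log_base_params(pop, effects, s$flags)
        if (include_parameter_uncertainty && !is.null(theta_cov)) {
          lb <- lb + MASS::mvrnorm(1, rep(0, 6), theta_cov)
        }
        eta <- MASS::mvrnorm(1, rep(0, 6), pop$omega)
        x <- cd4_solve_cpp(s$times, c(exp(lb + eta), 1, 1), s$age0, cv)
        if (any(!is.finite(x)) || any(x <= 0)) return(rep(NA_real_, n))
        exp(log(x) + rnorm(n, 0, sqrt(pop$sigma2)))
      }))
      for (k in seq_len(nb)) {
        v <- sim_dv[b == k]
        v <- v[is.finite(v)]
        if (length(v)) sim_stats[r, k, ] <- stat3(v)
      }
    }
  })
  band <- function(stat_idx) {
    t(vapply(seq_len(nb), function(k) {
      unname(quantile(sim_stats[, k, stat_idx], c(0.025, 0.975),
                      na.rm = TRUE))
    }, numeric(2)))
  }
  bl <- band(1); bm <- band(2); bh <- band(3)
  bins <- data.frame(
    t_lo = edges[-length(edges)], t_hi = edges[-1],
    n_obs = tabulate(b, nbins = nb),
    obs_p2.5 = obs_stats[, 1], obs_median = obs_stats[, 2],
    obs_p97.5 = obs_stats[, 3],
    sim_p2.5_lo = bl[, 1], sim_p2.5_hi = bl[, 2],
    sim_median_lo = bm[, 1], sim_median_hi = bm[, 2],
    sim_p97.5_lo = bh[, 1], sim_p97.5_hi = bh[, 2])
  structure(list(bins = bins, n_replicates = n_replicates, seed = seed,
                 merged_bins = merged),
            class = "cd4_vpc")
}

#' @export
print.cd4_vpc <- function(x, ...) {
  cat(sprintf("Visual predictive check (%d replicates, %d bins%s)\n",
              x$n_replicates, nrow(x$bins),
              if (x$merged_bins) sprintf(", %d merged", x$merged_bins)
              else ""))
  print(signif(x$bins, 4), row.names = FALSE)
  invisible(x)
}
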