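param_names <- function() c("lambda0", "d0", "p0", "x0", "lambda_h", "lambda_r")

#' Population-level model parameters
#'
#' Typical values \eqn{\theta} on the natural scale for the six structural
#' parameters, a full 6x6 covariance matrix \eqn{\Omega} of the log-scale
#' random effects, and the residual variance \eqn{\sigma^2} on the
#' log-concentration scale.  All parameters are lognormally distributed across
#' subjects: an individual's parameter is
#' \eqn{\theta_j \prod (1+\theta_{cov}) e^{\eta_j}}.
#'
#' @param theta named positive vector (lambda0, d0, p0, x0, lambda_h,
#'   lambda_r).
#' @param omega 6x6 symmetric positive-semidefinite covariance matrix (a
#'   vector of length 6 is taken as a diagonal).
#' @param sigma2 residual variance of log CD4 (> 0).
#' @return A \code{cd4_population} (list).
#' @export
population_parameters <- function(theta, omega, sigma2) {
  theta <- theta[param_names()]
  if (any(is.na(theta)) || any(theta <= 0)) {
    stop("theta must contain positive values for all six parameters")
  }
  if (is.vector(omega) && is.null(dim(omega))) omega <- diag(omega)
  omega <- as.matrix(omega)
  if (!isTRUE(all.equal(omega, t(omega), tolerance = 1e-8)) ||
      nrow(omega) != 6) {
    stop("omega must be a symmetric 6x6 matrix")
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("omega must be positive semidefinite")
  }
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  dimnames(omega) <- list(param_names(), param_names())
  structure(list(theta = theta, omega = omega, sigma2 = sigma2),
            class = "cd4_population")
}

#' Published population parameter defaults
#'
#' Typical values from \code{\link{typical_parameters}} with the published
#' random-effect variances (1.57, 1.62, 0.251, 1.31, 1.27, 1.22 on the
#' diagonal; off-diagonals zero, since only the variances are published) and
#' residual variance 0.219.
#'
#' @return A \code{cd4_population}.
#' @export
default_population_parameters <- function() {
  population_parameters(
    theta = setNames(as.numeric(typical_parameters())[1:6], param_names()),
    omega = c(1.57, 1.62, 0.251, 1.31, 1.27, 1.22),
    sigma2 = 0.219)
}

#' @export
print.cd4_population <- function(x, ...) {
  cat("CD4 reconstitution population parameters\n  theta:\n")
  print(signif(x$theta, 4))
  cat("  omega diagonal:", paste(signif(diag(x$omega), 3), collapse = ", "),
      "\n  sigma2:", signif(x$sigma2, 4), "\n")
  invisible(x)
}

#' Multiplicative covariate effect on a structural parameter
#'
#' A dichotomous covariate scales the typical value of one parameter by
#' \eqn{(1 + \theta_{cov})} when the flag is set.
#'
#' @param covariate covariate (flag) name.
#' @param parameter one of the six structural parameter names.
#' @param effect proportional change \eqn{\theta_{cov}} (> -1).
#' @return A \code{cd4_effect} (list).
#' @export
covariate_effect <- function(covariate, parameter, effect) {
  if (!parameter %in% param_names()) {
    stop("unknown parameter name: ", parameter)
  }
  if (!is.finite(effect) || 1 + effect <= 0) {
    stop("effect must satisfy 1 + effect > 0")
  }
  structure(list(covariate = covariate, parameter = parameter,
                 effect = effect), class = "cd4_effect")
}

# log of the covariate-adjusted typical values for one subject's flags
log_base_params <- function(pop, effects, flags) {
  lb <- log(pop$theta)
  for (ef in effects) {
    if (!ef$covariate %in% names(flags)) {
      stop("subject lacks covariate flag: ", ef$covariate)
    }
    if (flags[[ef$covariate]] == 1) {
      lb[ef$parameter] <- lb[ef$parameter] + log1p(ef$effect)
    }
  }
  lb
}

#' Assemble an individual's structural parameters
#'
#' \eqn{p_j = \theta_j \prod_{\mathrm{active}} (1+\theta_{cov}) e^{\eta_j}},
#' with the competition strengths cp = cd = 1 appended.  Covariate effects
#' enter the typical value before the random effect, so two effects on the
#' same parameter compose multiplicatively and order-independently.
#'
#' @param pop a \code{\link{population_parameters}} object (or a named theta
#'   vector).
#' @param effects list of \code{\link{covariate_effect}}s.
#' @param flags named 0/1 covariate vector for the subject.
#' @param eta log-scale random-effect vector (length 6; default zero).
#' @return A \code{\link{structural_parameters}} object.
#' @export
individual_parameters <- function(pop, effects = list(), flags = numeric(),
                                  eta = rep(0, 6)) {
  if (is.numeric(pop)) pop <- list(theta = pop[param_names()])
  lb <- log_base_params(pop, effects, flags)
  p <- exp(lb + eta)
  structural_parameters(p[["lambda0"]], p[["d0"]], p[["p0"]], p[["x0"]],
                        p[["lambda_h"]], p[["lambda_r"]])
}

#' Log likelihood of a subject's observations given fixed parameters
#'
#' Log CD4 observations are modelled as normal around the log of the solved
#' trajectory with variance \code{sigma2} (log-additive residual error).
#'
#' @param subject a \code{\link{subject_record}}.
#' @param params a \code{\link{structural_parameters}} object.
#' @param sigma2 residual variance (log scale).
#' @param consts reference constants.
#' @return Sum of normal log densities over the subject's observations.
#' @export
observation_loglik <- function(subject, params, sigma2,
                               consts = age_reference_constants()) {
  if (length(subject$times) == 0) return(0)
  lp <- matrix(log(as.numeric(params)[1:6]), nrow = 1)
  cd4_loglik_cpp(lp, subject$age0, subject$times, subject$log_dv, sigma2,
                 consts_vector(consts), params[["cp"]], params[["cd"]])[1]
}

## ---- multivariate normal / t helpers (log densities) ----

log_dmvnorm <- function(x, mean, chol_upper) {
  q <- length(mean)
  z <- backsolve(chol_upper, x - mean, transpose = TRUE)
  -0.5 * q * log(2 * pi) - sum(log(diag(chol_upper))) - 0.5 * sum(z^2)
}

log_dmvt_rows <- function(x, mean, chol_upper, df) {
  # x: matrix with samples in rows
  q <- ncol(x)
  z <- backsolve(chol_upper, t(x) - mean, transpose = TRUE)
  mahal <- colSums(z^2)
  lgamma((df + q) / 2) - lgamma(df / 2) - 0.5 * q * log(df * pi) -
    sum(log(diag(chol_upper))) - 0.5 * (df + q) * log1p(mahal / df)
}

rmvt_rows <- function(n, mean, chol_upper, df) {
  q <- length(mean)
  z <- matrix(rnorm(n * q), n, q) %*% chol_upper
  u <- sqrt(df / stats::rchisq(n, df))
  sweep(z * u, 2, mean, `+`)
}

# negative log posterior machinery for one subject's free random effects
subject_negpost <- function(subject, pop, effects, free, consts) {
  q <- length(free)
  lb <- log_base_params(pop, effects, subject$flags)
  cv <- consts_vector(consts)
  omega_f <- pop$omega[free, free, drop = FALSE]
  chol_om <- chol(nearest_psd(omega_f, 1e-12))
  loglik_eta <- function(eta_mat) {
    # eta_mat: rows are free-component vectors
    lp <- matrix(rep(lb, each = nrow(eta_mat)), nrow(eta_mat), 6)
    lp[, free] <- lp[, free] + eta_mat
    cd4_loglik_cpp(lp, subject$age0, subject$times, subject$log_dv,
                   pop$sigma2, cv)
  }
  neg_post <- function(eta) {
    v <- -loglik_eta(matrix(eta, 1)) - log_dmvnorm(eta, rep(0, q), chol_om)
    # infeasible draws (failed trajectories) get a large finite penalty with
    # a gradient back towards the feasible region
    if (!is.finite(v)) v <- 1e8 * (1 + sum(eta^2))
    v
  }
  list(loglik_eta = loglik_eta, neg_post = neg_post, omega_f = omega_f,
       chol_om = chol_om, q = q)
}

find_posterior_mode <- function(neg_post, start, mode_maxit, q) {
  start <- if (is.null(start)) rep(0, q) else start
  if (neg_post(start) >= 1e7 && any(start != 0)) start <- rep(0, q)
  if (mode_maxit >= 50) {
    # fresh start: derivative-free search first, then gradient polish
    o1 <- optim(start, neg_post, method = "Nelder-Mead",
                control = list(maxit = 500))
    tryCatch(optim(o1$par, neg_post, method = "BFGS",
                   control = list(maxit = 25, reltol = 1e-8)),
             error = function(e) o1)
  } else {
    tryCatch(optim(start, neg_post, method = "BFGS",
                   control = list(maxit = mode_maxit, reltol = 1e-8)),
             error = function(e) {
               optim(start, neg_post, method = "Nelder-Mead",
                     control = list(maxit = 300))
             })
  }
}

# central-difference Hessian of the negative log posterior at the mode
curvature_at <- function(neg_post, mode, f0 = neg_post(mode)) {
  q <- length(mode)
  h <- 1e-4 * (1 + abs(mode))
  H <- matrix(0, q, q)
  fp <- numeric(q); fm <- numeric(q)
  for (j in seq_len(q)) {
    ej <- rep(0, q); ej[j] <- h[j]
    fp[j] <- neg_post(mode + ej); fm[j] <- neg_post(mode - ej)
    H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h[j]^2
  }
  if (q > 1) {
    for (j in 1:(q - 1)) for (k in (j + 1):q) {
      ej <- rep(0, q); ej[j] <- h[j]
      ek <- rep(0, q); ek[k] <- h[k]
      fpp <- neg_post(mode + ej + ek)
      fmm <- neg_post(mode - ej - ek)
      H[j, k] <- H[k, j] <-
        (fpp - fp[j] - fp[k] + 2 * f0 - fm[j] - fm[k] + fmm) /
        (2 * h[j] * h[k])
    }
  }
  (H + t(H)) / 2
}

#' Laplace approximation of a subject's marginal -2 log likelihood
#'
#' Deterministic alternative to \code{\link{marginal_neg2ll_is}}: the
#' marginal likelihood is approximated from the posterior mode and the
#' curvature there, \eqn{-2\log L \approx 2 g(\hat\eta) - q \log(2\pi) +
#' \log\det H}, with \eqn{g} the negative log posterior.  Used where a
#' smooth, noise-free objective matters (typical-value refinement); the
#' importance-sampling estimator remains the reference elsewhere.
#'
#' @inheritParams marginal_neg2ll_is
#' @return List with \code{objective} and \code{mode}.
#' @export
marginal_neg2ll_laplace <- function(subject, pop, effects = list(),
                                    consts = age_reference_constants(),
                                    mode_start = NULL, mode_maxit = 100) {
  free <- which(diag(pop$omega) > 0)
  q <- length(free)
  if (length(subject$times) == 0 || q == 0) {
    ll0 <- if (length(subject$times) == 0) 0 else {
      observation_loglik(subject,
                         individual_parameters(pop, effects, subject$flags),
                         pop$sigma2, consts)
    }
    return(list(objective = -2 * ll0, mode = rep(0, q)))
  }
  np <- subject_negpost(subject, pop, effects, free, consts)
  opt <- find_posterior_mode(np$neg_post, mode_start, mode_maxit, q)
  if (opt$value >= 1e7) {
    return(list(objective = 1e8, mode = rep(0, q)))
  }
  H <- curvature_at(np$neg_post, opt$par, opt$value)
  ev <- pmax(eigen(H, symmetric = TRUE, only.values = TRUE)$values, 1e-6)
  list(objective = 2 * opt$value - q * log(2 * pi) + sum(log(ev)),
       mode = opt$par)
}

# symmetric PSD projection (eigenvalue clipping)
nearest_psd <- function(m, floor = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' Importance-sampling estimate of a subject's marginal -2 log likelihood
#'
#' Estimates \eqn{-2 \log \int p(y \mid \eta)\, N(\eta; 0, \Omega)\, d\eta}
#' by importance sampling with a heavy-tailed (multivariate t, df 3) proposal
#' centred at the posterior mode with spread from the mode's curvature, and
#' returns the self-normalised posterior mean and covariance of \eqn{\eta}.
#' Random effects whose \eqn{\Omega} diagonal is zero are held at zero.
#'
#' @param subject a \code{\link{subject_record}}.
#' @param pop a \code{\link{population_parameters}} object.
#' @param effects list of \code{\link{covariate_effect}}s.
#' @param n_samples number of importance samples (>= 100 recommended).
#' @param seed integer seed (reproducible result).
#' @param consts reference constants.
#' @param df degrees of freedom of the t proposal.
#' @param mode_start optional warm start for the posterior mode (free
#'   components).
#' @param proposal_cov optional proposal covariance (free components); when
#'   supplied the curvature computation is skipped.
#' @param mode_maxit iteration cap for the mode search.
#' @return List with \code{objective} (-2 log marginal likelihood),
#'   \code{eta_mean}, \code{eta_cov} (6-vector / 6x6, fixed components zero),
#'   \code{wssr} (posterior-weighted sum of squared log residuals),
#'   \code{n_obs}, \code{ess} (effective sample size), \code{mode},
#'   \code{fallback} (TRUE when the curvature was degenerate and the prior
#'   covariance was used as proposal spread) and \code{seed}.
#' @export
marginal_neg2ll_is <- function(subject, pop, effects = list(),
                               n_samples = 300, seed = 1L,
                               consts = age_reference_constants(),
                               df = 3, mode_start = NULL,
                               proposal_cov = NULL, mode_maxit = 100) {
  free <- which(diag(pop$omega) > 0)
  q <- length(free)
  n_obs <- length(subject$times)
  if (n_obs == 0 || q == 0) {
    ll0 <- if (n_obs == 0) 0 else {
      observation_loglik(subject,
                         individual_parameters(pop, effects, subject$flags),
                         pop$sigma2, consts)
    }
    return(list(objective = -2 * ll0, eta_mean = rep(0, 6),
                eta_cov = pop$omega * 0, wssr = NA_real_, n_obs = n_obs,
                ess = NA_real_, mode = rep(0, q), fallback = FALSE,
                seed = seed))
  }
  np <- subject_negpost(subject, pop, effects, free, consts)
  opt <- find_posterior_mode(np$neg_post, mode_start, mode_maxit, q)
  mode <- opt$par
  fallback <- FALSE
  if (opt$value >= 1e7) {
    # no feasible mode found: centre a wide proposal on the prior
    mode <- rep(0, q)
    proposal_cov <- np$omega_f
    fallback <- TRUE
  }
  if (is.null(proposal_cov)) {
    H <- curvature_at(np$neg_post, mode, opt$value)
    pc <- tryCatch({
      ev <- eigen(H, symmetric = TRUE)
      if (min(ev$values) <= 1e-8) stop("degenerate curvature")
      ev$vectors %*% ((1 / ev$values) * t(ev$vectors))
    }, error = function(e) NULL)
    if (is.null(pc)) {
      pc <- np$omega_f
      fallback <- TRUE
    }
    proposal_cov <- pc
  }
  loglik_eta <- np$loglik_eta
  chol_om <- np$chol_om
  chol_prop <- chol(nearest_psd(proposal_cov, 1e-12))
  with_seed(seed, {
    for (attempt in 1:2) {
      eta_s <- rmvt_rows(n_samples, mode, chol_prop, df)
      ll <- loglik_eta(eta_s)
      lp_prior <- apply(eta_s, 1, log_dmvnorm, mean = rep(0, q),
                        chol_upper = chol_om)
      lq <- log_dmvt_rows(eta_s, mode, chol_prop, df)
      lw <- ll + lp_prior - lq
      lw[!is.finite(lw)] <- -Inf
      m <- max(lw)
      if (is.finite(m)) break
      # retry once from the prior before giving up
      mode <- rep(0, q)
      chol_prop <- chol_om
      fallback <- TRUE
    }
    if (!is.finite(m)) {
      stop("importance sampling failed: all weights zero for subject ",
           subject$id)
    }
    log_marg <- m + log(mean(exp(lw - m)))
    w <- exp(lw - m); w <- w / sum(w)
    post_mean_f <- colSums(w * eta_s)
    centred <- sweep(eta_s, 2, post_mean_f)
    post_cov_f <- t(centred) %*% (w * centred)
    sumw2 <- sum(w^2)
    # posterior-weighted residual sum of squares (for the sigma2 update):
    # ll = -n/2 log(2 pi s2) - ssr/(2 s2)  =>  ssr = -2 s2 (ll + n/2 log(...))
    ssr <- -2 * pop$sigma2 *
      (ll + n_obs / 2 * log(2 * pi * pop$sigma2))
    ssr[w == 0 | !is.finite(ssr)] <- 0
    wssr <- sum(w * ssr)
    eta_mean <- rep(0, 6); eta_mean[free] <- post_mean_f
    eta_cov <- matrix(0, 6, 6)
    eta_cov[free, free] <- nearest_psd(post_cov_f, 0)
    list(objective = -2 * log_marg, eta_mean = eta_mean, eta_cov = eta_cov,
         wssr = wssr, n_obs = n_obs, ess = 1 / sumw2,
         mode = mode, proposal_cov = proposal_cov, fallback = fallback,
         seed = seed)
  })
}

#' Empirical-Bayes estimate of a subject's random effects
#'
#' Expectation-only importance sampling: the posterior mean and covariance of
#' \eqn{\eta} given the subject's observations, with the population
#' parameters held fixed.  A subject with no observations returns the prior.
#'
#' @inheritParams marginal_neg2ll_is
#' @return As \code{\link{marginal_neg2ll_is}}; for a subject without
#'   observations \code{eta_mean} is zero and \code{eta_cov} is \eqn{\Omega}.
#' @export
empirical_bayes <- function(subject, pop, effects = list(), n_samples = 300,
                            seed = 1L, consts = age_reference_constants(),
                            df = 3) {
  if (length(subject$times) == 0) {
    return(list(objective = 0, eta_mean = rep(0, 6), eta_cov = pop$omega,
                wssr = NA_real_, n_obs = 0, ess = NA_real_,
                fallback = FALSE, seed = seed))
  }
  marginal_neg2ll_is(subject, pop, effects, n_samples, seed, consts, df)
}

#' Estimation settings for the population fit
#'
#' @param n_samples importance samples per subject per E-step.
#' @param max_iter maximum EM iterations.
#' @param obj_tol,obj_consec convergence: the objective trace is declared
#'   converged when the least-squares slope through the last
#'   \code{obj_consec + 1} iterations is shallower than \code{obj_tol} per
#'   iteration (importance samples are redrawn each iteration, so the trace
#'   carries Monte Carlo noise; a slope criterion on several iterations is
#'   robust to it).
#' @param seed base seed; per-subject, per-iteration seeds are derived
#'   deterministically.
#' @param df proposal degrees of freedom.
#' @param mode_maxit BFGS iteration cap for the per-subject mode search after
#'   the first iteration (warm starts make a small cap sufficient).
#' @param min_iter iterations before convergence may be declared.
#' @param update character subset of \code{c("theta", "omega", "sigma2")} to
#'   update in the M-step.
#' @param resample draw fresh importance samples every iteration (default).
#'   With \code{FALSE} the per-subject seeds are fixed across iterations;
#'   the trace is then smoother but the fit can adapt to the fixed Monte
#'   Carlo noise, so this is only appropriate for short refinement runs.
#' @param hessian_refresh recompute the per-subject proposal curvature every
#'   this many iterations (stale proposal covariances keep the importance
#'   weights valid, only their efficiency decays).
#' @param accel_every apply an Aitken extrapolation to the log typical values
#'   every this many iterations (EM steps along weakly identified directions
#'   decay geometrically; extrapolating the series cuts the iteration count).
#' @param param_tol convergence also requires the window-averaged absolute
#'   change in log typical values to drop below this.
#' @param polish after the EM stage, refine the typical values, covariate
#'   coefficients and \eqn{\sigma^2} by quasi-Newton maximisation of a
#'   sample-reuse importance-sampling likelihood (per-subject draws taken
#'   once in absolute parameter space and reweighted analytically), then
#'   re-update \eqn{\Omega} and \eqn{\sigma^2} by a few EM iterations.  EM
#'   steps along compensation ridges (for example thymic input against loss)
#'   contract very slowly; the direct search traverses them.
#' @param polish_maxit BFGS iteration cap per polish cycle.
#' @param polish_em_iter EM iterations of the post-polish
#'   \eqn{\Omega}/\eqn{\sigma^2} re-update.
#' @param polish_cycles number of draw-optimise-reupdate cycles.
#' @param polish_draws reusable draws per subject per cycle.
#' @param average_last report the average of the parameter estimates over
#'   this many final iterations (reduces Monte Carlo jitter; 1 = last
#'   iterate).
#' @param final_samples importance samples for the final reported objective
#'   (an independent evaluation pass at the reported estimates; 0 skips the
#'   pass and reports the last trace value).
#' @return List of settings.
#' @export
fit_settings <- function(n_samples = 200, max_iter = 60, obj_tol = 0.5,
                         obj_consec = 9, seed = 1L, df = 3,
                         mode_maxit = 15, min_iter = 20,
                         update = c("theta", "omega", "sigma2"),
                         resample = TRUE, average_last = 5,
                         final_samples = 600, hessian_refresh = 10,
                         accel_every = 5, param_tol = 0.005,
                         polish = TRUE, polish_maxit = 120,
                         polish_em_iter = 8, polish_cycles = 3,
                         polish_draws = 1500) {
  list(n_samples = n_samples, max_iter = max_iter, obj_tol = obj_tol,
       obj_consec = obj_consec, seed = as.integer(seed), df = df,
       mode_maxit = mode_maxit, min_iter = min_iter, update = update,
       resample = resample, average_last = average_last,
       final_samples = final_samples, hessian_refresh = hessian_refresh,
       accel_every = accel_every, param_tol = param_tol, polish = polish,
       polish_maxit = polish_maxit, polish_em_iter = polish_em_iter,
       polish_cycles = polish_cycles, polish_draws = polish_draws)
}

# parameters targeted by at least one effect, with their design columns
effect_design <- function(effects, subjects) {
  lapply(param_names(), function(pn) {
    idx <- which(vapply(effects, function(e) e$parameter == pn, logical(1)))
    if (!length(idx)) return(NULL)
    X <- vapply(idx, function(i) {
      vapply(subjects, function(s) s$flags[[effects[[i]]$covariate]],
             numeric(1))
    }, numeric(length(subjects)))
    list(idx = idx, X = as.matrix(X))
  })
}

# One cycle of typical-value refinement by sample-reuse importance sampling.
#
# Per subject, draws are taken ONCE in absolute log-parameter space (heavy
# tailed t around the current posterior, widened so that typical-value moves
# of about half a log unit stay covered) and the expensive data likelihood
# (ODE solves) is computed once per draw.  Changing the typical values, the
# covariate coefficients or sigma2 only changes the random-effect prior
# density and the residual normalising terms, both analytic, so the marginal
# -2 log likelihood can be re-evaluated for any candidate in milliseconds
# and is a smooth deterministic function of the candidate.  A quasi-Newton
# search then moves along ridge directions that EM steps cannot traverse.
polish_typicals <- function(subjects, pop, effs, est, settings, consts,
                            cycle = 1) {
  n <- length(subjects)
  free <- which(diag(pop$omega) > 0)
  q <- length(free)
  n_eff <- length(effs)
  if (q == 0) return(list(pop = pop, effects = effs))
  K <- settings$polish_draws
  cv <- consts_vector(consts)
  chol_om <- chol(nearest_psd(pop$omega[free, free, drop = FALSE], 1e-12))
  draws <- vector("list", n)
  with_seed(derive_seed(settings$seed, 88000L + cycle), {
    for (i in seq_len(n)) {
      s <- subjects[[i]]
      if (length(s$times) == 0) next
      centre <- est[[i]]$eta_mean[free]
      sc <- est[[i]]$eta_cov[free, free, drop = FALSE] + diag(0.16, q)
      chol_prop <- chol(nearest_psd(sc, 1e-10))
      eta_s <- rmvt_rows(K, centre, chol_prop, 4)
      lq <- log_dmvt_rows(eta_s, centre, chol_prop, 4)
      lb <- log_base_params(pop, effs, s$flags)
      lp <- matrix(rep(lb, each = K), K, 6)
      lp[, free] <- lp[, free] + eta_s
      ll <- cd4_loglik_cpp(lp, s$age0, s$times, s$log_dv, pop$sigma2, cv)
      # recover the residual sum of squares so sigma2 stays analytic
      n_i <- length(s$times)
      ssr <- -2 * pop$sigma2 * (ll + n_i / 2 * log(2 * pi * pop$sigma2))
      ssr[!is.finite(ssr)] <- Inf
      draws[[i]] <- list(psi = lp[, free, drop = FALSE], lq = lq,
                         ssr = ssr, n_i = n_i, flags = s$flags)
    }
  })
  pol_obj <- function(v) {
    ltheta <- v[1:6]
    phis <- if (n_eff) v[6 + seq_len(n_eff)] else numeric(0)
    s2 <- exp(v[7 + n_eff])
    effs2 <- effs
    if (n_eff) for (k in seq_len(n_eff)) effs2[[k]]$effect <- expm1(phis[k])
    pop2 <- list(theta = setNames(exp(ltheta), param_names()))
    tot <- 0
    for (i in seq_len(n)) {
      d <- draws[[i]]
      if (is.null(d)) next
      lb2 <- log_base_params(pop2, effs2, d$flags)[free]
      z <- backsolve(chol_om, t(d$psi) - lb2, transpose = TRUE)
      lprior <- -0.5 * q * log(2 * pi) - sum(log(diag(chol_om))) -
        0.5 * colSums(z^2)
      lw <- -d$n_i / 2 * log(2 * pi * s2) - d$ssr / (2 * s2) +
        lprior - d$lq
      m <- max(lw)
      if (!is.finite(m)) return(1e10)
      tot <- tot - 2 * (m + log(mean(exp(lw - m))))
    }
    if (!is.finite(tot)) 1e10 else tot
  }
  v0 <- c(log(pop$theta),
          vapply(effs, function(e) log1p(e$effect), numeric(1)),
          log(pop$sigma2))
  po <- tryCatch(
    optim(v0, pol_obj, method = "BFGS",
          control = list(maxit = settings$polish_maxit, reltol = 1e-10)),
    error = function(e) optim(v0, pol_obj, method = "Nelder-Mead",
                              control = list(maxit = 500)))
  # trust region: sample reuse is only reliable while the proposals cover
  # the moved posteriors, so cap each component's move per cycle
  dv <- pmin(pmax(po$par - v0, -0.7), 0.7)
  v1 <- v0 + dv
  pop$theta <- setNames(exp(v1[1:6]), param_names())
  if (n_eff) {
    for (k in seq_len(n_eff)) effs[[k]]$effect <- expm1(v1[6 + k])
  }
  if ("sigma2" %in% settings$update) pop$sigma2 <- exp(v1[7 + n_eff])
  list(pop = pop, effects = effs)
}

#' Fit the population model by importance-sampling EM
#'
#' E-step: per-subject posterior moments of the log-scale random effects by
#' importance sampling (t proposal at the posterior mode; modes and proposal
#' covariances are warm-started across iterations; per-subject seeds are held
#' fixed so the objective trace is comparable across iterations).  M-step:
#' typical values (and covariate coefficients, on the log scale) from the
#' conditional means by least squares; \eqn{\Omega} from conditional second
#' moments (PSD-projected if needed); \eqn{\sigma^2} from the conditional
#' mean squared log residual.  Stops when the objective changes by less than
#' \code{obj_tol} for \code{obj_consec} consecutive iterations, or at
#' \code{max_iter}.
#'
#' @param dataset a \code{\link{cd4_dataset}} (>= 2 subjects).
#' @param init initial \code{\link{population_parameters}}.
#' @param effects list of \code{\link{covariate_effect}}s to estimate
#'   (their values are the initial estimates).
#' @param settings a \code{\link{fit_settings}} list.
#' @param consts reference constants.
#' @return A \code{cd4_fit}: list with \code{pop} (estimates),
#'   \code{effects}, \code{objective}, \code{trace}, \code{converged},
#'   \code{individual} (per-subject posterior summaries), \code{n_subjects},
#'   \code{seed} and \code{settings}.
#' @export
fit_population <- function(dataset, init = default_population_parameters(),
                           effects = list(), settings = fit_settings(),
                           consts = age_reference_constants()) {
  subjects <- as_subject_list(dataset)
  n <- length(subjects)
  if (n < 2) stop("at least 2 subjects are required")
  pop <- init
  effs <- effects
  modes <- vector("list", n)
  prop_covs <- vector("list", n)
  trace <- numeric(0)
  converged <- FALSE
  omega_projected <- FALSE
  est <- NULL
  history <- list()
  for (iter in seq_len(settings$max_iter)) {
    refresh <- iter == 1 || iter %% settings$hessian_refresh == 1
    est <- lapply(seq_len(n), function(i) {
      s_it <- if (settings$resample) 131L * iter + i else 100L + i
      marginal_neg2ll_is(subjects[[i]], pop, effs,
                         n_samples = settings$n_samples,
                         seed = derive_seed(settings$seed, s_it),
                         consts = consts, df = settings$df,
                         mode_start = modes[[i]],
                         proposal_cov = if (refresh) NULL else prop_covs[[i]],
                         mode_maxit = if (iter == 1) 100 else
                           settings$mode_maxit)
    })
    modes <- lapply(est, `[[`, "mode")
    if (refresh) prop_covs <- lapply(est, `[[`, "proposal_cov")
    obj <- sum(vapply(est, `[[`, numeric(1), "objective"))
    trace <- c(trace, obj)
    # ---- M-step ----
    free <- which(diag(pop$omega) > 0)
    M <- t(vapply(seq_len(n), function(i) {
      log_base_params(pop, effs, subjects[[i]]$flags) + est[[i]]$eta_mean
    }, numeric(6)))
    design <- effect_design(effs, subjects)
    new_ltheta <- log(pop$theta)
    new_effs <- effs
    fitted <- matrix(rep(new_ltheta, each = n), n, 6)
    for (j in seq_len(6)) {
      pn <- param_names()[j]
      if (!(j %in% free) && !length(design[[j]])) next
      if (is.null(design[[j]])) {
        new_ltheta[j] <- mean(M[, j])
        fitted[, j] <- new_ltheta[j]
      } else {
        X <- cbind(1, design[[j]]$X)
        cf <- qr.coef(qr(X), M[, j])
        new_ltheta[j] <- cf[1]
        for (k in seq_along(design[[j]]$idx)) {
          new_effs[[design[[j]]$idx[k]]]$effect <- expm1(cf[1 + k])
        }
        fitted[, j] <- X %*% cf
      }
    }
    if ("theta" %in% settings$update) {
      pop$theta <- setNames(exp(new_ltheta), param_names())
      effs <- new_effs
    } else {
      # means held fixed: residuals are the conditional eta means themselves
      fitted <- t(vapply(seq_len(n), function(i) {
        log_base_params(pop, effs, subjects[[i]]$flags)
      }, numeric(6)))
    }
    if ("omega" %in% settings$update && length(free)) {
      R <- M - fitted
      S <- Reduce(`+`, lapply(seq_len(n), function(i) {
        # the Monte Carlo variance of the estimated posterior mean
        # (about S_i / ESS_i) enters r_i r_i' as pure noise; left in place
        # it compounds across iterations and inflates omega geometrically
        mc <- if (is.finite(est[[i]]$ess) && est[[i]]$ess > 1) {
          1 / est[[i]]$ess
        } else 0
        est[[i]]$eta_cov[free, free, drop = FALSE] * (1 - mc) +
          tcrossprod(R[i, free])
      })) / n
      ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 0) omega_projected <- TRUE
      om <- pop$omega
      om[free, free] <- nearest_psd(S, 1e-8)
      pop$omega <- om
    }
    if ("sigma2" %in% settings$update) {
      wssr <- vapply(est, `[[`, numeric(1), "wssr")
      nobs <- vapply(est, `[[`, numeric(1), "n_obs")
      ok <- is.finite(wssr)
      if (any(ok)) pop$sigma2 <- max(sum(wssr[ok]) / sum(nobs[ok]), 1e-6)
    }
    # Aitken extrapolation: EM steps along flat directions form a geometric
    # series; jump ahead by its estimated remaining sum
    w <- settings$accel_every
    if ("theta" %in% settings$update && w > 0 && iter > 2 * w &&
        iter %% w == 0) {
      lth <- log(pop$theta)
      lth_prev <- history[[iter - w]]$ltheta
      lth_prev2 <- history[[iter - 2 * w]]$ltheta
      d1 <- (lth - lth_prev) / w          # current mean step
      d0 <- (lth_prev - lth_prev2) / w    # previous mean step
      rho <- ifelse(sign(d1) == sign(d0) & abs(d0) > 1e-8,
                    pmin(pmax(d1 / d0, 0), 0.92), 0)
      jump <- d1 * rho / (1 - rho)
      jump <- pmin(pmax(jump, -1), 1)
      pop$theta <- setNames(exp(lth + jump), param_names())
    }
    history[[iter]] <- list(ltheta = log(pop$theta), omega = pop$omega,
                            sigma2 = pop$sigma2,
                            phi = vapply(effs, function(e) log1p(e$effect),
                                         numeric(1)))
    # convergence: flat objective trend AND negligible parameter drift over a
    # recent window (the resampled trace is noisy; single-step changes are
    # not informative)
    win <- settings$obj_consec + 1
    if (iter >= max(win, settings$min_iter)) {
      recent <- trace[(iter - win + 1):iter]
      slope <- stats::coef(stats::lm.fit(cbind(1, seq_len(win)),
                                         recent))[2]
      dpar <- mean(abs(history[[iter]]$ltheta -
                         history[[iter - win + 1]]$ltheta)) / win
      if (abs(slope) < settings$obj_tol && dpar < settings$param_tol) {
        converged <- TRUE
        break
      }
    }
  }
  # average the last few iterates to shave Monte Carlo jitter
  L <- min(settings$average_last, length(history))
  if (L > 1) {
    keep <- history[(length(history) - L + 1):length(history)]
    pop$theta <- setNames(exp(Reduce(`+`, lapply(keep, `[[`, "ltheta")) / L),
                          param_names())
    pop$omega <- Reduce(`+`, lapply(keep, `[[`, "omega")) / L
    pop$sigma2 <- mean(vapply(keep, `[[`, numeric(1), "sigma2"))
    if (length(effs)) {
      phim <- Reduce(`+`, lapply(keep, `[[`, "phi")) / L
      for (k in seq_along(effs)) effs[[k]]$effect <- expm1(phim[k])
    }
  }
  # refinement of the typical values, covariate coefficients and sigma2 by
  # direct maximisation of a sample-reuse importance-sampling likelihood:
  # EM contracts very slowly along compensation ridges (e.g. thymic input
  # against loss); a quasi-Newton search on a smooth objective does not
  if (isTRUE(settings$polish) && "theta" %in% settings$update) {
    for (cycle in seq_len(settings$polish_cycles)) {
      upd <- polish_typicals(subjects, pop, effs, est, settings, consts,
                             cycle)
      pop <- upd$pop
      effs <- upd$effects
      if (settings$polish_em_iter > 0 &&
          any(c("omega", "sigma2") %in% settings$update)) {
        s2 <- settings
        s2$max_iter <- settings$polish_em_iter
        s2$min_iter <- 1
        s2$polish <- FALSE
        s2$update <- setdiff(settings$update, "theta")
        s2$average_last <- min(settings$average_last,
                               settings$polish_em_iter)
        s2$seed <- derive_seed(settings$seed, 777L + cycle)
        refit <- fit_population(dataset, init = pop, effects = effs,
                                settings = s2, consts = consts)
        pop$omega <- refit$pop$omega
        pop$sigma2 <- refit$pop$sigma2
        est <- refit$individual
      }
    }
  }
  final <- if (settings$final_samples > 0) {
    evaluate_objective(dataset, pop, effs,
                       n_samples = settings$final_samples,
                       seed = derive_seed(settings$seed, 999983L),
                       consts = consts)
  } else list(objective = trace[length(trace)])
  structure(list(pop = pop, effects = effs, objective = final$objective,
                 trace = trace, converged = converged,
                 omega_projected = omega_projected,
                 individual = est, subject_ids = vapply(subjects, `[[`,
                                                        character(1), "id"),
                 n_subjects = n, seed = settings$seed, settings = settings),
            class = "cd4_fit")
}

#' @export
print.cd4_fit <- function(x, ...) {
  cat(sprintf("CD4 population fit: %d subjects, objective %.2f (%s)\n",
              x$n_subjects, x$objective,
              if (x$converged) "converged" else "iteration limit"))
  print(signif(x$pop$theta, 4))
  if (length(x$effects)) {
    for (ef in x$effects) {
      cat(sprintf("  effect %s on %s: %+.3f\n", ef$covariate, ef$parameter,
                  ef$effect))
    }
  }
  invisible(x)
}

#' Evaluate the population objective without updating parameters
#'
#' A fixed evaluation pass: the sum over subjects of the importance-sampling
#' marginal -2 log likelihood at the supplied parameters.  Used by the
#' stepwise covariate search so that likelihood-ratio statistics come from a
#' common, larger-sample evaluation rather than the EM trace.
#'
#' @inheritParams fit_population
#' @param pop population parameters at which to evaluate.
#' @param n_samples importance samples per subject.
#' @param seed base seed (per-subject seeds derived deterministically).
#' @param subset optional integer subset of subjects to evaluate.
#' @param mode_cache optional environment carrying warm-start posterior modes
#'   between repeated evaluations at nearby parameters.
#' @return List with \code{objective} and per-subject \code{contributions}.
#' @export
evaluate_objective <- function(dataset, pop, effects = list(),
                               n_samples = 500, seed = 1L,
                               consts = age_reference_constants(),
                               subset = NULL, mode_cache = NULL) {
  subjects <- as_subject_list(dataset)
  idx <- if (is.null(subset)) seq_along(subjects) else subset
  contrib <- vapply(idx, function(i) {
    key <- as.character(i)
    warm <- if (!is.null(mode_cache)) mode_cache[[key]] else NULL
    r <- marginal_neg2ll_is(subjects[[i]], pop, effects,
                            n_samples = n_samples,
                            seed = derive_seed(seed, 100L + i),
                            consts = consts, mode_start = warm,
                            mode_maxit = if (is.null(warm)) 100 else 10)
    if (!is.null(mode_cache)) mode_cache[[key]] <- r$mode
    r$objective
  }, numeric(1))
  list(objective = sum(contrib), contributions = setNames(contrib, idx))
}

#' Bootstrap standard errors for the population fit
#'
#' Subject-level resampling with replacement; each replicate is refitted
#' (reduced EM iterations, warm-started at the original estimates) and the
#' standard deviation across converged replicates is reported for the typical
#' values, the random-effect variances, the covariate effects and
#' \eqn{\sigma^2}.
#'
#' @param dataset a \code{\link{cd4_dataset}}.
#' @param fit a \code{\link{fit_population}} result to resample around.
#' @param n_boot number of bootstrap replicates (>= 2; published default 200).
#' @param seed integer seed.
#' @param settings fit settings for the replicates (default: the fit's
#'   settings with \code{max_iter} reduced to 10).
#' @param consts reference constants.
#' @return List with \code{se} (named vector), \code{estimates} (replicate
#'   matrix), \code{n_failed} and \code{seed}.
#' @export
bootstrap_se <- function(dataset, fit, n_boot = 200, seed = 1L,
                         settings = NULL,
                         consts = age_reference_constants()) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  if (is.null(settings)) {
    settings <- fit$settings
    settings$max_iter <- 10
    settings$min_iter <- 2
    settings$obj_consec <- 2
    settings$polish <- FALSE      # replicates refit by short warm-started EM
    settings$final_samples <- 0   # replicate objectives are not reported
  }
  ids <- unique(dataset$SUBJID)
  est_names <- c(param_names(),
                 paste0("omega_", param_names()),
                 if (length(fit$effects)) {
                   vapply(fit$effects, function(e) {
                     paste0(e$covariate, ":", e$parameter)
                   }, character(1))
                 },
                 "sigma2")
  reps <- matrix(NA_real_, n_boot, length(est_names),
                 dimnames = list(NULL, est_names))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    take <- with_seed(derive_seed(seed, 500L + b),
                      sample(ids, length(ids), replace = TRUE))
    rows <- lapply(seq_along(take), function(k) {
      r <- dataset[dataset$SUBJID == take[k], , drop = FALSE]
      r$SUBJID <- sprintf("B%03d", k)
      r
    })
    bdat <- cd4_dataset(do.call(rbind, rows),
                        covariates = attr(dataset, "covariates"))
    bset <- settings
    bset$seed <- derive_seed(seed, 900L + b)
    bf <- tryCatch(fit_population(bdat, init = fit$pop,
                                  effects = fit$effects, settings = bset,
                                  consts = consts),
                   error = function(e) NULL)
    if (is.null(bf) || !is.finite(bf$objective)) {
      n_failed <- n_failed + 1L
      next
    }
    reps[b, ] <- c(bf$pop$theta, diag(bf$pop$omega),
                   if (length(bf$effects)) {
                     vapply(bf$effects, `[[`, numeric(1), "effect")
                   },
                   bf$pop$sigma2)
  }
  ok <- stats::complete.cases(reps)
  list(se = apply(reps[ok, , drop = FALSE], 2, sd),
       estimates = reps[ok, , drop = FALSE],
       n_failed = n_failed, seed = seed)
}
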