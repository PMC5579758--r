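#' Specification of a synthetic transplant cohort
#'
#' Describes the demographic and sampling structure used to generate
#' synthetic cohorts: age-at-transplant band weights, dichotomous covariate
#' prevalences, a right-skewed samples-per-subject distribution (median 8,
#' clipped to 1-43), and an observation window denser early after transplant.
#' The defaults emulate the published demographics of a pediatric transplant
#' cohort (age bands 0-1 y 16\%, 1-2 y 21\%, 2-5 y 23\%, 5-10 y 24\%,
#' >10 y 16\%; alemtuzumab 50\%, fludarabine 21\%, reported acute GvHD 32\%).
#'
#' @param n_subjects number of subjects.
#' @param age_band_weights numeric weights (must sum to 1) for the age bands
#'   0-1, 1-2, 2-5, 5-10 and 10-18 years.
#' @param covariate_prevalence named vector of Bernoulli prevalences in
#'   [0, 1].
#' @param samples_meanlog,samples_sdlog lognormal parameters of the
#'   samples-per-subject count before rounding and clipping.
#' @param samples_range inclusive bounds for the per-subject sample count.
#' @param first_day earliest observation day post-HSCT.
#' @param horizon_days follow-up horizon (days).
#' @param seed integer seed controlling every stage of generation.
#' @return A \code{cd4_cohort_spec} (named list).
#' @export
cohort_spec <- function(n_subjects = 100,
                        age_band_weights = c(0.16, 0.21, 0.23, 0.24, 0.16),
                        covariate_prevalence = c(alemtuzumab = 0.50,
                                                 fludarabine = 0.21,
                                                 gvhd = 0.32),
                        samples_meanlog = log(8),
                        samples_sdlog = 0.75,
                        samples_range = c(1, 43),
                        first_day = 14,
                        horizon_days = 7 * 365,
                        seed = 1L) {
  if (abs(sum(age_band_weights) - 1) > 1e-8) {
    stop("age_band_weights must sum to 1")
  }
  if (length(age_band_weights) != 5) {
    stop("age_band_weights must have 5 entries (0-1, 1-2, 2-5, 5-10, >10 y)")
  }
  if (any(covariate_prevalence < 0 | covariate_prevalence > 1)) {
    stop("covariate prevalences must lie in [0, 1]")
  }
  if (horizon_days <= first_day) stop("horizon must exceed first_day")
  structure(list(n_subjects = n_subjects,
                 age_band_weights = age_band_weights,
                 covariate_prevalence = covariate_prevalence,
                 samples_meanlog = samples_meanlog,
                 samples_sdlog = samples_sdlog,
                 samples_range = samples_range,
                 first_day = first_day,
                 horizon_days = horizon_days,
                 seed = as.integer(seed)),
            class = "cd4_cohort_spec")
}

# age band edges in days; 0-1 y band floored at 14 days (log-uniform draw
# needs a positive lower edge; younger transplant ages are not emulated)
age_band_edges <- function() {
  rbind(c(14, 365), c(365, 730), c(730, 1825), c(1825, 3650), c(3650, 6570))
}

# deterministic per-stage seed streams derived from one base seed
# (double arithmetic stays exact below 2^53, result always a valid integer)
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stage) * 9176) %%
               2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw subject skeletons (age at transplant and covariate flags)
#'
#' Ages are drawn by band (band probabilities from the spec) and log-uniformly
#' within band; covariate flags are independent Bernoulli draws at the stated
#' prevalences.  Fully reproducible from the spec seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return Data frame with columns \code{id}, \code{age0} and one 0/1 column
#'   per covariate.
#' @export
sample_demographics <- function(spec) {
  edges <- age_band_edges()
  with_seed(derive_seed(spec$seed, 1L), {
    band <- sample.int(5, spec$n_subjects, replace = TRUE,
                       prob = spec$age_band_weights)
    age0 <- exp(runif(spec$n_subjects, log(edges[band, 1]),
                      log(edges[band, 2])))
    out <- data.frame(id = sprintf("S%04d", seq_len(spec$n_subjects)),
                      age0 = age0, stringsAsFactors = FALSE)
    for (cv in names(spec$covariate_prevalence)) {
      out[[cv]] <- rbinom(spec$n_subjects, 1, spec$covariate_prevalence[[cv]])
    }
    out
  })
}

#' Draw per-subject observation schedules
#'
#' Sample counts come from a rounded lognormal clipped to the spec range;
#' observation times are log-uniform between \code{first_day} and the horizon
#' (denser early, emulating more frequent monitoring in the first year),
#' sorted and thinned to at least 3-day spacing.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param n number of subjects (default from the spec).
#' @return List of strictly increasing time vectors (days).
#' @export
sample_schedule <- function(spec, n = spec$n_subjects) {
  with_seed(derive_seed(spec$seed, 2L), {
    counts <- pmin(pmax(round(rlnorm(n, spec$samples_meanlog,
                                     spec$samples_sdlog)),
                        spec$samples_range[1]), spec$samples_range[2])
    lapply(counts, function(k) {
      t <- sort(exp(runif(k, log(spec$first_day), log(spec$horizon_days))))
      keep <- c(TRUE, diff(t) >= 3)
      while (!all(keep)) {
        t <- t[keep]
        keep <- c(TRUE, diff(t) >= 3)
      }
      t
    })
  })
}

#' Simulate a longitudinal CD4 dataset from the population model
#'
#' For each subject a log-scale random-effect vector is drawn from
#' \eqn{N(0, \Omega)}, individual parameters are assembled via
#' \code{\link{individual_parameters}}, the trajectory is solved at the
#' subject's observation times, and observations are emitted as
#' \eqn{\exp(\log X(t) + \epsilon)} with \eqn{\epsilon \sim N(0, \sigma^2)}.
#' The true random effects and parameters are stored in the \code{"truth"}
#' attribute for recovery experiments.
#'
#' @param pop a \code{\link{population_parameters}} object.
#' @param effects list of \code{\link{covariate_effect}}s applied during
#'   simulation.
#' @param skeletons data frame from \code{\link{sample_demographics}}.
#' @param schedules list of time vectors from \code{\link{sample_schedule}}.
#' @param seed integer seed for random effects and residual noise.
#' @param consts reference constants.
#' @return A \code{\link{cd4_dataset}} with a \code{"truth"} attribute
#'   (list with \code{eta} and \code{params} matrices, one row per subject).
#' @export
simulate_dataset <- function(pop, effects = list(), skeletons, schedules,
                             seed = 1L, consts = age_reference_constants()) {
  n <- nrow(skeletons)
  if (length(schedules) != n) stop("skeletons and schedules lengths differ")
  covs <- setdiff(names(skeletons), c("id", "age0"))
  cv <- consts_vector(consts)
  with_seed(derive_seed(seed, 3L), {
    eta <- MASS::mvrnorm(n, mu = rep(0, 6), Sigma = pop$omega)
    if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1)
    colnames(eta) <- param_names()
    par_mat <- matrix(NA_real_, n, 6, dimnames = list(NULL, param_names()))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      flags <- unlist(skeletons[i, covs, drop = FALSE])
      for (attempt in 1:2) {
        p <- individual_parameters(pop, effects, flags, eta[i, ])
        x <- cd4_solve_cpp(schedules[[i]], as.numeric(p), skeletons$age0[i],
                           cv)
        if (all(is.finite(x)) && all(x > 0)) break
        if (attempt == 2) {
          stop(sprintf("trajectory failed twice for subject %s",
                       skeletons$id[i]))
        }
        eta[i, ] <- MASS::mvrnorm(1, mu = rep(0, 6), Sigma = pop$omega)
      }
      par_mat[i, ] <- as.numeric(p)[1:6]
      dv <- exp(log(x) + rnorm(length(x), 0, sqrt(pop$sigma2)))
      df <- data.frame(SUBJID = rep(skeletons$id[i], length(x)),
                       AGE0_DAYS = rep(skeletons$age0[i], length(x)),
                       TIME_DAYS = schedules[[i]], CD4 = dv,
                       stringsAsFactors = FALSE)
      for (cvn in covs) df[[cvn]] <- rep(unname(flags[cvn]), length(x))
      rows[[i]] <- df
    }
    out <- cd4_dataset(do.call(rbind, rows), covariates = covs)
    attr(out, "truth") <- list(eta = eta, params = par_mat,
                               subject_ids = skeletons$id, seed = seed)
    out
  })
}

#' Simulate a complete synthetic cohort in one call
#'
#' Convenience wrapper chaining \code{\link{sample_demographics}},
#' \code{\link{sample_schedule}} and \code{\link{simulate_dataset}} under the
#' spec's seed.
#'
#' @inheritParams simulate_dataset
#' @param spec a \code{\link{cohort_spec}}.
#' @return A \code{\link{cd4_dataset}}.
#' @export
simulate_cohort <- function(pop, effects = list(), spec = cohort_spec(),
                            consts = age_reference_constants()) {
  skel <- sample_demographics(spec)
  sched <- sample_schedule(spec)
  simulate_dataset(pop, effects, skel, sched, seed = spec$seed,
                   consts = consts)
}
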