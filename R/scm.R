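#' Likelihood-ratio test p-value
#'
#' Upper-tail chi-square probability for a difference in -2 log likelihood
#' between nested models.
#'
#' @param delta_objective difference in -2 log likelihood (any real; negative
#'   values give p = 1).
#' @param df number of additional parameters (>= 1).
#' @return Probability in [0, 1].
#' @export
lrt_pvalue <- function(delta_objective, df) {
  if (any(df < 1)) stop("df must be at least 1")
  pchisq(pmax(delta_objective, 0), df = df, lower.tail = FALSE)
}

#' Settings for the stepwise covariate search
#'
#' @param scan_samples importance samples per subject in the objective
#'   evaluation passes (kept larger than the EM default so Monte Carlo noise
#'   is well below the chi-square decision thresholds).
#' @param scan one of \code{"effect_only"} (candidate effects are profiled
#'   with the other population parameters held at the base fit; only flagged
#'   subjects are re-evaluated) or \code{"full"} (each candidate model is
#'   refitted by EM).
#' @param refit_max_iter EM iteration cap for \code{scan = "full"} refits.
#' @param seed base seed for all evaluation passes.
#' @return List of settings.
#' @export
scm_settings <- function(scan_samples = 500, scan = c("effect_only", "full"),
                         refit_max_iter = 15, seed = 1L) {
  list(scan_samples = scan_samples, scan = match.arg(scan),
       refit_max_iter = refit_max_iter, seed = as.integer(seed))
}

# profile the objective over one candidate effect's value, others fixed.
# Only subjects carrying the flag contribute to the change in objective,
# so unflagged subjects are evaluated once and cached by the caller.
profile_effect <- function(dataset, pop, effects, candidate, flagged_idx,
                           n_samples, seed, consts) {
  cache <- new.env(parent = emptyenv())
  obj_at <- function(phi) {
    eff <- covariate_effect(candidate$covariate, candidate$parameter,
                            expm1(phi))
    evaluate_objective(dataset, pop, c(effects, list(eff)),
                       n_samples = n_samples, seed = seed, consts = consts,
                       subset = flagged_idx, mode_cache = cache)$objective
  }
  opt <- optimize(obj_at, interval = c(-4, 2), tol = 1e-3)
  list(effect = expm1(opt$minimum), objective_flagged = opt$objective)
}

#' Stepwise covariate model building
#'
#' Forward inclusion / backward elimination of dichotomous covariate effects
#' by likelihood-ratio testing.  In the forward search every remaining
#' candidate pair is added singly to the current model and the pair with the
#' lowest p-value is included if p < \code{forward_alpha} (default 0.01);
#' this repeats until no candidate qualifies.  In the backward elimination
#' retained effects are removed singly and the least significant effect is
#' dropped while its removal p-value is >= \code{backward_alpha} (default
#' 0.005).  Ties are broken by larger objective drop, then by pair name.
#' Objective values come from fixed evaluation passes (not the EM trace) with
#' common per-subject seeds, so candidate comparisons share Monte Carlo noise.
#'
#' @param dataset a \code{\link{cd4_dataset}}.
#' @param candidates data frame with columns \code{covariate} and
#'   \code{parameter} (default: every covariate crossed with every structural
#'   parameter).
#' @param forward_alpha,backward_alpha inclusion / retention thresholds.
#' @param base_fit optional precomputed base \code{\link{fit_population}}
#'   result (no covariate effects); fitted here when absent.
#' @param fit_settings_base settings for the base fit.
#' @param settings a \code{\link{scm_settings}} list.
#' @param consts reference constants.
#' @return A \code{cd4_scm}: list with \code{steps} (decision log data
#'   frame), \code{final_effects}, \code{final_fit} and the base fit.
#' @export
scm <- function(dataset, candidates = NULL, forward_alpha = 0.01,
                backward_alpha = 0.005, base_fit = NULL,
                fit_settings_base = fit_settings(),
                settings = scm_settings(),
                consts = age_reference_constants()) {
  covs <- attr(dataset, "covariates")
  if (is.null(candidates)) {
    candidates <- expand.grid(covariate = covs, parameter = param_names(),
                              stringsAsFactors = FALSE)
  }
  if (!all(candidates$covariate %in% covs)) {
    stop("candidate covariate not present in the dataset")
  }
  if (!all(candidates$parameter %in% param_names())) {
    stop("candidate parameter is not a structural parameter")
  }
  if (is.null(base_fit)) {
    base_fit <- fit_population(dataset, effects = list(),
                               settings = fit_settings_base, consts = consts)
  }
  subjects <- as_subject_list(dataset)
  pop <- base_fit$pop
  pair_name <- function(cv, pn) paste0(cv, ":", pn)
  steps <- data.frame(phase = character(), step = integer(),
                      pair = character(), delta_objective = numeric(),
                      df = integer(), p_value = numeric(),
                      effect = numeric(), decision = character(),
                      stringsAsFactors = FALSE)
  current <- list()   # accepted covariate_effects
  step_no <- 0L

  eval_cache <- new.env(parent = emptyenv())
  eval_subset <- function(effects, idx, seed) {
    if (!length(idx)) return(0)
    evaluate_objective(dataset, pop, effects, settings$scan_samples,
                       seed = seed, consts = consts,
                       subset = idx, mode_cache = eval_cache)$objective
  }

  remaining <- seq_len(nrow(candidates))
  repeat {
    step_no <- step_no + 1L
    seed_f <- derive_seed(settings$seed, 40L + step_no)
    results <- lapply(remaining, function(ci) {
      cand <- candidates[ci, ]
      flagged <- which(vapply(subjects, function(s) {
        s$flags[[cand$covariate]] == 1
      }, logical(1)))
      if (!length(flagged)) {
        return(list(ok = FALSE, ci = ci))
      }
      ref <- eval_subset(current, flagged, seed_f)
      pr <- tryCatch(
        profile_effect(dataset, pop, current, cand, flagged,
                       settings$scan_samples, seed_f, consts),
        error = function(e) NULL)
      if (is.null(pr)) return(list(ok = FALSE, ci = ci))
      delta <- ref - pr$objective_flagged
      list(ok = TRUE, ci = ci, delta = delta, effect = pr$effect,
           p = lrt_pvalue(delta, 1))
    })
    ok <- vapply(results, `[[`, logical(1), "ok")
    if (!any(ok)) break
    res <- results[ok]
    tab <- data.frame(
      ci = vapply(res, `[[`, numeric(1), "ci"),
      delta = vapply(res, `[[`, numeric(1), "delta"),
      effect = vapply(res, `[[`, numeric(1), "effect"),
      p = vapply(res, `[[`, numeric(1), "p"))
    tab$pair <- pair_name(candidates$covariate[tab$ci],
                          candidates$parameter[tab$ci])
    tab <- tab[order(tab$p, -tab$delta, tab$pair), , drop = FALSE]
    best <- tab[1, ]
    accepted <- best$p < forward_alpha
    steps <- rbind(steps, data.frame(
      phase = "forward", step = step_no, pair = best$pair,
      delta_objective = best$delta, df = 1L, p_value = best$p,
      effect = best$effect,
      decision = if (accepted) "included" else "stopped",
      stringsAsFactors = FALSE))
    if (!accepted) break
    ci <- best$ci
    current <- c(current, list(covariate_effect(candidates$covariate[ci],
                                                candidates$parameter[ci],
                                                best$effect)))
    remaining <- setdiff(remaining, ci)
    if (!length(remaining)) break
  }

  # backward elimination at the stricter threshold
  repeat {
    if (!length(current)) break
    step_no <- step_no + 1L
    seed_b <- derive_seed(settings$seed, 70L + step_no)
    idx_all <- seq_along(subjects)
    full_obj <- eval_subset(current, idx_all, seed_b)
    removal <- lapply(seq_along(current), function(k) {
      reduced <- current[-k]
      delta <- eval_subset(reduced, idx_all, seed_b) - full_obj
      list(k = k, delta = delta, p = lrt_pvalue(delta, 1))
    })
    tab <- data.frame(
      k = vapply(removal, `[[`, numeric(1), "k"),
      delta = vapply(removal, `[[`, numeric(1), "delta"),
      p = vapply(removal, `[[`, numeric(1), "p"))
    tab$pair <- vapply(tab$k, function(k) {
      pair_name(current[[k]]$covariate, current[[k]]$parameter)
    }, character(1))
    tab <- tab[order(-tab$p, tab$delta, tab$pair), , drop = FALSE]
    worst <- tab[1, ]
    dropped <- worst$p >= backward_alpha
    steps <- rbind(steps, data.frame(
      phase = "backward", step = step_no, pair = worst$pair,
      delta_objective = worst$delta, df = 1L, p_value = worst$p,
      effect = current[[worst$k]]$effect,
      decision = if (dropped) "removed" else "retained",
      stringsAsFactors = FALSE))
    if (!dropped) break
    current <- current[-worst$k]
  }

  final_fit <- if (length(current)) {
    fs <- fit_settings_base
    fs$max_iter <- settings$refit_max_iter
    fit_population(dataset, init = pop, effects = current, settings = fs,
                   consts = consts)
  } else base_fit
  structure(list(steps = steps, final_effects = final_fit$effects,
                 final_fit = final_fit, base_fit = base_fit,
                 forward_alpha = forward_alpha,
                 backward_alpha = backward_alpha),
            class = "cd4_scm")
}

#' @export
print.cd4_scm <- function(x, ...) {
  cat("Stepwise covariate model building\n")
  print(x$steps, row.names = FALSE)
  if (length(x$final_effects)) {
    cat("final model effects:\n")
    for (ef in x$final_effects) {
      cat(sprintf("  %s on %s: %+.3f\n", ef$covariate, ef$parameter,
                  ef$effect))
    }
  } else cat("final model: no covariate effects\n")
  invisible(x)
}
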