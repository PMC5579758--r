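#' Read a run configuration
#'
#' YAML with the sections \code{reference} (overrides for
#' \code{\link{age_reference_constants}}, including the thymic-output
#' grouping tag), \code{parameters} (\code{theta} named map, \code{omega}
#' either a diagonal vector or full matrix rows, \code{sigma2}),
#' \code{covariates} (list of \{covariate, parameter, effect\} maps),
#' \code{estimation} (overrides for \code{\link{fit_settings}}),
#' \code{forecast} (\code{cutoff_days}, \code{n_samples},
#' \code{horizon_days}) and \code{seeds} (\code{base}).  Unknown section or
#' key names are rejected.
#'
#' @param path YAML file path.
#' @return A \code{cd4_config}: list with elements \code{consts},
#'   \code{pop}, \code{effects}, \code{estimation}, \code{forecast},
#'   \code{seed}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("reference", "parameters", "covariates", "estimation",
             "forecast", "seeds")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  check_keys <- function(section, allowed) {
    extra <- setdiff(names(cfg[[section]]), allowed)
    if (length(extra)) {
      stop(sprintf("unknown key(s) in section '%s': %s", section,
                   paste(extra, collapse = ", ")))
    }
  }
  check_keys("reference", names(formals(age_reference_constants)))
  consts <- do.call(age_reference_constants,
                    cfg$reference %||% list())
  pop <- NULL
  if (!is.null(cfg$parameters)) {
    check_keys("parameters", c("theta", "omega", "sigma2"))
    th <- unlist(cfg$parameters$theta)
    om <- cfg$parameters$omega
    if (is.list(om)) om <- do.call(rbind, lapply(om, unlist))
    pop <- population_parameters(th, om, cfg$parameters$sigma2)
  }
  effects <- lapply(cfg$covariates %||% list(), function(e) {
    extra <- setdiff(names(e), c("covariate", "parameter", "effect"))
    if (length(extra)) {
      stop("unknown key(s) in covariate entry: ",
           paste(extra, collapse = ", "))
    }
    covariate_effect(e$covariate, e$parameter, e$effect)
  })
  check_keys("estimation", names(formals(fit_settings)))
  estimation <- do.call(fit_settings, cfg$estimation %||% list())
  check_keys("forecast", c("cutoff_days", "n_samples", "horizon_days"))
  fc <- modifyList(list(cutoff_days = 183, n_samples = 500,
                        horizon_days = 3 * 365), cfg$forecast %||% list())
  check_keys("seeds", "base")
  seed <- as.integer((cfg$seeds %||% list(base = 1L))$base)
  structure(list(consts = consts, pop = pop, effects = effects,
                 estimation = estimation, forecast = fc, seed = seed),
            class = "cd4_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write fitted parameters as a configuration file
#'
#' Serialises a fit's population parameters and covariate effects in the
#' \code{parameters}/\code{covariates} schema of
#' \code{\link{read_run_config}}, so a fit's output can be fed directly to
#' forecasting and predictive checks.
#'
#' @param fit a \code{\link{fit_population}} result (or list with \code{pop}
#'   and \code{effects}).
#' @param path output path.
#' @param seed optional base seed to record.
#' @return The path, invisibly.
#' @export
write_fit_config <- function(fit, path, seed = NULL) {
  cfg <- list(
    parameters = list(
      theta = as.list(fit$pop$theta),
      omega = lapply(seq_len(nrow(fit$pop$omega)), function(i) {
        as.numeric(fit$pop$omega[i, ])
      }),
      sigma2 = fit$pop$sigma2),
    covariates = lapply(fit$effects, function(e) {
      list(covariate = e$covariate, parameter = e$parameter,
           effect = e$effect)
    }))
  if (!is.null(seed)) cfg$seeds <- list(base = as.integer(seed))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
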