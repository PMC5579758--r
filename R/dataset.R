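#' Longitudinal CD4 dataset
#'
#' A \code{cd4_dataset} is a data frame with one row per observation and
#' columns \code{SUBJID} (character), \code{AGE0_DAYS} (age at transplant,
#' days; constant within subject), \code{TIME_DAYS} (days post-HSCT, >= 0),
#' \code{CD4} (cells/uL, > 0) and zero or more named 0/1 covariate columns.
#' The covariate column names are recorded in the \code{"covariates"}
#' attribute.
#'
#' @param data a data frame with the columns above.
#' @param covariates character vector naming the covariate columns (default:
#'   every column beyond the four mandatory ones, in order).
#' @return A \code{cd4_dataset}.
#' @export
cd4_dataset <- function(data, covariates = NULL) {
  required <- c("SUBJID", "AGE0_DAYS", "TIME_DAYS", "CD4")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(covariates)) covariates <- setdiff(names(data), required)
  data <- data[, c(required, covariates), drop = FALSE]
  data$SUBJID <- as.character(data$SUBJID)
  if (any(!is.finite(data$CD4)) || any(data$CD4 <= 0)) {
    stop("CD4 must be strictly positive on all rows")
  }
  if (any(!is.finite(data$TIME_DAYS)) || any(data$TIME_DAYS < 0)) {
    stop("TIME_DAYS must be non-negative")
  }
  for (cv in covariates) {
    if (!all(data[[cv]] %in% c(0, 1))) {
      stop(sprintf("covariate column '%s' must be 0/1", cv))
    }
  }
  age_per_subject <- tapply(data$AGE0_DAYS, data$SUBJID,
                            function(a) length(unique(a)))
  if (any(age_per_subject > 1)) {
    bad <- names(age_per_subject)[age_per_subject > 1][1]
    stop(sprintf("subject '%s' has inconsistent AGE0_DAYS", bad))
  }
  ord <- order(match(data$SUBJID, unique(data$SUBJID)), data$TIME_DAYS)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  structure(data, covariates = covariates,
            class = c("cd4_dataset", "data.frame"))
}

#' Single-subject record
#'
#' @param id subject identifier.
#' @param age_at_hsct age at transplant (days).
#' @param times,cd4 observation times (days post-HSCT, non-decreasing) and
#'   CD4 concentrations (cells/uL, > 0); may be empty.
#' @param flags named 0/1 vector of dichotomous covariates.
#' @return A \code{cd4_subject} (list with elements \code{id}, \code{age0},
#'   \code{flags}, \code{times}, \code{dv}, \code{log_dv}).
#' @export
subject_record <- function(id, age_at_hsct, times = numeric(),
                           cd4 = numeric(), flags = numeric()) {
  if (length(times) != length(cd4)) stop("times and cd4 lengths differ")
  if (length(times) && (any(diff(times) < 0) || any(times < 0))) {
    stop("times must be non-decreasing and non-negative")
  }
  if (length(cd4) && any(cd4 <= 0)) stop("cd4 must be strictly positive")
  stop_if_negative_age(age_at_hsct)
  structure(list(id = as.character(id), age0 = age_at_hsct,
                 flags = flags, times = as.numeric(times),
                 dv = as.numeric(cd4), log_dv = log(as.numeric(cd4))),
            class = "cd4_subject")
}

#' Split a dataset into subject records
#'
#' @param dataset a \code{\link{cd4_dataset}}.
#' @return List of \code{\link{subject_record}} objects, in order of first
#'   appearance.
#' @export
as_subject_list <- function(dataset) {
  covs <- attr(dataset, "covariates")
  ids <- unique(dataset$SUBJID)
  lapply(ids, function(id) {
    rows <- dataset[dataset$SUBJID == id, , drop = FALSE]
    flags <- vapply(covs, function(cv) rows[[cv]][1], numeric(1))
    subject_record(id, rows$AGE0_DAYS[1], rows$TIME_DAYS, rows$CD4, flags)
  })
}

subjects_to_dataset <- function(subjects, covariates) {
  rows <- lapply(subjects, function(s) {
    n <- length(s$times)
    if (n == 0) return(NULL)
    df <- data.frame(SUBJID = rep(s$id, n), AGE0_DAYS = rep(s$age0, n),
                     TIME_DAYS = s$times, CD4 = s$dv,
                     stringsAsFactors = FALSE)
    for (cv in covariates) df[[cv]] <- rep(unname(s$flags[cv]), n)
    df
  })
  cd4_dataset(do.call(rbind, rows), covariates = covariates)
}
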