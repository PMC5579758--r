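#' Healthy-child reference constants
#'
#' Fixed coefficients of the healthy-child reference curves used to scale the
#' mechanistic model for age: the expected total CD4 concentration
#' \eqn{N(\tau) = 924 + 2354 e^{-0.001012 \tau}} and naive CD4 concentration
#' \eqn{N_n(\tau) = 496.5 + 2074 e^{-0.000869 \tau}} (cells/uL, age \eqn{\tau}
#' in days), the age-declining fraction of CD4 cells expressing the
#' proliferation marker Ki67, \eqn{y(\tau) = 0.02 e^{-0.00027 \tau}}, the
#' duration of Ki67 expression (days), and the average TREC content of naive
#' T cells leaving the thymus (\code{trec_thymus}) and of the circulating
#' naive pool (\code{trec_pool}).
#'
#' The theoretical thymic-output-for-age curve is proportional to
#' \eqn{y(\tau) N_n(\tau)} times an age-independent multiplier assembled from
#' \code{trec_pool}, \code{ki67_at_birth}, \code{ki67_duration} and
#' \code{(trec_thymus - trec_pool)}.  How those constants combine is
#' configurable through \code{lambda_age_grouping} because the source algebra
#' is ambiguous; see \code{\link{grouping_multiplier}}.  The default grouping
#' was frozen by calibration against published typical-trajectory summaries
#' (see the methods vignette).
#'
#' @param n_total_asymptote,n_total_amplitude asymptote and amplitude of
#'   \eqn{N(\tau)} (cells/uL).
#' @param n_total_rate decay rate of \eqn{N(\tau)} (per day).
#' @param n_naive_asymptote,n_naive_amplitude,n_naive_rate the same for the
#'   naive curve \eqn{N_n(\tau)}.
#' @param ki67_at_birth Ki67+ fraction at birth (dimensionless, in (0, 1)).
#' @param ki67_decay_rate decay rate of the Ki67+ fraction (per day).
#' @param ki67_duration duration of Ki67 expression (days).
#' @param trec_thymus,trec_pool average TREC content of recent thymic
#'   emigrants and of the naive pool (dimensionless;
#'   \code{trec_thymus > trec_pool} required).
#' @param lambda_age_grouping one of \code{"num_cmg"} (default),
#'   \code{"den_keta_cmg"}, \code{"num_eta_cmg"}, \code{"den_keta"},
#'   \code{"den_eta_cmg"}; see \code{\link{grouping_multiplier}}.
#' @return An object of class \code{cd4_reference} (a named list).
#' @export
age_reference_constants <- function(n_total_asymptote = 924,
                                    n_total_amplitude = 2354,
                                    n_total_rate = 0.001012,
                                    n_naive_asymptote = 496.5,
                                    n_naive_amplitude = 2074,
                                    n_naive_rate = 0.000869,
                                    ki67_at_birth = 0.02,
                                    ki67_decay_rate = 0.00027,
                                    ki67_duration = 0.52,
                                    trec_thymus = 0.25,
                                    trec_pool = 0.08,
                                    lambda_age_grouping = "num_cmg") {
  consts <- list(
    n_total_asymptote = n_total_asymptote,
    n_total_amplitude = n_total_amplitude,
    n_total_rate = n_total_rate,
    n_naive_asymptote = n_naive_asymptote,
    n_naive_amplitude = n_naive_amplitude,
    n_naive_rate = n_naive_rate,
    ki67_at_birth = ki67_at_birth,
    ki67_decay_rate = ki67_decay_rate,
    ki67_duration = ki67_duration,
    trec_thymus = trec_thymus,
    trec_pool = trec_pool,
    lambda_age_grouping = match.arg(lambda_age_grouping,
                                    c("num_cmg", "den_keta_cmg",
                                      "num_eta_cmg", "den_keta",
                                      "den_eta_cmg"))
  )
  num <- consts[setdiff(names(consts), "lambda_age_grouping")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(unlist(num) <= 0)) {
    stop("all reference constants must be strictly positive numbers")
  }
  if (ki67_at_birth >= 1) stop("ki67_at_birth must lie in (0, 1)")
  if (trec_thymus <= trec_pool) {
    stop("trec_thymus must exceed trec_pool (c > gamma)")
  }
  structure(consts, class = "cd4_reference")
}

#' @export
print.cd4_reference <- function(x, ...) {
  cat("Healthy-child CD4 reference constants\n")
  cat(sprintf("  N(age)  = %g + %g exp(-%g age)\n", x$n_total_asymptote,
              x$n_total_amplitude, x$n_total_rate))
  cat(sprintf("  Nn(age) = %g + %g exp(-%g age)\n", x$n_naive_asymptote,
              x$n_naive_amplitude, x$n_naive_rate))
  cat(sprintf("  y(age)  = %g exp(-%g age)\n", x$ki67_at_birth,
              x$ki67_decay_rate))
  cat(sprintf("  thymic-output grouping: %s (multiplier %.4f)\n",
              x$lambda_age_grouping, grouping_multiplier(x)))
  invisible(x)
}

stop_if_negative_age <- function(age) {
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("age must be finite and non-negative (days)")
  }
}

#' Expected total CD4 concentration of a healthy child
#'
#' @param age age in days (non-negative).
#' @param consts a \code{\link{age_reference_constants}} object.
#' @return Concentration in cells/uL; strictly decreasing in age and bounded
#'   below by the asymptote.
#' @export
expected_total_cd4 <- function(age, consts = age_reference_constants()) {
  stop_if_negative_age(age)
  consts$n_total_asymptote +
    consts$n_total_amplitude * exp(-consts$n_total_rate * age)
}

#' Expected naive CD4 concentration of a healthy child
#'
#' @inheritParams expected_total_cd4
#' @return Concentration in cells/uL.
#' @export
expected_naive_cd4 <- function(age, consts = age_reference_constants()) {
  stop_if_negative_age(age)
  consts$n_naive_asymptote +
    consts$n_naive_amplitude * exp(-consts$n_naive_rate * age)
}

#' Fraction of CD4 cells expressing Ki67 at a given age
#'
#' @inheritParams expected_total_cd4
#' @return Dimensionless fraction in (0, ki67_at_birth].
#' @export
ki67_fraction <- function(age, consts = age_reference_constants()) {
  stop_if_negative_age(age)
  consts$ki67_at_birth * exp(-consts$ki67_decay_rate * age)
}

#' Age-independent multiplier of the thymic-output-for-age curve
#'
#' The thymic output of a healthy child of age \eqn{\tau} is modelled as
#' \eqn{\lambda_{age}(\tau) = m \, y(\tau) N_n(\tau)} where the multiplier
#' \eqn{m} combines the TREC constants \eqn{\gamma} (\code{trec_pool}),
#' \eqn{c - \gamma} (\code{trec_thymus - trec_pool}), the Ki67 expression
#' duration \eqn{\eta} and the birth Ki67 fraction \eqn{k}.  The algebraic
#' grouping of these constants is ambiguous in the source formula, so the
#' plausible readings are enumerated:
#' \describe{
#'   \item{num_cmg}{\eqn{\gamma (c-\gamma) / (k \eta)} -- the frozen,
#'     calibrated default (about 1.308)}
#'   \item{den_keta_cmg}{\eqn{\gamma / (k \eta (c-\gamma))} (about 45.25)}
#'   \item{num_eta_cmg}{\eqn{\gamma \eta (c-\gamma) / k} (about 0.354)}
#'   \item{den_keta}{\eqn{\gamma / (k \eta)} (about 7.69)}
#'   \item{den_eta_cmg}{\eqn{\gamma / (\eta (c-\gamma))} (about 0.905)}
#' }
#'
#' @param consts a \code{\link{age_reference_constants}} object.
#' @return The positive multiplier \eqn{m}.
#' @export
grouping_multiplier <- function(consts = age_reference_constants()) {
  g   <- consts$trec_pool
  cmg <- consts$trec_thymus - consts$trec_pool
  k   <- consts$ki67_at_birth
  eta <- consts$ki67_duration
  if (cmg <= 0) stop("configuration error: trec_thymus <= trec_pool")
  switch(consts$lambda_age_grouping,
         num_cmg      = g * cmg / (k * eta),
         den_keta_cmg = g / (k * eta * cmg),
         num_eta_cmg  = g * eta * cmg / k,
         den_keta     = g / (k * eta),
         den_eta_cmg  = g / (eta * cmg))
}

#' Theoretical thymic output of a healthy child for age
#'
#' \eqn{\lambda_{age}(\tau) = m\, y(\tau) N_n(\tau)} with the grouping
#' multiplier \eqn{m} of \code{\link{grouping_multiplier}}.  In the full model
#' this curve is scaled by the estimated proportion \code{lambda0} and by the
#' post-transplant recovery function.
#'
#' @inheritParams expected_total_cd4
#' @return Output rate in cells/uL/day; strictly decreasing in age.
#' @export
thymic_output_for_age <- function(age, consts = age_reference_constants()) {
  stop_if_negative_age(age)
  grouping_multiplier(consts) * ki67_fraction(age, consts) *
    expected_naive_cd4(age, consts)
}

# consts packed for the C++ solver
consts_vector <- function(consts) {
  c(consts$n_total_asymptote, consts$n_total_amplitude, consts$n_total_rate,
    consts$n_naive_asymptote, consts$n_naive_amplitude, consts$n_naive_rate,
    consts$ki67_at_birth, consts$ki67_decay_rate,
    grouping_multiplier(consts))
}

#' Days per month used when reporting monthly summaries
#'
#' Calendar-average month length (30.4375 days).
#' @export
DAYS_PER_MONTH <- 30.4375
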