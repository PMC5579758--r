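#' Structural model parameters for one individual
#'
#' The single-compartment reconstitution model has six estimated parameters:
#' \code{lambda0} (proportion of theoretical thymic output), \code{d0}
#' (proportion of expected loss, /day), \code{p0} (proportion of expected
#' proliferation, /day), \code{x0} (CD4 concentration at transplant,
#' cells/uL), \code{lambda_h} (time scale of thymic recovery, days) and
#' \code{lambda_r} (rate of thymic recovery).  The competition strengths
#' \code{cp} and \code{cd} are fixed to one by default (identifiability: their
#' effect on the reconstitution curve is absorbed by the other parameters) and
#' carry no random effects.
#'
#' @param lambda0,d0,p0,x0,lambda_h,lambda_r structural parameters, all
#'   strictly positive.
#' @param cp,cd competition strengths on proliferation and loss; fixed to 1.
#' @return An object of class \code{cd4_params} (named numeric vector with a
#'   \code{fixed} attribute marking \code{cp}/\code{cd}).
#' @export
structural_parameters <- function(lambda0, d0, p0, x0, lambda_h, lambda_r,
                                  cp = 1, cd = 1) {
  p <- c(lambda0 = lambda0, d0 = d0, p0 = p0, x0 = x0,
         lambda_h = lambda_h, lambda_r = lambda_r, cp = cp, cd = cd)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("all structural parameters must be finite and strictly positive")
  }
  structure(p, fixed = c(cp = TRUE, cd = TRUE), class = "cd4_params")
}

#' Published typical structural parameter values
#'
#' The typical (population median) estimates: lambda0 0.216, d0 0.477/day,
#' p0 0.207/day, x0 168 cells/uL, lambda_h 133 days, lambda_r 9.66.
#'
#' @return A \code{cd4_params} object.
#' @export
typical_parameters <- function() {
  structural_parameters(lambda0 = 0.216, d0 = 0.477, p0 = 0.207,
                        x0 = 168, lambda_h = 133, lambda_r = 9.66)
}

#' Calibrated typical transplanted child
#'
#' The published typical parameter values with the initial concentration
#' replaced by 30.6 cells/uL, i.e. the typical value under lymphodepleting
#' antibody conditioning (178 cells/uL reduced by 83\%), which half of the
#' study population received.  Freezing this configuration -- together with
#' the default thymic-output grouping -- was the result of calibrating the
#' model's discrete reading choices against the published typical-trajectory
#' summaries; see the methods vignette for the calibration and its
#' limitations.
#'
#' @return A \code{cd4_params} object.
#' @export
typical_hsct_child <- function() {
  p <- typical_parameters()
  p["x0"] <- 30.6
  p
}

#' Sigmoidal post-transplant recovery of thymic output
#'
#' \deqn{\Delta(t) = \frac{1 - e^{-2t/\lambda_h}}{1 + e^{\lambda_r (1 - t/\lambda_h)}}}
#'
#' Zero at \code{t = 0}, monotone non-decreasing, approaching 1.  The
#' denominator is evaluated overflow-safely for large \code{lambda_r}.
#'
#' @param t time after transplant (days, non-negative); vectorised.
#' @param lambda_h time scale of recovery (days, > 0).
#' @param lambda_r rate of recovery (> 0).
#' @return Fraction in [0, 1).
#' @export
thymic_recovery <- function(t, lambda_h, lambda_r) {
  if (any(t < 0) || lambda_h <= 0 || lambda_r <= 0) {
    stop("t must be >= 0 and lambda_h, lambda_r > 0")
  }
  num <- 1 - exp(-2 * t / lambda_h)
  z <- lambda_r * (1 - t / lambda_h)
  ifelse(z > 700, num * exp(-z), num / (1 + exp(z)))
}

#' Density-dependent proliferation rate
#'
#' \eqn{p(X, \tau) = p_0 \, y(\tau) \, e^{c_p (1 - X/N(\tau))}}: proliferation
#' slows as the compartment fills towards the age-expected concentration
#' \eqn{N(\tau)} (homeostatic competition for resources).
#'
#' @param x CD4 concentration (cells/uL, > 0).
#' @param age current age (days).
#' @param p0 proliferation scale (/day).
#' @param cp competition strength (default 1).
#' @param consts reference constants.
#' @return Per-day rate.
#' @export
proliferation_rate <- function(x, age, p0, cp = 1,
                               consts = age_reference_constants()) {
  if (any(x <= 0)) stop("concentration x must be strictly positive")
  p0 * ki67_fraction(age, consts) *
    exp(cp * (1 - x / expected_total_cd4(age, consts)))
}

#' Density-dependent loss rate
#'
#' \eqn{d(X, \tau) = d_0 \, y(\tau) \, e^{c_d (X/N(\tau) - 1)}}: loss
#' accelerates with crowding.
#'
#' @inheritParams proliferation_rate
#' @param d0 loss scale (/day).
#' @param cd competition strength (default 1).
#' @return Per-day rate.
#' @export
loss_rate <- function(x, age, d0, cd = 1,
                      consts = age_reference_constants()) {
  if (any(x <= 0)) stop("concentration x must be strictly positive")
  d0 * ki67_fraction(age, consts) *
    exp(cd * (x / expected_total_cd4(age, consts) - 1))
}

#' Solve the reconstitution trajectory
#'
#' Integrates \eqn{dX/dt = \lambda_0 \lambda_{age}(\tau) \Delta(t)
#' - d(X,\tau) X + p(X,\tau) X} with \eqn{\tau = } \code{age_at_hsct} \eqn{+ t}
#' (age advances during follow-up) from \eqn{X(0) = x_0}, using an adaptive
#' Dormand-Prince 5(4) integrator (relative tolerance 1e-8, absolute 1e-6
#' cells/uL by default).
#'
#' @param params a \code{\link{structural_parameters}} object.
#' @param age_at_hsct age at transplant (days).
#' @param horizon follow-up horizon (days, > 0); ignored when \code{grid} is
#'   given.
#' @param grid output times (days, non-decreasing, >= 0); default a daily grid
#'   over the horizon.
#' @param consts reference constants.
#' @param rtol,atol solver tolerances.
#' @return A \code{cd4_trajectory}: data frame with columns \code{time}
#'   (days post-HSCT) and \code{cd4} (cells/uL), with the age at HSCT as an
#'   attribute.
#' @export
solve_trajectory <- function(params, age_at_hsct, horizon = 7 * 365,
                             grid = NULL,
                             consts = age_reference_constants(),
                             rtol = 1e-8, atol = 1e-6) {
  stop_if_negative_age(age_at_hsct)
  if (is.null(grid)) {
    if (horizon <= 0) stop("horizon must be positive")
    grid <- seq(0, horizon, by = 1)
  }
  if (any(diff(grid) < 0) || any(grid < 0)) {
    stop("grid must be non-decreasing and non-negative")
  }
  x <- cd4_solve_cpp(grid, as.numeric(params), age_at_hsct,
                     consts_vector(consts), rtol, atol)
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x))[1]
    stop(sprintf(paste0("trajectory solver failed near t = %.2f days ",
                        "(params: %s)"), grid[bad],
                 paste(sprintf("%s=%.3g", names(params), as.numeric(params)),
                       collapse = ", ")))
  }
  structure(data.frame(time = grid, cd4 = x),
            age_at_hsct = age_at_hsct, params = params,
            class = c("cd4_trajectory", "data.frame"))
}

#' Time to first reach a CD4 threshold
#'
#' Finds the first time the trajectory crosses either an absolute
#' concentration or a given fraction of the age-expected concentration
#' \eqn{N(\tau)} (with \eqn{\tau} advancing).  The crossing is bracketed on a
#' daily grid and refined by bisection on re-solves to within 0.01 days.
#'
#' @inheritParams solve_trajectory
#' @param threshold positive threshold: cells/uL, or a fraction of
#'   \eqn{N(\tau)} when \code{relative = TRUE}.
#' @param relative interpret \code{threshold} as a fraction of the
#'   age-expected total CD4 concentration.
#' @param horizon search horizon in days.
#' @return First crossing time in days, or \code{NA_real_} if the threshold
#'   is not reached within the horizon.
#' @export
time_to_threshold <- function(params, age_at_hsct, threshold,
                              relative = FALSE, horizon = 10 * 365,
                              consts = age_reference_constants(),
                              rtol = 1e-8, atol = 1e-6) {
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be a positive number")
  }
  thr_fun <- if (relative) {
    function(t) threshold * expected_total_cd4(age_at_hsct + t, consts)
  } else {
    function(t) rep_len(threshold, length(t))
  }
  traj <- solve_trajectory(params, age_at_hsct, grid = seq(0, horizon, by = 1),
                           consts = consts, rtol = rtol, atol = atol)
  above <- traj$cd4 >= thr_fun(traj$time)
  if (above[1]) return(0)
  idx <- which(above)[1]
  if (is.na(idx)) return(NA_real_)
  lo <- traj$time[idx - 1]
  hi <- traj$time[idx]
  cv <- consts_vector(consts)
  f <- function(t) {
    cd4_solve_cpp(t, as.numeric(params), age_at_hsct, cv, rtol, atol) -
      thr_fun(t)
  }
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Thymic output over follow-up
#'
#' \eqn{\lambda(t) = \lambda_0 \, \lambda_{age}(\tau) \, \Delta(t)} on a time
#' grid: zero at transplant, rising with thymic recovery and then declining
#' with thymic involution as the child ages.
#'
#' @inheritParams solve_trajectory
#' @param grid output times (days).
#' @return Data frame with columns \code{time} and \code{output}
#'   (cells/uL/day).
#' @export
thymic_output_curve <- function(params, age_at_hsct,
                                grid = seq(0, 7 * 365, by = 1),
                                consts = age_reference_constants()) {
  stop_if_negative_age(age_at_hsct)
  out <- params[["lambda0"]] *
    thymic_output_for_age(age_at_hsct + grid, consts) *
    thymic_recovery(grid, params[["lambda_h"]], params[["lambda_r"]])
  data.frame(time = grid, output = out)
}

#' Mean CD4 T-cell lifespan implied by the loss rate
#'
#' The reciprocal of the loss rate evaluated at an occupancy
#' \code{occupancy * N(age)}.  The default occupancy 0.9 is the model's
#' long-run level relative to the healthy-child expectation.
#'
#' @param age age in days.
#' @param d0 loss scale (/day).
#' @param occupancy fraction of the age-expected concentration at which the
#'   lifespan is evaluated (> 0).
#' @param cd competition strength (default 1).
#' @param consts reference constants.
#' @return Lifespan in days; increases with age.
#' @export
mean_lifespan <- function(age, d0, occupancy = 0.9, cd = 1,
                          consts = age_reference_constants()) {
  if (any(occupancy <= 0)) stop("occupancy must be positive")
  n <- expected_total_cd4(age, consts)
  1 / loss_rate(occupancy * n, age, d0, cd, consts)
}
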