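#' Damage time course
#'
#' One observed series of membrane-damage measurements at a fixed
#' temperature and nanoparticle density. Either per-time-point counts
#' (cells counted / cells damaged) or fractions may be supplied; when counts
#' are present the fraction is recomputed from them.
#'
#' @param time_min observation times in minutes, strictly increasing.
#' @param cells_counted,cells_damaged integer counts per time point
#'   (optional if \code{fraction} is given).
#' @param fraction damaged fraction per time point (optional if counts are
#'   given).
#' @param temperature_K incubation temperature.
#' @param nanoparticle_density_per_m3 initial nanoparticle density CB0.
#' @param label free-text series label.
#' @return An object of class \code{damage_timecourse}: a data.frame with
#'   columns \code{time_min}, \code{cells_counted}, \code{cells_damaged},
#'   \code{fraction} and attributes \code{temperature},
#'   \code{nanoparticle_density}, \code{label}.
#' @export
damage_timecourse <- function(time_min, cells_counted = NULL,
                              cells_damaged = NULL, fraction = NULL,
                              temperature_K, nanoparticle_density_per_m3,
                              label = "") {
  stopifnot(is.numeric(time_min), all(is.finite(time_min)),
            all(time_min >= 0))
  if (is.unsorted(time_min, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  n <- length(time_min)
  if (!is.null(cells_counted)) {
    stopifnot(length(cells_counted) == n, length(cells_damaged) == n,
              all(cells_counted >= 0), all(cells_damaged >= 0))
    if (any(cells_damaged > cells_counted))
      stop("damaged count cannot exceed counted cells", call. = FALSE)
    fraction <- ifelse(cells_counted > 0, cells_damaged / cells_counted, 0)
  } else {
    stopifnot(!is.null(fraction), length(fraction) == n,
              all(fraction >= 0), all(fraction <= 1))
    cells_counted <- rep(NA_real_, n)
    cells_damaged <- rep(NA_real_, n)
  }
  out <- data.frame(time_min = time_min, cells_counted = cells_counted,
                    cells_damaged = cells_damaged, fraction = fraction)
  attr(out, "temperature") <- temperature_K
  attr(out, "nanoparticle_density") <- nanoparticle_density_per_m3
  attr(out, "label") <- label
  class(out) <- c("damage_timecourse", "data.frame")
  out
}

#' Coefficient of determination
#'
#' \deqn{R^2 = 1 - SS_{res}/SS_{tot}} with
#' \eqn{SS_{res} = \sum (y_i - \hat y_i)^2} and
#' \eqn{SS_{tot} = \sum (y_i - \bar y)^2}. May be negative when the model
#' fits worse than the mean; equals 1 only for exact predictions.
#'
#' @param observed,predicted numeric vectors of equal length >= 2; the
#'   observations must not be all identical (zero total sum of squares).
#' @return R-squared, dimensionless.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (length(observed) < 2)
    stop("at least two points are required", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observations are all identical: R-squared undefined",
         call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Least-squares estimation of the death probability P2
#'
#' Fits the single free parameter P2 of the damage model to one observed
#' time course by minimising the sum of squared residuals on the fraction
#' scale,
#' \deqn{\sum_i \left( f_i - \frac{C_{B0} k_2(P_2)\, t_i}
#'   {C_{B0} k_2(P_2)\, t_i + 1} \right)^2,}
#' over P2 in [1e-3, 1] on a log scale (bounded scalar optimisation, fixed
#' tolerance, no randomness: identical input gives identical output).
#' Residuals and R-squared are computed on the fitted predictions. Plain
#' (unweighted) least squares is the default; inverse-variance weights by
#' the per-point count are available.
#'
#' @param timecourse a [damage_timecourse()].
#' @param medium a [medium_state()]; defaults to water at the series
#'   temperature.
#' @param condition an [experiment_condition()]; defaults to one built from
#'   the series attributes with the default particle/cell geometry.
#' @param convention sign convention for k2, see [aod_survival_model()].
#' @param time_window_min optional \code{c(min, max)} in minutes restricting
#'   which points enter the fit (e.g. to exclude a late oxidative-stress
#'   regime).
#' @param weight_by_counts logical; use per-point cell counts as weights.
#' @return An object of class \code{p2_fit}: list with \code{p2_hat},
#'   \code{k2_hat}, \code{p2_se} (Wald standard error from the curvature of
#'   the objective at the optimum; NA at a domain boundary or with fewer
#'   than 3 points), \code{eact2_hat}, \code{r_squared}, \code{residuals},
#'   \code{fitted}, \code{n_points}, \code{convention},
#'   \code{temperature}, \code{at_boundary}, \code{label}.
#' @export
fit_p2 <- function(timecourse, medium = NULL, condition = NULL,
                   convention = c("corrected", "printed"),
                   time_window_min = NULL, weight_by_counts = FALSE) {
  convention <- match.arg(convention)
  stopifnot(inherits(timecourse, "damage_timecourse"))
  temperature <- attr(timecourse, "temperature")
  cb0 <- attr(timecourse, "nanoparticle_density")
  if (is.null(medium)) medium <- medium_state(temperature)
  if (is.null(condition))
    condition <- experiment_condition(temperature, cb0)
  if (condition$nanoparticle_density <= 0)
    stop("nanoparticle density CB0 must be positive for fitting",
         call. = FALSE)
  tc <- as.data.frame(timecourse)
  if (!is.null(time_window_min)) {
    stopifnot(length(time_window_min) == 2)
    tc <- tc[tc$time_min >= time_window_min[1] &
             tc$time_min <= time_window_min[2], , drop = FALSE]
  }
  if (nrow(tc) < 2)
    stop("at least two points are required to fit P2", call. = FALSE)
  w <- if (weight_by_counts && all(is.finite(tc$cells_counted)))
    tc$cells_counted else rep(1, nrow(tc))
  t_s <- tc$time_min * 60
  obs <- tc$fraction
  sys <- pair_system_from_specs(condition$particle, condition$cell, medium,
                                condition$nanoparticle_density)
  k1 <- stationary_rate_constant(sys)
  cb0 <- condition$nanoparticle_density
  floor_p2 <- 1e-3
  sse <- function(log_p2) {
    p2 <- exp(log_p2)
    k2 <- k1 * exp(convention_exponent(p2, convention))
    sum(w * (obs - damaged_fraction(t_s, k2, cb0))^2)
  }
  at_boundary <- FALSE
  if (all(obs == 0)) {
    warning("all observed fractions are zero: P2 pinned at the lower floor",
            call. = FALSE)
    p2_hat <- floor_p2
    at_boundary <- TRUE
  } else {
    opt <- stats::optimize(sse, interval = c(log(floor_p2), 0),
                           tol = 1e-12)
    p2_hat <- exp(opt$minimum)
    # accept an interior optimum only if it beats both boundaries
    for (b in c(floor_p2, 1)) {
      if (sse(log(b)) < sse(log(p2_hat))) {
        p2_hat <- b
        at_boundary <- TRUE
      }
    }
    if (p2_hat <= floor_p2 * (1 + 1e-6)) at_boundary <- TRUE
  }
  k2_hat <- k1 * exp(convention_exponent(p2_hat, convention))
  fitted <- damaged_fraction(t_s, k2_hat, cb0)
  res <- obs - fitted
  r2 <- if (stats::var(obs) > 0) r_squared(obs, fitted) else NA_real_
  # Wald standard error from the curvature of the objective at the optimum
  # (standard nonlinear least squares); undefined at a domain boundary
  p2_se <- NA_real_
  if (!at_boundary && nrow(tc) > 2) {
    h <- 1e-4 * p2_hat
    d2 <- (sse(log(p2_hat + h)) - 2 * sse(log(p2_hat)) +
             sse(log(p2_hat - h))) / h^2
    sigma2 <- sse(log(p2_hat)) / (nrow(tc) - 1)
    if (is.finite(d2) && d2 > 0) p2_se <- sqrt(2 * sigma2 / d2)
  }
  structure(list(p2_hat = p2_hat, k2_hat = k2_hat, p2_se = p2_se,
                 eact2_hat = activation_energy_second(p2_hat, temperature),
                 r_squared = r2, residuals = res, fitted = fitted,
                 n_points = nrow(tc), convention = convention,
                 temperature = temperature, at_boundary = at_boundary,
                 label = attr(timecourse, "label")),
            class = "p2_fit")
}

#' @export
print.p2_fit <- function(x, ...) {
  cat(sprintf(
    "p2_fit%s: P2 = %.4g, k2 = %.4g m3/s, Eact2 = %.4g J, R2 = %.4f (n = %d, %s)\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$p2_hat, x$k2_hat, x$eact2_hat, x$r_squared, x$n_points, x$convention))
  invisible(x)
}

#' Activation-energy profile across temperatures
#'
#' Tabulates the effective death activation energy Eact2 = Eact1(T)/P2 for a
#' set of per-temperature fits and identifies the temperatures of maximal
#' and minimal Eact2 (maximal Eact2 = least susceptible cells).
#'
#' @param fits a list of [fit_p2()] results at distinct temperatures.
#' @return A data.frame with columns \code{temperature_K},
#'   \code{temperature_C}, \code{p2_hat}, \code{eact2_hat_J}, sorted by
#'   temperature, with attributes \code{argmax_K} and \code{argmin_K}.
#' @export
activation_energy_profile <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "p2_fit")))
  temps <- vapply(fits, function(f) f$temperature, numeric(1))
  if (anyDuplicated(temps))
    stop("fits must be at distinct temperatures", call. = FALSE)
  out <- data.frame(
    temperature_K = temps,
    temperature_C = temps - 273.15,
    p2_hat = vapply(fits, function(f) f$p2_hat, numeric(1)),
    eact2_hat_J = vapply(fits, function(f) f$eact2_hat, numeric(1)))
  out <- out[order(out$temperature_K), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "argmax_K") <- out$temperature_K[which.max(out$eact2_hat_J)]
  attr(out, "argmin_K") <- out$temperature_K[which.min(out$eact2_hat_J)]
  out
}
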