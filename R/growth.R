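#' Construct a growth series
#'
#' A growth series is the record of one experimental unit: abundance
#' (cell density or blank-corrected chlorophyll-a fluorescence) tracked
#' over time for one strain in one condition and replicate.
#'
#' @param times Numeric vector of sampling times in days; nonnegative,
#'   strictly increasing, at least 3 points.
#' @param abundances Numeric vector of positive abundances (cells/mL or
#'   blank-corrected fluorescence), same length as `times`.
#' @param strain_id Strain identifier.
#' @param condition Named list of condition values, e.g.
#'   `list(temperature = 5)` (degrees C), `list(photoperiod = 16)` (h).
#' @param replicate Replicate index.
#'
#' @return An object of class `growth_series`: a list with elements
#'   `times`, `abundances`, `strain_id`, `condition`, `replicate`.
#' @export
growth_series <- function(times, abundances, strain_id = "strain",
                          condition = list(), replicate = 1L) {
  times <- as.numeric(times)
  abundances <- as.numeric(abundances)
  if (length(times) != length(abundances))
    stop("`times` and `abundances` must have equal length")
  if (length(times) < 3L)
    stop("a growth series needs at least 3 time points, got ", length(times))
  if (anyNA(times) || anyNA(abundances))
    stop("growth series must not contain missing values")
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (any(times < 0)) stop("`times` must be nonnegative")
  if (any(abundances <= 0))
    stop("all abundances must be positive (blank-correct first?)")
  structure(
    list(times = times, abundances = abundances, strain_id = strain_id,
         condition = condition, replicate = as.integer(replicate)),
    class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("<growth_series> strain %s, replicate %d, %d points over %.1f days\n",
              x$strain_id, x$replicate, length(x$times), diff(range(x$times))))
  invisible(x)
}

#' Subtract a medium blank from raw fluorescence readings
#'
#' Chlorophyll-a fluorescence includes a background contribution from the
#' medium; the mean blank is subtracted before growth rates are fitted.
#' Readings that are nonpositive after subtraction carry no usable signal
#' and are dropped (with a warning); if fewer than 3 points remain the
#' series is unusable and an error is raised.
#'
#' @param times Sampling times in days.
#' @param raw Raw fluorescence readings, same length as `times`.
#' @param blank Mean blank fluorescence of the medium (>= 0).
#' @inheritParams growth_series
#'
#' @return A [growth_series()] with blank-corrected abundances. The number
#'   of dropped points is attached as attribute `n_dropped`.
#' @export
correct_blank <- function(times, raw, blank, strain_id = "strain",
                          condition = list(), replicate = 1L) {
  if (length(blank) != 1L || is.na(blank) || blank < 0)
    stop("`blank` must be a single nonnegative value")
  corrected <- raw - blank
  keep <- corrected > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    warning(n_dropped, " reading(s) nonpositive after blank correction; dropped")
  if (sum(keep) < 3L)
    stop("fewer than 3 usable points after blank correction (",
         sum(keep), " remain)")
  out <- growth_series(times[keep], corrected[keep], strain_id = strain_id,
                       condition = condition, replicate = replicate)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Maximum specific growth rate from the log-linear part of a growth curve
#'
#' Fits a smoothing spline to ln(abundance) versus time and takes the
#' maximum of its first derivative over the observed interval as the
#' maximum specific growth rate mu_max (per day). The smoothing penalty is
#' chosen by generalized cross-validation unless `spar` is supplied.
#' The derivative is maximized on a 200-point grid over the observed
#' time range. Series with exactly 3 points (too few for a spline) fall
#' back to the ordinary least-squares log-linear slope.
#'
#' @param series A [growth_series()].
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) selects it by GCV.
#'
#' @return A list of class `growth_rate_estimate` with elements
#'   `mu_max` (per day), `window` (c(t_start, t_end), the observed time
#'   interval bracketing the maximum slope), and `fit_quality` (residual
#'   standard deviation of the smoother on the log scale).
#' @export
fit_growth_rate <- function(series, spar = NULL) {
  stopifnot(inherits(series, "growth_series"))
  t <- series$times
  y <- log(series$abundances)
  if (any(!is.finite(y))) stop("non-finite log abundances")

  if (length(t) < 4L) {
    # spline needs >= 4 unique x; fall back to the log-linear OLS slope
    fit <- stats::lm(y ~ t)
    mu <- unname(stats::coef(fit)[2L])
    return(structure(
      list(mu_max = mu, window = range(t),
           fit_quality = stats::sd(stats::residuals(fit))),
      class = "growth_rate_estimate"))
  }

  ss <- if (is.null(spar)) stats::smooth.spline(t, y, cv = FALSE)
        else stats::smooth.spline(t, y, spar = spar)
  grid <- seq(min(t), max(t), length.out = 200L)
  slope <- stats::predict(ss, grid, deriv = 1L)$y
  i <- which.max(slope)
  # report the observed sampling interval containing the argmax
  lo <- max(t[t <= grid[i]])
  hi <- min(t[t >= grid[i]])
  if (lo == hi) {
    k <- which(t == lo)
    lo <- t[max(1L, k - 1L)]
    hi <- t[min(length(t), k + 1L)]
  }
  resid <- y - stats::predict(ss, t)$y
  structure(
    list(mu_max = slope[i], window = c(lo, hi),
         fit_quality = stats::sd(resid)),
    class = "growth_rate_estimate")
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf("mu_max = %.4f / day  (max slope in [%.2f, %.2f] d, resid sd %.3g)\n",
              x$mu_max, x$window[1], x$window[2], x$fit_quality))
  invisible(x)
}

#' Fit growth rates for a table of experimental units
#'
#' Convenience wrapper: splits a long table into experimental units
#' (strain x condition x replicate) and fits each with
#' [fit_growth_rate()].
#'
#' @param data Data frame with columns `strain_id`, `replicate`,
#'   `time_d`, `abundance`, plus any condition columns (e.g.
#'   `temperature`, `photoperiod`).
#' @param condition_cols Character vector naming the condition columns.
#' @inheritParams fit_growth_rate
#'
#' @return Data frame with one row per unit: identifiers, condition
#'   columns, `mu_max`, `window_start`, `window_end`, `fit_quality`.
#' @export
fit_growth_rates <- function(data, condition_cols = character(), spar = NULL) {
  need <- c("strain_id", "replicate", "time_d", "abundance", condition_cols)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(data[c("strain_id", "replicate", condition_cols)], drop = TRUE)
  out <- lapply(split(data, key), function(d) {
    d <- d[order(d$time_d), ]
    gs <- growth_series(d$time_d, d$abundance, strain_id = d$strain_id[1],
                        replicate = d$replicate[1])
    est <- fit_growth_rate(gs, spar = spar)
    cbind(d[1L, c("strain_id", "replicate", condition_cols), drop = FALSE],
          data.frame(mu_max = est$mu_max, window_start = est$window[1],
                     window_end = est$window[2], fit_quality = est$fit_quality))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
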