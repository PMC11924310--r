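#' Thermal performance curve value
#'
#' Evaluates the four-parameter exponential-times-quadratic thermal
#' performance curve
#' \deqn{\mu(T) = a\,e^{bT}\left[1 - \left(\frac{T - z}{w/2}\right)^2\right]}
#' which permits negative rates (mortality) outside the viable thermal
#' window \eqn{[z - w/2,\; z + w/2]}.
#'
#' @param t Temperature(s), degrees C. Vectorized.
#' @param a Rate scale (per day), > 0.
#' @param b Exponential temperature sensitivity (per degree C).
#' @param z Location of the quadratic maximum (degrees C).
#' @param w Thermal niche width (degrees C), > 0.
#'
#' @return Growth rate(s), per day.
#' @export
tpc_value <- function(t, a, b, z, w) {
  if (a <= 0) stop("`a` must be positive")
  if (w <= 0) stop("`w` must be positive")
  a * exp(b * t) * (1 - ((t - z) / (w / 2))^2)
}

#' Derived thermal traits of a fitted performance curve
#'
#' Computes, for a fitted curve restricted to the experimentally tested
#' temperature range (no extrapolation):
#' * `t_opt` — argmax of the curve on `t_range` (fine grid + local
#'   refinement with [stats::optimize()]);
#' * `mu_max` — the rate at `t_opt`;
#' * `tb80` — thermal breadth: width of the interval on which the curve
#'   is at least 80% of `mu_max`, bounds found by root bisection; a
#'   bound is clipped to the range edge (and flagged in `tb80_clipped`)
#'   when the 80% level is not crossed inside the tested range;
#' * `e_a` — activation energy (eV): slope of an Arrhenius regression of
#'   ln(mu) on \eqn{-1/(k_B T_K)} over temperatures below `t_opt` with
#'   positive rate (k_B = 8.617e-5 eV/K).
#'
#' @param params Named list or vector with `a`, `b`, `z`, `w` (see
#'   [tpc_value()]).
#' @param t_range Length-2 numeric: the tested temperature range,
#'   degrees C.
#' @param temperatures Optional tested temperatures at which the curve
#'   is evaluated for the Arrhenius regression; defaults to a 25-point
#'   grid over the rising limb.
#' @param threshold Breadth threshold as a fraction of `mu_max`
#'   (default 0.8, giving Tb80).
#'
#' @return List of class `tpc_derived`: `t_opt`, `mu_max`, `tb80`,
#'   `e_a`, `tb80_bounds` (c(t_lo, t_hi)), `tb80_clipped` (logical),
#'   `threshold`.
#' @export
derive_params <- function(params, t_range, temperatures = NULL,
                          threshold = 0.8) {
  p <- as.list(params)
  f <- function(t) tpc_value(t, p$a, p$b, p$z, p$w)
  t_range <- sort(as.numeric(t_range))
  grid <- seq(t_range[1], t_range[2], length.out = 512L)
  mu <- f(grid)
  if (all(mu <= 0)) stop("curve has no positive rates on the tested range")
  i <- which.max(mu)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-10)
  t_opt <- opt$maximum
  mu_max <- opt$objective
  if (f(t_range[1]) >= mu_max) { t_opt <- t_range[1]; mu_max <- f(t_opt) }
  if (f(t_range[2]) >= mu_max) { t_opt <- t_range[2]; mu_max <- f(t_opt) }

  lev <- threshold * mu_max
  g <- function(t) f(t) - lev
  clipped <- FALSE
  if (g(t_range[1]) < 0) {
    t_lo <- stats::uniroot(g, lower = t_range[1], upper = t_opt,
                           tol = 1e-9)$root
  } else { t_lo <- t_range[1]; clipped <- TRUE }
  if (g(t_range[2]) < 0) {
    t_hi <- stats::uniroot(g, lower = t_opt, upper = t_range[2],
                           tol = 1e-9)$root
  } else { t_hi <- t_range[2]; clipped <- TRUE }

  if (is.null(temperatures)) {
    temperatures <- seq(t_range[1], t_opt, length.out = 25L)
  }
  rising <- temperatures[temperatures < t_opt]
  e_a <- arrhenius_ea(rising, f(rising))

  structure(
    list(t_opt = t_opt, mu_max = mu_max, tb80 = t_hi - t_lo, e_a = e_a,
         tb80_bounds = c(t_lo, t_hi), tb80_clipped = clipped,
         threshold = threshold),
    class = "tpc_derived")
}

#' Activation energy by Arrhenius regression
#'
#' Regresses ln(rate) on \eqn{-1/(k_B T_K)}; the slope is the activation
#' energy in eV. Points with nonpositive rate are dropped.
#'
#' @param temperature Temperatures, degrees C.
#' @param rate Rates (per day), same length.
#' @param k_b Boltzmann constant, eV/K.
#'
#' @return Activation energy (eV), or `NA` with a warning if fewer than
#'   2 usable points remain.
#' @export
arrhenius_ea <- function(temperature, rate, k_b = 8.617e-5) {
  keep <- is.finite(rate) & rate > 0
  temperature <- temperature[keep]; rate <- rate[keep]
  if (length(rate) < 2L) {
    warning("fewer than 2 positive rates on the rising limb; E_A is NA")
    return(NA_real_)
  }
  x <- -1 / (k_b * (temperature + 273.15))
  unname(stats::coef(stats::lm(log(rate) ~ x))[2L])
}

# Multi-start grids for the nonlinear fit: z near the empirically best
# temperature, w from the observed span, a back-transformed from the
# maximum observed rate, b over a small set of plausible sensitivities.
tpc_starts <- function(temperature, rate) {
  t_best <- temperature[which.max(rate)]
  span <- diff(range(temperature))
  starts <- list()
  for (b0 in c(0, 0.05, 0.1)) {
    for (wf in c(1, 1.5, 2.5)) {
      a0 <- max(max(rate, na.rm = TRUE), 1e-3) * exp(-b0 * t_best)
      starts[[length(starts) + 1L]] <-
        list(a = a0, b = b0, z = t_best, w = wf * span)
    }
  }
  starts
}

tpc_fit_once <- function(temperature, rate, start) {
  dat <- data.frame(t = temperature, r = rate)
  tryCatch(
    minpack.lm::nlsLM(
      r ~ a * exp(b * t) * (1 - ((t - z) / (w / 2))^2),
      data = dat, start = start,
      lower = c(a = 1e-8, b = -1, z = min(temperature) - 20, w = 1e-3),
      upper = c(a = Inf, b = 1, z = max(temperature) + 20, w = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
}

#' Fit a thermal performance curve to growth rates
#'
#' Nonlinear least squares (Levenberg-Marquardt) with multi-start
#' initialization over the exponential-times-quadratic model of
#' [tpc_value()]. Derived traits are computed with [derive_params()]
#' restricted to the tested temperature range; the curve is never
#' extrapolated beyond it.
#'
#' @param rates Data frame with columns `temperature` (degrees C) and
#'   `rate` (per day); at least 5 distinct temperatures and at least one
#'   positive rate.
#'
#' @return List of class `tpc_fit`: `params` (named vector a, b, z, w),
#'   `derived` (a `tpc_derived`), `t_range`, `rss`, `fit` (the nls
#'   object), `data`.
#' @export
fit_tpc <- function(rates) {
  stopifnot(is.data.frame(rates),
            all(c("temperature", "rate") %in% names(rates)))
  rates <- rates[is.finite(rates$temperature) & is.finite(rates$rate), ]
  if (length(unique(rates$temperature)) < 5L)
    stop("need at least 5 distinct temperatures to fit a 4-parameter curve")
  if (!any(rates$rate > 0))
    stop("need at least one positive rate")
  if (stats::sd(rates$rate) == 0)
    stop("all rates identical: curve parameters are unidentifiable")

  fits <- lapply(tpc_starts(rates$temperature, rates$rate),
                 function(s) tpc_fit_once(rates$temperature, rates$rate, s))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("thermal performance curve fit failed to converge from all starts")
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  span <- diff(range(rates$temperature))
  if (cf[["w"]] > 20 * span)
    stop("fitted thermal width exceeds 20x the tested span: unidentifiable")
  t_range <- range(rates$temperature)
  der <- derive_params(as.list(cf), t_range,
                       temperatures = sort(unique(rates$temperature)))
  structure(
    list(params = cf, derived = der, t_range = t_range,
         rss = min(rss), fit = best, data = rates),
    class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("<tpc_fit>\n  params:",
      paste(sprintf("%s=%.4g", names(x$params), x$params), collapse = ", "),
      sprintf("\n  t_opt=%.2f C  mu_max=%.3f /d  tb80=%.2f C  e_a=%.3f eV\n",
              x$derived$t_opt, x$derived$mu_max, x$derived$tb80, x$derived$e_a))
  invisible(x)
}

#' Bootstrap confidence intervals for derived thermal traits
#'
#' Nonparametric case resampling of (temperature, rate) rows with
#' replacement. Each resample is refit (single start at the full-data
#' estimate) and the derived traits recomputed; intervals are the
#' 2.5/97.5 percentiles. Resamples whose fit fails are dropped and
#' counted; more than 50% failures is an error. Plain (unstratified)
#' case resampling is the default: stratifying by temperature with few
#' replicates per level shrinks the resampling variance (each stratum
#' of size n understates variance by a factor (n-1)/n) and the
#' intervals undercover; stratified resampling remains available for
#' designs with many replicates per level.
#'
#' @inheritParams fit_tpc
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed Integer seed; fixes the resampling exactly.
#' @param stratify Stratify resampling by temperature (default FALSE;
#'   see Details).
#'
#' @return List of class `tpc_bootstrap`: `point` (the full-data
#'   `tpc_fit`), `ci` (matrix with rows t_opt, mu_max, tb80, e_a, a, b,
#'   z, w and columns low, high), `n_boot`, `n_failed`, `draws`
#'   (data frame of per-resample derived traits).
#' @export
bootstrap_tpc <- function(rates, n_boot = 1000L, seed = 1L,
                          stratify = FALSE) {
  if (n_boot < 200L) stop("`n_boot` must be at least 200")
  point <- fit_tpc(rates)
  rates <- point$data
  t_range <- point$t_range
  temps <- sort(unique(rates$temperature))
  start <- as.list(point$params)
  start$w <- min(start$w, 5 * diff(t_range))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  idx_by_t <- split(seq_len(nrow(rates)), rates$temperature)
  one <- function() {
    idx <- if (stratify) {
      unlist(lapply(idx_by_t, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]))
    } else sample.int(nrow(rates), nrow(rates), replace = TRUE)
    d <- rates[idx, ]
    fit <- tpc_fit_once(d$temperature, d$rate, start)
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    der <- tryCatch(
      derive_params(as.list(cf), t_range, temperatures = temps),
      error = function(e) NULL)
    if (is.null(der)) return(NULL)
    c(t_opt = der$t_opt, mu_max = der$mu_max, tb80 = der$tb80,
      e_a = der$e_a, cf)
  }
  draws <- vector("list", n_boot)
  for (i in seq_len(n_boot)) draws[[i]] <- one()
  ok <- !vapply(draws, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > n_boot / 2)
    stop("bootstrap unstable: ", n_failed, " of ", n_boot,
         " resamples failed to fit")
  mat <- do.call(rbind, draws[ok])
  ci <- t(apply(mat, 2L, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  colnames(ci) <- c("low", "high")
  structure(
    list(point = point, ci = ci, n_boot = n_boot, n_failed = n_failed,
         draws = as.data.frame(mat)),
    class = "tpc_bootstrap")
}

#' @export
print.tpc_bootstrap <- function(x, ...) {
  print(x$point)
  cat(sprintf("  bootstrap: %d resamples (%d failed)\n", x$n_boot, x$n_failed))
  for (p in c("t_opt", "mu_max", "tb80", "e_a"))
    cat(sprintf("    %-6s 95%% CI [%.3f, %.3f]\n",
                p, x$ci[p, "low"], x$ci[p, "high"]))
  invisible(x)
}

#' Welch two-sample t test on strain-level trait values
#'
#' Compares a derived trait between origins (e.g. Arctic vs temperate)
#' using strain means as the unit of replication; unequal variances are
#' assumed (Welch-Satterthwaite degrees of freedom).
#'
#' @param group_a,group_b Numeric vectors of strain-level trait values,
#'   each with at least 2 values.
#'
#' @return List of class `welch_result`: `t`, `df`, `p` (two-sided).
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      identical(sort(group_a), sort(group_b)))
    return(structure(list(t = 0, df = length(group_a) + length(group_b) - 2,
                          p = 1), class = "welch_result"))
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value)),
    class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}
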