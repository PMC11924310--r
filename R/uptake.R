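#' Convert delta-15N to atom percent 15N
#'
#' \deqn{R = R_{ref}\,(\delta/1000 + 1), \qquad
#'   \mathrm{atom\%} = 100\,R/(1+R)}
#' where \eqn{R_{ref}} is the 15N/14N isotope ratio of the reference
#' (default 0.0036764, i.e. 0.3663 atom% 15N at delta = 0).
#'
#' @param delta delta-15N in per mil versus the reference; must be
#'   > -1000. Vectorized.
#' @param r_reference Reference isotope ratio 15N/14N.
#'
#' @return Atom percent 15N.
#' @export
delta_to_atom_percent <- function(delta, r_reference = 0.0036764) {
  if (any(delta <= -1000))
    stop("delta-15N must exceed -1000 per mil")
  r <- r_reference * (delta / 1000 + 1)
  100 * r / (1 + r)
}

#' Convert atom percent 15N to delta-15N
#'
#' Inverse of [delta_to_atom_percent()]; used when simulating the
#' delta-15N an analyzer would report for a given particulate
#' enrichment.
#'
#' @param atom_pct Atom percent 15N, in (0, 100).
#' @inheritParams delta_to_atom_percent
#'
#' @return delta-15N in per mil.
#' @export
atom_percent_to_delta <- function(atom_pct, r_reference = 0.0036764) {
  if (any(atom_pct <= 0 | atom_pct >= 100))
    stop("atom percent must lie in (0, 100)")
  r <- atom_pct / (100 - atom_pct)
  (r / r_reference - 1) * 1000
}

#' Atom percent 15N of the dissolved source pool for a tracer addition
#'
#' The added nitrate is mixed from a highly 15N-enriched stock and
#' natural-abundance nitrate: 1:1 14N:15N for additions of at most
#' 2 umol/L and 9:1 for larger additions. Any residual unlabeled nitrate
#' carried over from the washing procedure dilutes the label further.
#'
#' @param substrate Nitrate addition, umol/L. Vectorized.
#' @param enrichment Atom percent 15N of the labeled stock (default 98).
#' @param natural Atom percent 15N of unlabeled nitrate (default
#'   0.3663).
#' @param residual Residual unlabeled nitrate in the medium, umol/L
#'   (default 0.1).
#'
#' @return Atom percent 15N of the dissolved pool after mixing.
#' @export
source_atom_percent <- function(substrate, enrichment = 98,
                                natural = 0.3663, residual = 0.1) {
  frac15 <- ifelse(substrate <= 2, 0.5, 0.1)
  labeled <- substrate * (frac15 * enrichment + (1 - frac15) * natural)
  (labeled + residual * natural) / (substrate + residual)
}

#' Absolute nitrate uptake from 15N tracer enrichment
#'
#' Mass-balance mixing model: the fraction of particulate nitrogen newly
#' taken up during the incubation equals the excess enrichment of the
#' particulate pool relative to the span between baseline and source
#' pools,
#' \deqn{V_{abs} = \frac{A_{PN} - A_0}{A_{src} - A_0}\cdot
#'   \frac{PN}{\Delta t}}
#' where \eqn{A_{PN}} is the measured particulate atom% 15N (from
#' delta-15N), \eqn{A_0} the baseline (natural abundance / t0) atom%,
#' \eqn{A_{src}} the source-pool atom%, PN the particulate nitrogen and
#' \eqn{\Delta t} the incubation time.
#'
#' @param delta15n_particulate Measured particulate delta-15N, per mil.
#'   Vectorized.
#' @param pon Particulate organic nitrogen, umol N/L.
#' @param duration Incubation duration, h.
#' @param atom_pct_source Source-pool atom percent 15N.
#' @param atom_pct_baseline Baseline atom percent 15N (default 0.3663,
#'   the natural-abundance reference; supply a measured t0 value when
#'   available).
#' @inheritParams delta_to_atom_percent
#'
#' @return Absolute uptake rate V_abs, umol N / L / h.
#' @export
absolute_uptake <- function(delta15n_particulate, pon, duration,
                            atom_pct_source, atom_pct_baseline = 0.3663,
                            r_reference = 0.0036764) {
  if (any(duration <= 0)) stop("incubation duration must be positive")
  if (any(pon <= 0)) stop("particulate nitrogen must be positive")
  if (any(atom_pct_source <= atom_pct_baseline))
    stop("source pool not enriched above baseline (A_src <= A_0)")
  a_pn <- delta_to_atom_percent(delta15n_particulate, r_reference)
  (a_pn - atom_pct_baseline) / (atom_pct_source - atom_pct_baseline) *
    pon / duration
}

#' Normalize an absolute uptake rate by cell density
#'
#' @param v_abs Absolute uptake, umol N / L / h. Vectorized.
#' @param cells Cell density, cells / L; positive.
#'
#' @return Cell-normalized uptake V, umol N / h / cell.
#' @export
cell_normalize <- function(v_abs, cells) {
  if (any(cells <= 0)) stop("cell density must be positive")
  v_abs / cells
}

#' Fit Michaelis-Menten uptake kinetics
#'
#' Nonlinear least squares for \eqn{V = V_{max} S / (K_s + S)}.
#' Initialization: V_max from the maximum observed rate; K_s from the
#' substrate level at half that rate, by interpolation of per-level mean
#' rates. Confidence intervals by nonparametric case bootstrap when
#' `n_boot` > 0.
#'
#' @param s Substrate concentrations, umol/L.
#' @param v Uptake rates at `s` (any consistent unit; typically
#'   umol N / h / cell).
#' @param n_boot Bootstrap resamples for percentile CIs (0 = none).
#' @param seed Integer seed for the bootstrap.
#'
#' @return List of class `mm_fit`: `v_max`, `k_s`, `residual_sd`,
#'   `ci` (matrix or NULL), `fit`.
#' @export
fit_michaelis_menten <- function(s, v, n_boot = 0L, seed = 1L) {
  keep <- is.finite(s) & is.finite(v)
  s <- s[keep]; v <- v[keep]
  if (length(unique(s)) < 3L)
    stop("need at least 3 distinct substrate levels")
  if (all(v <= 0)) stop("all uptake rates nonpositive")

  mm_once <- function(s, v) {
    vmax0 <- max(v)
    means <- tapply(v, s, mean)
    lev <- as.numeric(names(means))
    ks0 <- tryCatch(
      stats::approx(as.numeric(means), lev, xout = vmax0 / 2, ties = mean,
                    rule = 2)$y,
      error = function(e) stats::median(lev))
    if (!is.finite(ks0) || ks0 <= 0) ks0 <- stats::median(lev)
    tryCatch(
      minpack.lm::nlsLM(v ~ vmax * s / (ks + s),
                        data = data.frame(s = s, v = v),
                        start = list(vmax = vmax0, ks = ks0),
                        lower = c(vmax = 0, ks = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  fit <- mm_once(s, v)
  if (is.null(fit)) stop("Michaelis-Menten fit failed to converge")
  cf <- stats::coef(fit)
  if (cf[["ks"]] < min(s) || cf[["ks"]] > max(s))
    warning("fitted K_s (", signif(cf[["ks"]], 3),
            ") lies outside the tested substrate range")

  ci <- NULL
  if (n_boot > 0L) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    draws <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("vmax", "ks")))
    n <- length(s)
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- mm_once(s[idx], v[idx])
      if (!is.null(f)) draws[i, ] <- stats::coef(f)
    }
    ci <- t(apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE))
    colnames(ci) <- c("low", "high")
    rownames(ci) <- c("v_max", "k_s")
  }

  structure(
    list(v_max = cf[["vmax"]], k_s = cf[["ks"]],
         residual_sd = stats::sd(stats::residuals(fit)), ci = ci, fit = fit),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> V_max = %.4g, K_s = %.4g (resid sd %.3g)\n",
              x$v_max, x$k_s, x$residual_sd))
  invisible(x)
}

#' Uptake kinetics from an isotope sample table
#'
#' Runs the mixing model and cell normalization over a table of
#' incubation records, then fits Michaelis-Menten kinetics per strain.
#'
#' @param samples Data frame with columns `strain_id`, `substrate`,
#'   `delta15n_particulate`, `pon`, `duration`, `cells`,
#'   `atom_pct_source`, and optionally `atom_pct_baseline`.
#' @inheritParams fit_michaelis_menten
#'
#' @return Data frame with one row per strain: `strain_id`, `v_max`,
#'   `k_s`, `residual_sd`, and bootstrap CI columns when `n_boot` > 0.
#' @export
uptake_kinetics <- function(samples, n_boot = 0L, seed = 1L) {
  need <- c("strain_id", "substrate", "delta15n_particulate", "pon",
            "duration", "cells", "atom_pct_source")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  a0 <- if ("atom_pct_baseline" %in% names(samples))
    samples$atom_pct_baseline else 0.3663
  v_abs <- absolute_uptake(samples$delta15n_particulate, samples$pon,
                           samples$duration, samples$atom_pct_source, a0)
  v <- cell_normalize(v_abs, samples$cells)
  out <- lapply(split(seq_len(nrow(samples)), samples$strain_id), function(ii) {
    f <- fit_michaelis_menten(samples$substrate[ii], v[ii],
                              n_boot = n_boot, seed = seed)
    row <- data.frame(strain_id = samples$strain_id[ii][1],
                      v_max = f$v_max, k_s = f$k_s,
                      residual_sd = f$residual_sd)
    if (!is.null(f$ci)) {
      row$v_max_low <- f$ci["v_max", "low"]; row$v_max_high <- f$ci["v_max", "high"]
      row$k_s_low <- f$ci["k_s", "low"]; row$k_s_high <- f$ci["k_s", "high"]
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
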