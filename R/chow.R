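#' LOWESS smoothing of a ratio curve
#'
#' Cleveland's locally weighted scatter-plot smoother: for every point, a
#' weighted linear regression over the `ceiling(fraction * n)` nearest
#' neighbours with tricube weights, optionally re-weighted by bisquare
#' robustness weights for `iterations > 0`. The local fit is evaluated at
#' every x (no interpolation shortcut), so affine input is reproduced to
#' machine precision.
#'
#' @param x strictly increasing predictor values (ELN levels).
#' @param y response values (log odds or hazard ratios).
#' @param fraction smoother span in (0, 1]; the share of points in each local
#'   neighbourhood. Default 2/3.
#' @param iterations robustness iterations (0 = plain LOWESS).
#' @param weights optional per-point precision weights, carried along for the
#'   downstream Chow scan (they do not enter the smoothing itself).
#' @return an `eln_smoothed_curve`: list with `x`, `y_raw`, `y_smooth`,
#'   `fraction`, `iterations`, `weights`.
#' @export
lowess_smooth <- function(x, y, fraction = 2 / 3, iterations = 0L,
                          weights = NULL) {
  if (length(x) < 3L || length(unique(x)) < 3L) {
    stop("LOWESS needs at least 3 distinct x values", call. = FALSE)
  }
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE)) {
    stop("x must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(weights) && length(weights) != length(x)) {
    stop("weights length differs from x", call. = FALSE)
  }
  sm <- lowess(x, y, f = fraction, iter = iterations, delta = 0)
  structure(list(x = as.numeric(x), y_raw = as.numeric(y),
                 y_smooth = as.numeric(sm$y), fraction = fraction,
                 iterations = as.integer(iterations), weights = weights),
            class = "eln_smoothed_curve")
}

#' Wrap a raw series as an (unsmoothed) curve
#'
#' Convenience constructor for feeding a raw series to [chow_scan()]:
#' `y_smooth` is set equal to `y_raw`.
#'
#' @inheritParams lowess_smooth
#' @return an `eln_smoothed_curve` with `y_smooth == y_raw`.
#' @export
as_curve <- function(x, y, weights = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE)) {
    stop("x must be strictly increasing", call. = FALSE)
  }
  structure(list(x = as.numeric(x), y_raw = as.numeric(y),
                 y_smooth = as.numeric(y), fraction = NA_real_,
                 iterations = 0L, weights = weights),
            class = "eln_smoothed_curve")
}

# Weighted residual sum of squares of a simple linear regression, via the
# centered closed form. A degenerate segment (no x spread) gets the
# intercept-only RSS.
.wrss <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  sxy <- sum(w * (x - mx) * (y - my))
  syy <- sum(w * (y - my)^2)
  if (sxx <= 0) return(syy)
  max(0, syy - sxy^2 / sxx)
}

#' Chow F test at a single candidate breakpoint
#'
#' Compares one pooled simple linear regression of `y` on `x` against two
#' segment regressions split at `k` -- left segment `x <= k`, right segment
#' `x >= k`. The candidate point itself belongs to both segments: the ratio
#' curves this test is built for bend *continuously* (the breakpoint lies on
#' both regimes' lines), and sharing the kink point makes the true kink the
#' unique location where two lines fit a noiseless bent series exactly.
#' With `p = 2` parameters per line and segment sizes `n1`, `n2`
#' (`n1 + n2 = n + 1`),
#' `F = [(RSS_pooled - (RSS_1 + RSS_2)) / p] / [(RSS_1 + RSS_2) / (n1 + n2 - 2p)]`
#' on `(p, n1 + n2 - 2p)` degrees of freedom.
#'
#' Degenerate cases are defined explicitly: if the pooled fit is already
#' exact (`RSS_pooled = 0` up to numerical tolerance), `F = 0` and `p = 1`;
#' if the segment fits are exact while the pooled fit is not, `F = +Inf` and
#' `p = 0` (an exact structural break).
#'
#' @param x predictor values.
#' @param y response values.
#' @param k candidate breakpoint: last x value of the left regime and first
#'   of the right (shared by both segments).
#' @param weights optional precision weights for all three regressions.
#' @return list with `f_stat`, `p_value`, `dof` (numerator, denominator),
#'   `rss_pooled`, `rss_left`, `rss_right`.
#' @export
chow_f <- function(x, y, k, weights = NULL) {
  stopifnot(length(x) == length(y))
  left <- x <= k
  right <- x >= k
  n1 <- sum(left); n2 <- sum(right)
  if (n1 < 3L || n2 < 3L) {
    stop("undersized segment at k = ", k,
         " (need >= 3 points on each side)", call. = FALSE)
  }
  w <- weights
  if (!is.null(w)) stopifnot(length(w) == length(x))
  rss_p <- .wrss(x, y, w)
  rss_1 <- .wrss(x[left], y[left], w[left])
  rss_2 <- .wrss(x[right], y[right], w[right])
  dof <- c(2, n1 + n2 - 4)
  # numerical zero thresholds relative to the series' own scale
  scale_ss <- sum((y - mean(y))^2) + .Machine$double.xmin
  if (rss_p <= 1e-12 * scale_ss) {
    f <- 0; p <- 1
  } else if (rss_1 + rss_2 <= 1e-9 * rss_p) {
    f <- Inf; p <- 0
  } else {
    f <- max(0, ((rss_p - rss_1 - rss_2) / dof[1]) /
               ((rss_1 + rss_2) / dof[2]))
    p <- pf(f, dof[1], dof[2], lower.tail = FALSE)
  }
  list(f_stat = f, p_value = p, dof = dof, rss_pooled = rss_p,
       rss_left = rss_1, rss_right = rss_2)
}

#' Chow-test scan for a structural break
#'
#' Evaluates [chow_f()] at every candidate breakpoint leaving at least
#' `min_segment` points per side and takes the location of the maximum F as
#' the break estimate, ties broken toward the smaller level (the less
#' resource-intensive cutoff).
#'
#' The scanned maximum of pointwise F statistics is anticonservative when its
#' largest p-value is compared to `alpha` directly, so the significance
#' decision Bonferroni-adjusts the p-value across the number of scanned
#' candidates by default (`p_adjust = "none"` restores the naive decision;
#' see the methods vignette for the measured null rates).
#'
#' Scanning the LOWESS-smoothed values (`use = "smooth"`) mimics a break scan
#' of the displayed curve but both shifts the break estimate and voids the F
#' null distribution; the default scans the raw series.
#'
#' @param curve an `eln_smoothed_curve` (from [lowess_smooth()] or
#'   [as_curve()]), or any list with elements `x` and `y`.
#' @param min_segment minimum points per segment (3 = two line parameters
#'   plus one residual degree of freedom).
#' @param alpha significance level for declaring the break real.
#' @param use scan the `"raw"` (default) or `"smooth"` series.
#' @param weights optional per-point precision weights; overrides weights
#'   stored on the curve.
#' @param p_adjust `"bonferroni"` (default) or `"none"`.
#' @return an `eln_breakpoint`: `k_hat`, `f_stat`, `p_value` (pointwise at
#'   `k_hat`), `p_adjusted`, `dof`, the RSS triple at `k_hat`, the full
#'   `candidates` table (k, F, p), `significant`, and the scan settings.
#' @export
chow_scan <- function(curve, min_segment = 3L, alpha = 0.05,
                      use = c("raw", "smooth"), weights = NULL,
                      p_adjust = c("bonferroni", "none")) {
  use <- match.arg(use)
  p_adjust <- match.arg(p_adjust)
  x <- curve$x
  y <- if (use == "smooth" && !is.null(curve$y_smooth)) curve$y_smooth
       else if (!is.null(curve$y_raw)) curve$y_raw else curve$y
  if (is.null(weights)) weights <- curve$weights
  n <- length(x)
  idx <- which(seq_len(n) >= min_segment &
                 n - seq_len(n) + 1L >= min_segment)
  if (!length(idx)) {
    stop("no candidate breakpoints: series too short for min_segment = ",
         min_segment, call. = FALSE)
  }
  ks <- x[idx]
  tests <- lapply(ks, function(k) chow_f(x, y, k, weights))
  fs <- vapply(tests, `[[`, 0, "f_stat")
  ps <- vapply(tests, `[[`, 0, "p_value")
  best <- which.max(fs) # first max: ties break toward the smaller level
  m <- length(ks)
  p_adj <- if (p_adjust == "bonferroni") min(1, ps[best] * m) else ps[best]
  structure(list(
    k_hat = ks[best],
    f_stat = fs[best],
    p_value = ps[best],
    p_adjusted = p_adj,
    dof = tests[[best]]$dof,
    rss_pooled = tests[[best]]$rss_pooled,
    rss_left = tests[[best]]$rss_left,
    rss_right = tests[[best]]$rss_right,
    candidates = data.frame(k = ks, f_stat = fs, p_value = ps),
    significant = p_adj < alpha,
    alpha = alpha, p_adjust = p_adjust, use = use,
    weighted = !is.null(weights)
  ), class = "eln_breakpoint")
}

#' @export
print.eln_breakpoint <- function(x, ...) {
  cat(sprintf("Structural break at %g (F = %.3g, pointwise P %s, %s-adjusted P %s, %ssignificant at alpha = %g)\n",
              x$k_hat, x$f_stat, format.pval(x$p_value, digits = 3),
              x$p_adjust, format.pval(x$p_adjusted, digits = 3),
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Locate the optimal ELN cutoff in a cohort
#'
#' The full cutpoint procedure: build the per-ELN-count ratio curve
#' (odds-ratio curve of stage migration against a one-node reference, or
#' hazard-ratio curve of overall survival), take its log-ratio series, smooth
#' with LOWESS (span `fraction`), and scan for the structural break with the
#' Chow test. The break location is the minimum adequate lymphadenectomy.
#'
#' The scan weighs each level's contribution by the inverse sampling variance
#' of its log ratio by default, since high-count levels hold few patients and
#' would otherwise dominate the segment residuals; the reference level (whose
#' log ratio is pinned at zero) is assigned the smallest non-reference
#' variance.
#'
#' @param records cohort `data.frame`.
#' @param curve_source `"migration"` (odds-ratio curve; default) or
#'   `"survival"` (hazard-ratio curve within `stratum`).
#' @param reference_count reference ELN count; defaults to 1 for the
#'   migration curve and 16 for the survival curve.
#' @param stratum nodal stratum for the survival curve.
#' @param adjust,histology,max_level,min_per_level passed to the curve fit.
#' @param fraction,iterations LOWESS settings.
#' @param min_segment,alpha,p_adjust Chow-scan settings.
#' @param weights `"inverse-variance"` (default), `"level-n"` or `"none"`.
#' @param scan scan the `"raw"` log-ratio series (default) or the
#'   `"smooth"`ed one.
#' @return an `eln_breakpoint` whose `provenance` element carries the ratio
#'   curve and the smoothed series that produced it.
#' @export
find_cutpoint <- function(records, curve_source = c("migration", "survival"),
                          reference_count = NULL,
                          stratum = "node-negative", adjust = "t_stage",
                          histology = NULL, max_level = 60L,
                          min_per_level = 20L, fraction = 2 / 3,
                          iterations = 0L, min_segment = 3L, alpha = 0.05,
                          weights = c("inverse-variance", "level-n", "none"),
                          scan = c("raw", "smooth"),
                          p_adjust = c("bonferroni", "none")) {
  curve_source <- match.arg(curve_source)
  weights <- match.arg(weights)
  scan <- match.arg(scan)
  p_adjust <- match.arg(p_adjust)
  if (curve_source == "migration") {
    if (is.null(reference_count)) reference_count <- 1L
    rc <- per_count_or_curve(records, reference_count = reference_count,
                             adjust = adjust, histology = histology,
                             max_level = max_level,
                             min_per_level = min_per_level)
  } else {
    if (is.null(reference_count)) reference_count <- 16L
    rc <- per_count_hr_curve(records, stratum = stratum,
                             reference_count = reference_count,
                             adjust = adjust, histology = histology,
                             max_level = max_level,
                             min_per_level = min_per_level)
  }
  w <- switch(weights,
              "inverse-variance" = {
                if (!any(rc$se > 0)) NULL else {
                  v <- rc$se^2
                  v[rc$se == 0] <- min(v[rc$se > 0])
                  1 / v
                }
              },
              "level-n" = as.numeric(rc$n),
              "none" = NULL)
  smoothed <- lowess_smooth(rc$level, rc$log_ratio, fraction = fraction,
                            iterations = iterations, weights = w)
  bp <- chow_scan(smoothed, min_segment = min_segment, alpha = alpha,
                  use = scan, p_adjust = p_adjust)
  bp$provenance <- list(
    curve = rc,
    smoothed = smoothed,
    settings = list(curve_source = curve_source,
                    reference_count = reference_count,
                    stratum = if (curve_source == "survival") stratum,
                    adjust = adjust, histology = histology,
                    max_level = max_level, min_per_level = min_per_level,
                    fraction = fraction, iterations = iterations,
                    min_segment = min_segment, alpha = alpha,
                    weights = weights, scan = scan, p_adjust = p_adjust)
  )
  bp
}
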