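# Independent oracles used to cross-check the package's own implementations.
# They deliberately share no code with the package: regressions are solved
# from explicitly written normal equations.

# Weighted simple linear regression via normal equations; returns the RSS.
oracle_wls_rss <- function(x, y, w = rep(1, length(x))) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * y)
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) {
    # no x spread: intercept-only fit
    c(sum(w * y) / sum(w), 0)
  })
  r <- y - X %*% beta
  sum(w * r^2)
}

# Brute-force Chow F: three regressions (pooled, left x <= k, right x >= k,
# the candidate shared by both segments),
# F = [(RSSp - RSS1 - RSS2)/2] / [(RSS1 + RSS2)/(n1 + n2 - 4)].
oracle_chow_f <- function(x, y, k, w = rep(1, length(x))) {
  left <- x <= k
  right <- x >= k
  rss_p <- oracle_wls_rss(x, y, w)
  rss_1 <- oracle_wls_rss(x[left], y[left], w[left])
  rss_2 <- oracle_wls_rss(x[right], y[right], w[right])
  den_df <- sum(left) + sum(right) - 4
  f <- max(0, ((rss_p - rss_1 - rss_2) / 2) / ((rss_1 + rss_2) / den_df))
  list(f = f, rss_pooled = rss_p, rss_left = rss_1, rss_right = rss_2)
}

# Brute-force LOWESS fit at a single point: weighted least squares over the
# ns nearest neighbours with tricube weights.
oracle_lowess_point <- function(x, y, xi, fraction) {
  n <- length(x)
  ns <- max(2L, min(n, floor(fraction * n + 1e-7)))
  d <- abs(x - xi)
  nb <- order(d)[seq_len(ns)]
  dmax <- max(d[nb])
  w <- if (dmax == 0) rep(1, ns) else (1 - pmin(d[nb] / dmax, 1)^3)^3
  X <- cbind(1, x[nb])
  XtWX <- t(X) %*% (w * X)
  if (abs(det(XtWX)) < 1e-300 || sum(w > 0) < 2) {
    return(sum(w * y[nb]) / sum(w))
  }
  beta <- solve(XtWX, t(X) %*% (w * y[nb]))
  beta[1] + beta[2] * xi
}

# Small all-eligible cohort constructor for interface-level tests.
toy_cohort <- function(eln, pos, months, event,
                       t_stage = rep("T3", length(eln)),
                       histology = rep("AC", length(eln))) {
  data.frame(
    patient_id = sprintf("T%04d", seq_along(eln)),
    age = 60L, sex = "male", histology = histology,
    year_group = "2013-2016", t_stage = t_stage,
    eln_count = as.integer(eln),
    positive_nodes_examined = as.integer(pos),
    observed_n_stage = as.character(
      cut(pos, c(-Inf, 0, 2, 6, Inf), labels = c("N0", "N1", "N2", "N3"))),
    true_node_positive = pos > 0,
    survival_months = months,
    death_event = as.integer(event),
    stringsAsFactors = FALSE
  )
}
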