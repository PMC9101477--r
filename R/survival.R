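#' Continuous-ELN Cox model of overall survival within a nodal stratum
#'
#' Fits a Cox proportional hazards model of overall survival on the ELN count
#' as a continuous covariate, adjusted for T stage, within the requested
#' nodal stratum (node-negative = observed N0; node-positive = N1--N3). Ties
#' are handled with the Efron approximation, the less biased choice for
#' heavily tied registry survival months. The exponentiated ELN coefficient
#' is the hazard ratio per additional node examined.
#'
#' @param records cohort `data.frame`.
#' @param stratum `"node-negative"`, `"node-positive"` or `"all"`.
#' @param adjust covariates to adjust for; `"t_stage"` or `NULL`.
#' @param histology optional histology subset.
#' @param conf_level confidence level for the Wald interval.
#' @return an `eln_cox_fit` with `hr_per_eln`, `ci95`, `p_value`, `n_used`,
#'   `events`, the stratum and the covariate coding record.
#' @export
fit_cox_continuous <- function(records,
                               stratum = c("node-negative", "node-positive",
                                           "all"),
                               adjust = "t_stage", histology = NULL,
                               conf_level = 0.95) {
  stratum <- match.arg(stratum)
  af <- subset_stratum(records, stratum, adjust, histology)
  if (sum(af$death_event) < 1L) {
    stop("zero events in the ", stratum, " stratum; the Cox partial ",
         "likelihood is undefined", call. = FALSE)
  }
  rhs <- paste(c("eln_count", adjust_terms(adjust)), collapse = " + ")
  fit <- coxph(as.formula(paste("Surv(survival_months, death_event) ~", rhs)),
               data = af, ties = "efron")
  est <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  b <- est["eln_count", ]
  structure(list(
    hr_per_eln = exp(b[["coef"]]),
    ci95 = exp(b[["coef"]] + c(-1, 1) * z * b[["se(coef)"]]),
    p_value = b[["Pr(>|z|)"]],
    n_used = nrow(af),
    events = sum(af$death_event),
    stratum = stratum,
    coefficients = est,
    coding = list(exposure = "eln_count (continuous)", adjust = adjust,
                  histology = histology, ties = "efron",
                  dropped_zero_eln = attr(af, "n_dropped_zero_eln")),
    conf_level = conf_level
  ), class = "eln_cox_fit")
}

#' @export
print.eln_cox_fit <- function(x, ...) {
  cat(sprintf("OS (%s): HR per ELN %.3f (%.0f%% CI %.3f-%.3f), P %s, n = %d, events = %d\n",
              x$stratum, x$hr_per_eln, 100 * x$conf_level, x$ci95[1],
              x$ci95[2], format.pval(x$p_value, digits = 3), x$n_used,
              x$events))
  invisible(x)
}

subset_stratum <- function(records, stratum, adjust = NULL, histology = NULL) {
  req <- c("eln_count", "positive_nodes_examined", "survival_months",
           "death_event", if (!is.null(adjust)) adjust,
           if (!is.null(histology)) "histology")
  af <- analysis_frame(records, req)
  if (!is.null(histology)) {
    af <- af[af$histology %in% histology, , drop = FALSE]
    if (nrow(af) == 0L) stop("empty histology subset", call. = FALSE)
  }
  if (any(!is.finite(af$survival_months))) {
    stop("non-finite survival times in cohort", call. = FALSE)
  }
  node_pos <- node_positive_outcome(af) == 1L
  n_zero <- attr(af, "n_dropped_zero_eln")
  af <- switch(stratum,
               "node-negative" = af[!node_pos, , drop = FALSE],
               "node-positive" = af[node_pos, , drop = FALSE],
               "all" = af)
  attr(af, "n_dropped_zero_eln") <- n_zero
  af
}

#' Per-ELN-count hazard-ratio curve beyond a reference count
#'
#' Dummy-codes the ELN count at and above `reference_count` and fits one Cox
#' model within the nodal stratum, so each level's hazard ratio is relative
#' to the reference count (HR = 1 there). This is the beyond-the-cutoff
#' survival curve: a flat curve means no additional survival benefit from
#' dissecting more nodes once the cutoff has been reached.
#'
#' Sparse levels are merged as in [per_count_or_curve()]; levels without any
#' death event cannot be estimated by partial likelihood and are merged into
#' their lower neighbour (logged).
#'
#' @inheritParams fit_cox_continuous
#' @param reference_count the anchoring ELN count; only records with
#'   `eln_count >= reference_count` enter the fit.
#' @param max_level pool counts >= this value into one top bin.
#' @param min_per_level merge levels with fewer patients than this.
#' @return an `eln_ratio_curve` with attribute `scale = "hazard-ratio"`.
#' @export
per_count_hr_curve <- function(records,
                               stratum = c("node-negative", "node-positive",
                                           "all"),
                               reference_count = 16L, adjust = "t_stage",
                               histology = NULL, max_level = 60L,
                               min_per_level = 20L, conf_level = 0.95) {
  stratum <- match.arg(stratum)
  af <- subset_stratum(records, stratum, adjust, histology)
  af <- af[af$eln_count >= reference_count, , drop = FALSE]
  if (nrow(af) == 0L) {
    stop("no records at or above reference count ", reference_count,
         call. = FALSE)
  }
  if (sum(af$death_event) < 1L) {
    stop("zero events at or above the reference count", call. = FALSE)
  }
  bins <- bin_eln_levels(af$eln_count, max_level, min_per_level)
  if (bins$levels[1] != reference_count) {
    stop("reference level is empty: no records at ELN count ",
         reference_count, call. = FALSE)
  }
  # merge event-free levels downward until every level carries an event
  repeat {
    ev <- tapply(af$death_event, bins$bin, sum)[as.character(bins$levels)]
    bad <- which(ev == 0)
    if (!length(bad) || length(bins$levels) <= 1L) break
    i <- bad[length(bad)]
    j <- if (i == 1L) 2L else i - 1L
    bins$merges <- rbind(bins$merges,
                         data.frame(from = bins$levels[i],
                                    to = bins$levels[j]))
    bins$levels <- bins$levels[-i]
    bins$bin <- bins$levels[findInterval(pmin(af$eln_count, max_level),
                                         bins$levels)]
  }
  tot <- tapply(af$death_event, bins$bin, length)[as.character(bins$levels)]
  ref_level <- bins$levels[1]
  af$.lvl <- factor(bins$bin, levels = bins$levels)
  rhs <- paste(c(".lvl", adjust_terms(adjust)), collapse = " + ")
  fit <- coxph(as.formula(paste("Surv(survival_months, death_event) ~", rhs)),
               data = af, ties = "efron")
  est <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)

  curve <- data.frame(level = bins$levels, n = as.integer(tot),
                      log_ratio = NA_real_, se = NA_real_, flag = "")
  curve$log_ratio[1] <- 0
  curve$se[1] <- 0
  for (lev in as.character(bins$levels[-1])) {
    nm <- paste0(".lvl", lev)
    i <- curve$level == as.integer(lev)
    curve$log_ratio[i] <- est[nm, "coef"]
    curve$se[i] <- est[nm, "se(coef)"]
  }
  curve$ratio <- exp(curve$log_ratio)
  curve$lo <- c(NA_real_, exp(curve$log_ratio[-1] - z * curve$se[-1]))
  curve$hi <- c(NA_real_, exp(curve$log_ratio[-1] + z * curve$se[-1]))
  curve <- curve[, c("level", "n", "ratio", "lo", "hi", "log_ratio", "se",
                     "flag")]
  structure(curve,
            reference_count = as.integer(ref_level),
            scale = "hazard-ratio",
            merges = bins$merges,
            coding = list(stratum = stratum, adjust = adjust,
                          histology = histology, max_level = max_level,
                          min_per_level = min_per_level, ties = "efron"),
            class = c("eln_ratio_curve", "data.frame"))
}

#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit estimator of overall survival for one group, with Greenwood
#' standard errors, the median survival time and its confidence interval by
#' inverting the pointwise survival band (the Brookmeyer--Crowley
#' construction), and the 60-month (five-year) survival read directly off the
#' step function.
#'
#' @param records cohort `data.frame` with `survival_months` and
#'   `death_event` columns.
#' @param label group label carried into the summary.
#' @param conf_level confidence level.
#' @return an `eln_km_summary` with the step function (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `lo`, `hi`), `median_months` with CI,
#'   `survival_at_60mo` with CI, `n` and `events`. An unreached median is
#'   `NA`.
#' @export
km_estimate <- function(records, label = "all", conf_level = 0.95) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("cannot estimate survival for an empty group", call. = FALSE)
  }
  req <- c("survival_months", "death_event")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(records$survival_months))) {
    stop("non-finite survival times", call. = FALSE)
  }
  fit <- survfit(Surv(survival_months, death_event) ~ 1, data = records,
                 conf.int = conf_level, conf.type = "log")
  tab <- summary(fit)$table
  s60 <- summary(fit, times = 60, extend = TRUE)
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv, lo = fit$lower, hi = fit$upper)
  structure(list(
    label = label,
    steps = steps,
    median_months = unname(tab["median"]),
    median_ci95 = unname(c(tab[grep("LCL$", names(tab))],
                           tab[grep("UCL$", names(tab))])),
    survival_at_60mo = s60$surv,
    survival_at_60mo_ci95 = c(s60$lower, s60$upper),
    n = nrow(records),
    events = sum(records$death_event),
    conf_level = conf_level
  ), class = "eln_km_summary")
}

#' @export
print.eln_km_summary <- function(x, ...) {
  med <- if (is.na(x$median_months)) "not reached" else
    sprintf("%.1f months (%.1f-%.1f)", x$median_months, x$median_ci95[1],
            x$median_ci95[2])
  cat(sprintf("KM [%s]: n = %d, events = %d, median %s, 5-year %.1f%%\n",
              x$label, x$n, x$events, med, 100 * x$survival_at_60mo))
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' @param records cohort `data.frame` with `survival_months` and
#'   `death_event`.
#' @param group grouping vector (length `nrow(records)`) or the name of a
#'   column in `records`.
#' @return an `eln_logrank` with `chi_square`, `df` (groups - 1) and
#'   `p_value`.
#' @export
logrank_test <- function(records, group) {
  if (is.character(group) && length(group) == 1L &&
      group %in% names(records)) {
    group <- records[[group]]
  }
  stopifnot(length(group) == nrow(records))
  g <- factor(group)
  if (nlevels(g) < 2L) {
    stop("log-rank test needs at least two groups", call. = FALSE)
  }
  if (sum(records$death_event) < 1L) {
    stop("log-rank test needs at least one event", call. = FALSE)
  }
  dat <- data.frame(time = records$survival_months,
                    event = records$death_event, g = g)
  sd <- survdiff(Surv(time, event) ~ g, data = dat)
  df <- nlevels(g) - 1L
  structure(list(chi_square = unname(sd$chisq), df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "eln_logrank")
}

#' @export
print.eln_logrank <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square %.3f on %d df, P %s\n", x$chi_square,
              x$df, format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Kaplan-Meier validation at a cutoff
#'
#' Dichotomizes the cohort at `eln_count >= cutoff` within a nodal stratum
#' and compares the two survival curves: per-side KM summaries and the
#' log-rank test. A cutoff that improves staging should show better survival
#' in the >= cutoff arm of the node-negative stratum, because under-staged
#' (truly node-positive but missed) patients concentrate below the cutoff.
#'
#' @param records cohort `data.frame`.
#' @param cutoff ELN count splitting the cohort.
#' @param stratum optional nodal stratum (`"node-negative"`,
#'   `"node-positive"`, `"all"`).
#' @return an `eln_km_comparison`: list with `above`, `below`
#'   ([km_estimate()] summaries), `logrank` and `cutoff`.
#' @export
km_compare_at_cutoff <- function(records, cutoff, stratum = "all") {
  af <- subset_stratum(records, match.arg(stratum, c("node-negative",
                                                     "node-positive",
                                                     "all")))
  ge <- af$eln_count >= cutoff
  if (!any(ge) || all(ge)) {
    stop("one-sided split: cutoff ", cutoff, " leaves an empty group",
         call. = FALSE)
  }
  above <- km_estimate(af[ge, , drop = FALSE],
                       label = sprintf("ELN >= %d", cutoff))
  below <- km_estimate(af[!ge, , drop = FALSE],
                       label = sprintf("ELN < %d", cutoff))
  lr <- logrank_test(af, ifelse(ge, "above", "below"))
  structure(list(above = above, below = below, logrank = lr,
                 cutoff = cutoff, stratum = stratum),
            class = "eln_km_comparison")
}

#' @export
print.eln_km_comparison <- function(x, ...) {
  cat(sprintf("Survival at the %d-ELN cutoff (%s stratum):\n", x$cutoff,
              x$stratum))
  print(x$above); print(x$below); print(x$logrank)
  invisible(x)
}
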