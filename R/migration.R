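#' Continuous-ELN stage-migration model
#'
#' Fits the logistic regression of observed nodal positivity (node-negative
#' vs node-positive) on the ELN count as a continuous covariate, adjusted for
#' T stage (TX kept as its own category). The exponentiated ELN coefficient
#' is the odds ratio of a node-positive call per additional node examined --
#' the stage-migration gradient.
#'
#' Records with `eln_count == 0` are dropped (with a logged count) because the
#' per-count design references one examined node. Wald confidence limits and
#' p-value are reported for the ELN coefficient.
#'
#' @param records cohort `data.frame`.
#' @param adjust covariates to adjust for; `"t_stage"` (default) or `NULL`
#'   for a crude model.
#' @param histology optional histology subset (`"AC"`, `"SCC"`, `"other"`).
#' @param conf_level confidence level for the Wald interval.
#' @return an `eln_logistic_fit` with `or_per_eln`, `ci95`, `p_value`,
#'   `n_used`, the full coefficient table and the covariate coding record.
#' @export
fit_continuous_or <- function(records, adjust = "t_stage", histology = NULL,
                              conf_level = 0.95) {
  req <- c("eln_count", "positive_nodes_examined",
           if (!is.null(adjust)) adjust, if (!is.null(histology)) "histology")
  af <- analysis_frame(records, req)
  if (!is.null(histology)) {
    af <- af[af$histology %in% histology, , drop = FALSE]
    if (nrow(af) == 0L) {
      stop("empty histology subset: ", paste(histology, collapse = ", "),
           call. = FALSE)
    }
  }
  y <- node_positive_outcome(af)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; both node-negative and node-positive ",
         "records are required", call. = FALSE)
  }
  rhs <- paste(c("eln_count", adjust_terms(adjust)), collapse = " + ")
  fit <- glm(as.formula(paste("y ~", rhs)), family = binomial(), data = af)
  check_separation(fit)
  est <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  b <- est["eln_count", ]
  structure(list(
    or_per_eln = exp(b[["Estimate"]]),
    ci95 = exp(b[["Estimate"]] + c(-1, 1) * z * b[["Std. Error"]]),
    p_value = b[["Pr(>|z|)"]],
    n_used = nrow(af),
    coefficients = est,
    coding = list(outcome = "observed node-positive (vs node-negative)",
                  exposure = "eln_count (continuous)",
                  adjust = adjust, histology = histology,
                  dropped_zero_eln = attr(af, "n_dropped_zero_eln")),
    conf_level = conf_level
  ), class = "eln_logistic_fit")
}

#' @export
print.eln_logistic_fit <- function(x, ...) {
  cat(sprintf("Stage migration: OR per ELN %.3f (%.0f%% CI %.3f-%.3f), P %s, n = %d\n",
              x$or_per_eln, 100 * x$conf_level, x$ci95[1], x$ci95[2],
              format.pval(x$p_value, digits = 3), x$n_used))
  invisible(x)
}

# Detect (quasi-)complete separation in the exposure terms of a glm fit and
# fail loudly naming the covariate rather than returning a meaningless Wald
# interval. Nuisance adjustment dummies (e.g. a nearly empty T-stage
# category) are allowed to be weakly identified; only the terms the result
# is about must be estimable.
check_separation <- function(fit, pattern = "^eln_count$") {
  est <- summary(fit)$coefficients
  keep <- grepl(pattern, rownames(est))
  bad <- keep & (!is.finite(est[, "Estimate"]) |
                   abs(est[, "Estimate"]) > 15 |
                   est[, "Std. Error"] > 100)
  if (any(bad)) {
    stop("complete or quasi-complete separation involving covariate(s): ",
         paste(rownames(est)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(fit)
}

#' Per-ELN-count odds-ratio curve
#'
#' Dummy-codes the ELN count and fits one logistic model of observed nodal
#' positivity with the level containing `reference_count` as the reference,
#' optionally adjusted for T stage. Counts at or above `max_level` are pooled
#' into a top bin and levels thinner than `min_per_level` are merged into
#' their nearest lower level (merges are logged in the result). The returned
#' curve is the odds ratio of a node-positive call at each examined-node
#' level versus the reference -- the raw material for cutpoint detection.
#'
#' Levels that are all-positive or all-negative cannot be estimated by
#' maximum likelihood; their OR is reported from the Haldane--Anscombe
#' 0.5-corrected 2x2 table against the reference level and flagged.
#'
#' @inheritParams fit_continuous_or
#' @param reference_count ELN count anchoring the curve (OR = 1 there).
#' @param max_level pool counts >= this value into one top bin.
#' @param min_per_level merge levels with fewer patients than this.
#' @return an `eln_ratio_curve`: a `data.frame` with one row per level
#'   (`level`, `n`, `ratio`, `lo`, `hi`, `log_ratio`, `se`, `flag`) carrying
#'   attributes `reference_count`, `scale = "odds-ratio"` and `merges`.
#' @export
per_count_or_curve <- function(records, reference_count = 1L,
                               adjust = "t_stage", histology = NULL,
                               max_level = 60L, min_per_level = 20L,
                               conf_level = 0.95) {
  req <- c("eln_count", "positive_nodes_examined",
           if (!is.null(adjust)) adjust, if (!is.null(histology)) "histology")
  af <- analysis_frame(records, req)
  if (!is.null(histology)) {
    af <- af[af$histology %in% histology, , drop = FALSE]
    if (nrow(af) == 0L) {
      stop("empty histology subset", call. = FALSE)
    }
  }
  y <- node_positive_outcome(af)
  bins <- bin_eln_levels(af$eln_count, max_level, min_per_level)
  if (!any(af$eln_count <= reference_count)) {
    stop("reference level is empty: no records at ELN count ",
         reference_count, " or below", call. = FALSE)
  }
  # if the reference count was merged upward, use the bin that absorbed it
  ref_level <- bins$levels[max(1L, findInterval(reference_count,
                                                bins$levels))]

  pos <- tapply(y, bins$bin, sum)[as.character(bins$levels)]
  tot <- tapply(y, bins$bin, length)[as.character(bins$levels)]
  neg <- tot - pos
  degenerate <- (pos == 0L | neg == 0L) & bins$levels != ref_level
  if (pos[as.character(ref_level)] == 0L || neg[as.character(ref_level)] == 0L) {
    stop("reference level has a single outcome class; choose another ",
         "reference_count", call. = FALSE)
  }

  keep_rows <- !(bins$bin %in% bins$levels[degenerate])
  lvl_f <- factor(bins$bin[keep_rows], levels = c(ref_level,
                  setdiff(bins$levels[!degenerate], ref_level)))
  dat <- af[keep_rows, , drop = FALSE]
  dat$.lvl <- lvl_f
  dat$.y <- y[keep_rows]
  rhs <- paste(c(".lvl", adjust_terms(adjust)), collapse = " + ")
  fit <- glm(as.formula(paste(".y ~", rhs)), family = binomial(), data = dat)
  check_separation(fit, pattern = "^\\.lvl")
  est <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)

  curve <- data.frame(level = bins$levels,
                      n = as.integer(tot),
                      log_ratio = NA_real_, se = NA_real_,
                      flag = ifelse(degenerate, "haldane-anscombe", ""))
  curve$log_ratio[curve$level == ref_level] <- 0
  curve$se[curve$level == ref_level] <- 0
  for (lev in setdiff(levels(lvl_f), as.character(ref_level))) {
    nm <- paste0(".lvl", lev)
    i <- curve$level == as.integer(lev)
    curve$log_ratio[i] <- est[nm, "Estimate"]
    curve$se[i] <- est[nm, "Std. Error"]
  }
  if (any(degenerate)) {
    a1 <- pos[as.character(ref_level)]; b1 <- neg[as.character(ref_level)]
    for (lev in bins$levels[degenerate]) {
      i <- curve$level == lev
      a <- pos[as.character(lev)]; b <- neg[as.character(lev)]
      curve$log_ratio[i] <- log(((a + 0.5) * (b1 + 0.5)) /
                                  ((b + 0.5) * (a1 + 0.5)))
      curve$se[i] <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) +
                            1 / (a1 + 0.5) + 1 / (b1 + 0.5))
    }
  }
  curve$ratio <- exp(curve$log_ratio)
  curve$lo <- ifelse(curve$level == ref_level, NA_real_,
                     exp(curve$log_ratio - z * curve$se))
  curve$hi <- ifelse(curve$level == ref_level, NA_real_,
                     exp(curve$log_ratio + z * curve$se))
  curve <- curve[, c("level", "n", "ratio", "lo", "hi", "log_ratio", "se",
                     "flag")]
  structure(curve,
            reference_count = as.integer(ref_level),
            scale = "odds-ratio",
            merges = bins$merges,
            coding = list(adjust = adjust, histology = histology,
                          max_level = max_level,
                          min_per_level = min_per_level,
                          dropped_zero_eln = attr(af, "n_dropped_zero_eln")),
            class = c("eln_ratio_curve", "data.frame"))
}

#' @export
print.eln_ratio_curve <- function(x, ...) {
  cat(sprintf("%s curve: %d levels, reference at %d\n",
              attr(x, "scale"), nrow(x), attr(x, "reference_count")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
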