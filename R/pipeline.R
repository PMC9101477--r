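#' Validate a cohort table against the analysis schema
#'
#' Checks column presence, types and value ranges for the patient-level
#' cohort schema: `eln_count >= 0`, `positive_nodes_examined` between 0 and
#' `eln_count`, `death_event` in \{0, 1\}, non-negative survival months, and
#' N-stage consistency (`N0` exactly when no positive node was examined).
#'
#' @param cohort a `data.frame` or the path of a cohort CSV.
#' @return a `data.frame` of violations (`row`, `column`, `rule`, `message`);
#'   zero rows means the table is valid.
#' @export
validate_schema <- function(cohort) {
  if (is.character(cohort)) {
    if (!file.exists(cohort)) {
      stop("cannot read cohort file: ", cohort, call. = FALSE)
    }
    cohort <- read_cohort(cohort)
  }
  stopifnot(is.data.frame(cohort))
  v <- list()
  note <- function(row, column, rule, message) {
    v[[length(v) + 1L]] <<- data.frame(row = row, column = column,
                                       rule = rule, message = message)
  }
  required <- c("eln_count", "positive_nodes_examined", "observed_n_stage",
                "t_stage", "histology", "survival_months", "death_event")
  for (col in setdiff(required, names(cohort))) {
    note(NA_integer_, col, "missing-column",
         paste0("required column '", col, "' is absent"))
  }
  bad_rows <- function(mask) which(!is.na(mask) & mask)
  if (all(c("eln_count") %in% names(cohort))) {
    if (!is.numeric(cohort$eln_count)) {
      note(NA_integer_, "eln_count", "type", "eln_count must be numeric")
    } else {
      for (r in bad_rows(cohort$eln_count < 0)) {
        note(r, "eln_count", "range", "eln_count must be >= 0")
      }
    }
  }
  if (all(c("eln_count", "positive_nodes_examined") %in% names(cohort)) &&
      is.numeric(cohort$positive_nodes_examined) &&
      is.numeric(cohort$eln_count)) {
    for (r in bad_rows(cohort$positive_nodes_examined > cohort$eln_count)) {
      note(r, "positive_nodes_examined", "range",
           "positive_nodes_examined exceeds eln_count")
    }
    for (r in bad_rows(cohort$positive_nodes_examined < 0)) {
      note(r, "positive_nodes_examined", "range",
           "positive_nodes_examined must be >= 0")
    }
  }
  if (all(c("observed_n_stage", "positive_nodes_examined") %in%
            names(cohort)) && is.numeric(cohort$positive_nodes_examined)) {
    mism <- (cohort$observed_n_stage == "N0") !=
      (cohort$positive_nodes_examined == 0)
    for (r in bad_rows(mism)) {
      note(r, "observed_n_stage", "consistency",
           "observed_n_stage must be N0 exactly when no positive node was examined")
    }
  }
  if ("death_event" %in% names(cohort)) {
    if (!is.numeric(cohort$death_event) &&
        !is.logical(cohort$death_event)) {
      note(NA_integer_, "death_event", "type",
           "death_event must be 0/1 or logical")
    } else {
      for (r in bad_rows(!(as.numeric(cohort$death_event) %in% c(0, 1)))) {
        note(r, "death_event", "range", "death_event must be 0 or 1")
      }
    }
  }
  if ("survival_months" %in% names(cohort)) {
    if (!is.numeric(cohort$survival_months)) {
      note(NA_integer_, "survival_months", "type",
           "survival_months must be numeric")
    } else {
      for (r in bad_rows(cohort$survival_months < 0)) {
        note(r, "survival_months", "range", "survival_months must be >= 0")
      }
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(row = integer(), column = character(), rule = character(),
               message = character())
}

#' Run the full cutpoint analysis end to end
#'
#' Sequences the whole pipeline on a cohort table: schema validation,
#' eligibility filtering, descriptives, continuous stage-migration and
#' survival fits overall and per histology, cutpoint detection on the
#' odds-ratio curve, Kaplan-Meier validation at the cutoff per nodal stratum,
#' and beyond-cutoff hazard-ratio curves. Every section of the report records
#' the operation that produced it (`op` key), so each number is traceable.
#'
#' @param cohort cohort `data.frame` or CSV path.
#' @param config named list overriding analysis settings: `rules`
#'   (eligibility rules), `adjust`, `reference_count`, `max_level`,
#'   `min_per_level`, `fraction`, `iterations`, `min_segment`, `alpha`,
#'   `weights`, `scan`, `p_adjust`, `cutoff` (force a cutoff instead of the
#'   detected one), `histologies`.
#' @return an `eln_analysis_report` (nested list; see [write_report()]).
#' @export
run_full_analysis <- function(cohort, config = list()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cfg <- modifyList(list(
    rules = seer_eligibility_rules(), adjust = "t_stage",
    reference_count = 1L, max_level = 60L, min_per_level = 20L,
    fraction = 2 / 3, iterations = 0L, min_segment = 3L, alpha = 0.05,
    weights = "inverse-variance", scan = "raw", p_adjust = "bonferroni",
    cutoff = NULL, histologies = NULL
  ), config)

  violations <- validate_schema(cohort)
  if (nrow(violations)) {
    stop("cohort fails schema validation (", nrow(violations),
         " violation(s)); first: ", violations$message[1],
         if (!is.na(violations$row[1]))
           paste0(" [row ", violations$row[1], "]"),
         call. = FALSE)
  }

  elig <- apply_eligibility(cohort, cfg$rules)
  records <- elig$records
  if (is.null(cfg$histologies)) {
    cfg$histologies <- intersect(c("AC", "SCC", "other"),
                                 unique(records$histology))
  }

  section <- function(op, value) list(op = op, value = value)
  try_fit <- function(op, expr) {
    tryCatch(section(op, expr),
             error = function(e) section(op, list(error = conditionMessage(e))))
  }

  hist_strata <- c(list(overall = NULL),
                   setNames(as.list(cfg$histologies), cfg$histologies))
  migration <- lapply(hist_strata, function(h) {
    try_fit("elncut::fit_continuous_or",
            unclass_fit(fit_continuous_or(records, adjust = cfg$adjust,
                                          histology = h)))
  })
  cox <- lapply(c("node-negative", "node-positive"), function(s) {
    lapply(hist_strata, function(h) {
      try_fit("elncut::fit_cox_continuous",
              unclass_fit(fit_cox_continuous(records, stratum = s,
                                             adjust = cfg$adjust,
                                             histology = h)))
    })
  })
  names(cox) <- c("node-negative", "node-positive")

  cutpoint <- find_cutpoint(records, curve_source = "migration",
                            reference_count = cfg$reference_count,
                            adjust = cfg$adjust, max_level = cfg$max_level,
                            min_per_level = cfg$min_per_level,
                            fraction = cfg$fraction,
                            iterations = cfg$iterations,
                            min_segment = cfg$min_segment, alpha = cfg$alpha,
                            weights = cfg$weights, scan = cfg$scan,
                            p_adjust = cfg$p_adjust)
  cutoff <- if (!is.null(cfg$cutoff)) cfg$cutoff else cutpoint$k_hat

  km <- lapply(c("node-negative", "node-positive"), function(s) {
    try_fit("elncut::km_compare_at_cutoff",
            unclass_km_comparison(km_compare_at_cutoff(records, cutoff,
                                                       stratum = s)))
  })
  names(km) <- c("node-negative", "node-positive")

  beyond <- lapply(c("node-negative", "node-positive"), function(s) {
    try_fit("elncut::per_count_hr_curve",
            curve_as_list(per_count_hr_curve(records, stratum = s,
                                             reference_count = cutoff,
                                             adjust = cfg$adjust,
                                             max_level = cfg$max_level,
                                             min_per_level = cfg$min_per_level)))
  })
  names(beyond) <- c("node-negative", "node-positive")

  beyond_trend <- lapply(c("node-negative", "node-positive"), function(s) {
    try_fit("elncut::fit_cox_continuous", {
      sub <- records[records$eln_count >= cutoff, , drop = FALSE]
      unclass_fit(fit_cox_continuous(sub, stratum = s, adjust = cfg$adjust))
    })
  })
  names(beyond_trend) <- c("node-negative", "node-positive")

  structure(list(
    eligibility = section("elncut::apply_eligibility",
                          unclass(elig$report)),
    descriptives = section("elncut::summarize_cohort",
                           summary_as_list(summarize_cohort(records))),
    migration = migration,
    survival_continuous = cox,
    cutpoint = section("elncut::find_cutpoint", breakpoint_as_list(cutpoint)),
    cutoff_used = section(if (is.null(cfg$cutoff)) "elncut::find_cutpoint"
                          else "config", cutoff),
    km_at_cutoff = km,
    beyond_cutoff_hr = beyond,
    beyond_cutoff_trend = beyond_trend,
    meta = list(n_input = nrow(cohort), settings = cfg[setdiff(names(cfg),
                                                               "rules")],
                package_version = as.character(utils::packageVersion("elncut")))
  ), class = "eln_analysis_report")
}

# ---- plain-list serializers (JSON-friendly, provenance preserved) ----

unclass_fit <- function(f) {
  f <- unclass(f)
  f$coefficients <- as.data.frame(f$coefficients)
  f$coefficients <- cbind(term = rownames(f$coefficients),
                          f$coefficients, row.names = NULL)
  f
}

curve_as_list <- function(rc) {
  list(reference_count = attr(rc, "reference_count"),
       scale = attr(rc, "scale"),
       merges = attr(rc, "merges"),
       levels = as.data.frame(rc))
}

breakpoint_as_list <- function(bp) {
  out <- unclass(bp)
  if (!is.null(out$provenance)) {
    out$provenance <- list(
      curve = curve_as_list(out$provenance$curve),
      smoothed = out$provenance$smoothed[c("x", "y_raw", "y_smooth",
                                           "fraction", "iterations")],
      settings = out$provenance$settings
    )
  }
  out
}

summary_as_list <- function(s) {
  s <- unclass(s)
  for (nm in grep("^by_", names(s), value = TRUE)) {
    if (!is.null(s[[nm]]) && inherits(s[[nm]], "table")) {
      s[[nm]] <- as.list(setNames(as.integer(s[[nm]]), names(s[[nm]])))
    }
  }
  s$eln_overall <- as.list(s$eln_overall)
  s
}

unclass_km_comparison <- function(kc) {
  list(cutoff = kc$cutoff, stratum = kc$stratum,
       above = unclass(kc$above), below = unclass(kc$below),
       logrank = unclass(kc$logrank))
}

#' Write an analysis report bundle
#'
#' Serializes an [run_full_analysis()] report to `report.json` in `out_dir`,
#' plus tidy CSVs for the ratio curves and KM step functions.
#'
#' @param report an `eln_analysis_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "eln_analysis_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  cp <- report$cutpoint$value$provenance
  if (!is.null(cp)) {
    write.csv(cp$curve$levels, file.path(out_dir, "or_curve.csv"),
              row.names = FALSE)
    write.csv(data.frame(x = cp$smoothed$x, y_raw = cp$smoothed$y_raw,
                         y_smooth = cp$smoothed$y_smooth),
              file.path(out_dir, "or_curve_smoothed.csv"), row.names = FALSE)
  }
  for (s in names(report$km_at_cutoff)) {
    val <- report$km_at_cutoff[[s]]$value
    if (is.null(val$error)) {
      steps <- rbind(cbind(group = val$above$label, val$above$steps),
                     cbind(group = val$below$label, val$below$steps))
      write.csv(steps, file.path(out_dir, paste0("km_", s, ".csv")),
                row.names = FALSE)
    }
  }
  invisible(out_dir)
}
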