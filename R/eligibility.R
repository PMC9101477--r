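#' Declarative eligibility rules
#'
#' An eligibility rule names the field it inspects and the predicate a record
#' must satisfy to stay in the cohort; `NA` predicate results drop the record.
#' Rules are applied in order, each counted against the records surviving the
#' previous rules, so the resulting attrition ledger is auditable.
#'
#' @param name human-readable rule name (appears in the attrition ledger).
#' @param field column the rule inspects.
#' @param keep function of the column vector returning a logical keep mask.
#' @return an object of class `eln_eligibility_rule`.
#' @export
eligibility_rule <- function(name, field, keep) {
  stopifnot(is.character(name), is.character(field), is.function(keep))
  structure(list(name = name, field = field, keep = keep),
            class = "eln_eligibility_rule")
}

# Built-in rules, in the order the source-registry criteria are stated:
# neoadjuvant radiation first, then the three "unknown" exclusions.
.eligibility_registry <- function() {
  list(
    neoadjuvant_radiation = eligibility_rule(
      "surgery alone (no radiation prior to surgery)", "rad_sequence",
      function(x) !is.na(x) & x %in% c("before", "before_surgery")
    ),
    known_nodes_examined = eligibility_rule(
      "unknown regional nodes examined", "eln_count",
      function(x) !is.na(x) & x >= 0
    ),
    known_nodes_positive = eligibility_rule(
      "unknown regional nodes positive", "positive_nodes_examined",
      function(x) !is.na(x) & x >= 0
    ),
    known_survival = eligibility_rule(
      "unknown survival time", "survival_months",
      function(x) !is.na(x) & x >= 0
    )
  )
}

#' Standard registry eligibility rule set
#'
#' The inclusion/exclusion criteria for an nCRT esophagectomy registry
#' cohort: radiation before surgery, and known nodes examined, nodes
#' positive and survival time. Records with `eln_count == 0` are *kept*
#' (zero is a known value); the analysis layer drops them later because the
#' one-node reference design needs at least one examined node.
#'
#' @param include_treatment include the radiation-before-surgery rule; the
#'   synthetic cohorts are all-neoadjuvant by construction and carry no
#'   treatment-sequence column, so this defaults to `FALSE`.
#' @return list of [eligibility_rule()] objects.
#' @export
seer_eligibility_rules <- function(include_treatment = FALSE) {
  reg <- .eligibility_registry()
  keep <- c(if (include_treatment) "neoadjuvant_radiation",
            "known_nodes_examined", "known_nodes_positive", "known_survival")
  reg[keep]
}

#' Apply eligibility rules and report attrition
#'
#' @param records raw cohort `data.frame` (missing values as `NA`).
#' @param rules list of [eligibility_rule()] objects, or a character vector of
#'   built-in rule names (`"neoadjuvant_radiation"`, `"known_nodes_examined"`,
#'   `"known_nodes_positive"`, `"known_survival"`).
#' @return list with `records` (retained rows) and `report`, an
#'   `eln_eligibility_report` with `n_input`, `n_retained` and the ordered
#'   exclusion ledger; counts reconcile exactly
#'   (`n_input == n_retained + sum(removed)`).
#' @export
apply_eligibility <- function(records, rules = seer_eligibility_rules()) {
  stopifnot(is.data.frame(records))
  if (is.character(rules)) {
    reg <- .eligibility_registry()
    unknown <- setdiff(rules, names(reg))
    if (length(unknown)) {
      stop("unknown eligibility rule name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    rules <- reg[rules]
  }
  if (!all(vapply(rules, inherits, TRUE, "eln_eligibility_rule"))) {
    stop("rules must be eligibility_rule objects or built-in rule names",
         call. = FALSE)
  }
  n_input <- nrow(records)
  ledger <- data.frame(rule = character(), removed = integer())
  for (rule in rules) {
    if (!rule$field %in% names(records)) {
      stop("eligibility rule '", rule$name,
           "' references a column absent from the cohort: ", rule$field,
           call. = FALSE)
    }
    keep <- rule$keep(records[[rule$field]])
    keep[is.na(keep)] <- FALSE
    ledger <- rbind(ledger,
                    data.frame(rule = rule$name, removed = sum(!keep)))
    records <- records[keep, , drop = FALSE]
  }
  report <- structure(list(n_input = n_input, n_retained = nrow(records),
                           exclusions = ledger),
                      class = "eln_eligibility_report")
  list(records = records, report = report)
}

#' @export
print.eln_eligibility_report <- function(x, ...) {
  cat("Eligibility:", x$n_input, "records in,", x$n_retained, "retained\n")
  if (nrow(x$exclusions)) {
    for (i in seq_len(nrow(x$exclusions))) {
      cat(sprintf("  - %s: %d removed\n", x$exclusions$rule[i],
                  x$exclusions$removed[i]))
    }
  }
  invisible(x)
}
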