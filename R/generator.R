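#' Configuration for the synthetic nCRT esophagectomy cohort generator
#'
#' Bundles every parameter of the data-generating model behind
#' [generate_cohort()] and validates it. Defaults emulate the marginal
#' structure of a US registry nCRT-plus-esophagectomy cohort: examined
#' lymph node (ELN) counts follow a shifted negative binomial per
#' diagnosis-year group (median drifting 9 to 15 across 2001--2016, overall
#' median 12), T stage and histology follow the registry marginals, and
#' overall survival is exponential proportional hazards with right censoring.
#'
#' Two generative modes control how nodal positivity is *observed*:
#'
#' * `"mechanistic"` (default): each patient has a latent nodal basin of `B`
#'   nodes of which `M` are truly positive (for truly node-positive patients);
#'   examining `n` nodes draws hypergeometrically from the basin, so the
#'   probability of detecting disease rises and saturates with `n`. Missed
#'   positive nodes carry excess hazard -- the survival side of stage
#'   migration.
#' * `"piecewise"`: observed positivity follows a logistic model whose
#'   log-odds are piecewise linear in the ELN count with a planted breakpoint
#'   `n_star`, i.e. `logit P = alpha + beta1 * min(n, n_star) +
#'   beta2 * max(0, n - n_star) + T-stage offsets`. This mode exists to make
#'   breakpoint recovery exactly testable.
#'
#' @param n_patients number of patients to generate.
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   byte for byte.
#' @param mode `"mechanistic"` or `"piecewise"` (see Details).
#' @param year_group_weights probabilities over the four diagnosis-year
#'   groups; must sum to 1.
#' @param eln_dist per-year-group list of `c(mu, size)` for the shifted
#'   negative binomial `1 + NB(mu, size)` of ELN counts.
#' @param t_stage_probs named probabilities over `T0,T1,T2,T3,T4,TX`.
#' @param histology_probs named probabilities over `AC,SCC,other`.
#' @param sex_probs named probabilities over `male,female`.
#' @param age_mean,age_sd,age_range normal age model, truncated to the range.
#' @param true_node_pos_prev probability a patient is truly node-positive;
#'   a scalar in `[0, 1]` or a named vector per T stage.
#' @param piecewise list with `alpha`, `beta1`, `beta2`, `n_star` (integer
#'   >= 2), optional `t_offsets` (named per T stage), and `pos_count_mu`,
#'   `pos_count_size` governing how many positive nodes an observed-positive
#'   patient shows.
#' @param mechanistic list with `basin_mu`, `basin_size` (total nodal basin,
#'   shifted negative binomial), `pos_mu`, `pos_size` (truly positive node
#'   count given node-positive), and `examine_all` (force ELN count = basin
#'   size, i.e. exhaustive sampling; used for calibration checks).
#' @param survival list with `baseline_hazard` (events/month, > 0),
#'   `log_hr_node_pos`, `log_hr_t_stage` (named per T stage),
#'   `log_hr_undetected` (per undetected positive node),
#'   `admin_censor_months` (administrative cutoff, may be `Inf`) and
#'   `censor_rate` (independent exponential censoring rate, 0 disables).
#' @param eln_fixed optional integer; force every ELN count to this value
#'   (overrides `eln_dist`).
#'
#' @return an object of class `eln_generator_config`.
#' @export
eln_generator_config <- function(
    n_patients = 10000L,
    seed = 20220429L,
    mode = c("mechanistic", "piecewise"),
    year_group_weights = c("2001-2004" = 0.152, "2005-2008" = 0.218,
                           "2009-2012" = 0.273, "2013-2016" = 0.357),
    eln_dist = list("2001-2004" = c(mu = 9.5,  size = 1.8),
                    "2005-2008" = c(mu = 11.5, size = 1.7),
                    "2009-2012" = c(mu = 14.5, size = 2.0),
                    "2013-2016" = c(mu = 16.0, size = 3.2)),
    t_stage_probs = c(T0 = 2, T1 = 471, T2 = 628, T3 = 2343, T4 = 235,
                      TX = 1031) / 4710,
    histology_probs = c(AC = 3664, SCC = 943, other = 103) / 4710,
    sex_probs = c(male = 3960, female = 750) / 4710,
    age_mean = 61, age_sd = 10, age_range = c(23, 88),
    true_node_pos_prev = 0.55,
    piecewise = list(alpha = -1.2, beta1 = 0.08, beta2 = 0, n_star = 16L,
                     t_offsets = NULL, pos_count_mu = 1.6,
                     pos_count_size = 1.2),
    mechanistic = list(basin_mu = 34, basin_size = 8, pos_mu = 2.8,
                       pos_size = 1.5, examine_all = FALSE),
    survival = list(baseline_hazard = 0.0074,
                    log_hr_node_pos = log(2.2),
                    log_hr_t_stage = c(T0 = 0, T1 = 0, T2 = 0.2, T3 = 0.45,
                                       T4 = 0.7, TX = 0.3),
                    log_hr_undetected = log(1.12),
                    admin_censor_months = 180,
                    censor_rate = 0.004),
    eln_fixed = NULL) {
  mode <- match.arg(mode)
  piecewise <- modifyList(eval(formals(eln_generator_config)$piecewise),
                          as.list(piecewise))
  mechanistic <- modifyList(eval(formals(eln_generator_config)$mechanistic),
                            as.list(mechanistic))
  survival <- modifyList(eval(formals(eln_generator_config)$survival),
                         as.list(survival))

  check_prob_vec <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("invalid probability vector for ", what,
           ": entries must be non-negative and sum to 1", call. = FALSE)
    }
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("n_patients must be a positive integer", call. = FALSE)
  }
  check_prob_vec(year_group_weights, "year_group_weights")
  check_prob_vec(t_stage_probs, "t_stage_probs")
  check_prob_vec(histology_probs, "histology_probs")
  check_prob_vec(sex_probs, "sex_probs")
  if (!setequal(names(year_group_weights), names(eln_dist))) {
    stop("eln_dist must name the same year groups as year_group_weights",
         call. = FALSE)
  }
  for (g in names(eln_dist)) {
    p <- eln_dist[[g]]
    if (any(!is.finite(p)) || p[["mu"]] <= 0 || p[["size"]] <= 0) {
      stop("eln_dist parameters for ", g, " must be positive", call. = FALSE)
    }
  }
  prev <- true_node_pos_prev
  if (any(prev < 0) || any(prev > 1)) {
    stop("true_node_pos_prev must lie in [0, 1]", call. = FALSE)
  }
  if (length(prev) > 1L && !all(names(t_stage_probs) %in% names(prev))) {
    stop("per-T-stage true_node_pos_prev must name every T stage",
         call. = FALSE)
  }
  if (mode == "piecewise") {
    if (piecewise$n_star < 2) {
      stop("piecewise n_star must be an integer >= 2", call. = FALSE)
    }
    upper <- if (!is.null(eln_fixed)) eln_fixed else {
      max(vapply(eln_dist,
                 function(p) 1 + qnbinom(0.999, mu = p[["mu"]],
                                         size = p[["size"]]), 0))
    }
    if (piecewise$n_star > upper) {
      stop("piecewise n_star (", piecewise$n_star,
           ") exceeds the support of the ELN distribution", call. = FALSE)
    }
  }
  if (survival$baseline_hazard <= 0) {
    stop("survival baseline_hazard must be > 0", call. = FALSE)
  }
  if (survival$censor_rate < 0 || survival$admin_censor_months <= 0) {
    stop("invalid censoring configuration", call. = FALSE)
  }

  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed), mode = mode,
    year_group_weights = year_group_weights, eln_dist = eln_dist,
    t_stage_probs = t_stage_probs, histology_probs = histology_probs,
    sex_probs = sex_probs, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, true_node_pos_prev = true_node_pos_prev,
    piecewise = piecewise, mechanistic = mechanistic, survival = survival,
    eln_fixed = eln_fixed
  ), class = "eln_generator_config")
}

#' Generate a synthetic nCRT esophagectomy cohort
#'
#' Draws `config$n_patients` patient records from the model described in
#' [eln_generator_config()]. The result is deterministic given the config and
#' seed, and the caller's RNG state is left untouched.
#'
#' @param config an [eln_generator_config()] object.
#' @param seed overrides `config$seed` when given.
#' @param keep_latent also return the latent columns `true_positive_nodes`
#'   (truly positive nodes present) and `undetected_positive_nodes`; the
#'   standard schema carries only `true_node_positive`.
#' @return a `data.frame` with one row per patient and columns `patient_id`,
#'   `age`, `sex`, `histology`, `year_group`, `t_stage`, `eln_count`,
#'   `positive_nodes_examined`, `observed_n_stage`, `true_node_positive`,
#'   `survival_months`, `death_event`. `true_node_positive` is synthetic
#'   ground truth; analysis functions never read it.
#' @export
generate_cohort <- function(config, seed = config$seed, keep_latent = FALSE) {
  stopifnot(inherits(config, "eln_generator_config"))
  with_seed(seed, {
    n <- config$n_patients
    groups <- names(config$year_group_weights)
    year_group <- sample(groups, n, replace = TRUE,
                         prob = config$year_group_weights)
    if (!is.null(config$eln_fixed)) {
      eln <- rep.int(as.integer(config$eln_fixed), n)
    } else {
      mu <- vapply(config$eln_dist, `[[`, 0, "mu")[year_group]
      size <- vapply(config$eln_dist, `[[`, 0, "size")[year_group]
      eln <- 1L + rnbinom(n, mu = mu, size = size)
    }
    t_stage <- sample(names(config$t_stage_probs), n, replace = TRUE,
                      prob = config$t_stage_probs)
    histology <- sample(names(config$histology_probs), n, replace = TRUE,
                        prob = config$histology_probs)
    sex <- sample(names(config$sex_probs), n, replace = TRUE,
                  prob = config$sex_probs)
    age <- round(pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
                           config$age_range[1]), config$age_range[2]))

    prev <- config$true_node_pos_prev
    prev_i <- if (length(prev) > 1L) unname(prev[t_stage]) else rep(prev, n)

    if (config$mode == "piecewise") {
      pw <- config$piecewise
      off <- if (is.null(pw$t_offsets)) rep(0, n) else
        unname(pw$t_offsets[t_stage])
      eta <- pw$alpha + pw$beta1 * pmin(eln, pw$n_star) +
        pw$beta2 * pmax(0, eln - pw$n_star) + off
      p_obs <- ifelse(prev_i == 0, 0, plogis(eta))
      obs_pos <- rbinom(n, 1L, p_obs) == 1L
      pos_exam <- integer(n)
      if (any(obs_pos)) {
        k <- 1L + rnbinom(sum(obs_pos), mu = pw$pos_count_mu,
                          size = pw$pos_count_size)
        pos_exam[obs_pos] <- pmin(k, eln[obs_pos])
      }
      # latent truth: every observed positive is truly positive; observed
      # negatives are topped up toward the configured prevalence where the
      # marginal leaves room
      p_extra <- ifelse(p_obs < prev_i & p_obs < 1,
                        pmax(0, (prev_i - p_obs) / (1 - p_obs)), 0)
      true_pos <- obs_pos | (rbinom(n, 1L, p_extra) == 1L)
      true_nodes <- ifelse(true_pos, pmax(pos_exam, 1L), 0L)
      undetected <- as.integer(true_pos & !obs_pos)
    } else {
      mech <- config$mechanistic
      basin <- 1L + rnbinom(n, mu = mech$basin_mu - 1, size = mech$basin_size)
      if (isTRUE(mech$examine_all)) {
        eln <- basin
      } else {
        basin <- pmax(basin, eln) # cannot examine more nodes than exist
      }
      true_pos <- rbinom(n, 1L, prev_i) == 1L
      true_nodes <- integer(n)
      if (any(true_pos)) {
        m <- 1L + rnbinom(sum(true_pos), mu = mech$pos_mu - 1,
                          size = mech$pos_size)
        true_nodes[true_pos] <- pmin(m, basin[true_pos])
      }
      pos_exam <- rhyper(n, m = true_nodes, n = basin - true_nodes, k = eln)
      obs_pos <- pos_exam > 0L
      undetected <- true_nodes - pos_exam
    }

    sv <- config$survival
    rate <- sv$baseline_hazard *
      exp(sv$log_hr_node_pos * as.numeric(true_pos) +
            unname(sv$log_hr_t_stage[t_stage]) +
            sv$log_hr_undetected * undetected)
    t_death <- rexp(n, rate)
    t_cens <- if (sv$censor_rate > 0) rexp(n, sv$censor_rate) else
      rep(Inf, n)
    t_cens <- pmin(t_cens, sv$admin_censor_months)
    survival_months <- round(pmin(t_death, t_cens), 1)
    death_event <- as.integer(t_death <= t_cens)

    out <- data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      age = as.integer(age), sex = sex, histology = histology,
      year_group = year_group, t_stage = t_stage,
      eln_count = as.integer(eln),
      positive_nodes_examined = as.integer(pos_exam),
      observed_n_stage = as.character(n_stage_from_positive(pos_exam)),
      true_node_positive = as.logical(true_pos),
      survival_months = survival_months,
      death_event = death_event,
      stringsAsFactors = FALSE
    )
    if (keep_latent) {
      out$true_positive_nodes <- as.integer(true_nodes)
      out$undetected_positive_nodes <- as.integer(undetected)
    }
    out
  })
}

#' Descriptive summary of a cohort
#'
#' Tabulates the cohort the way registry papers report demographics: counts
#' by sex, histology, T stage, N stage and diagnosis-year group, plus the
#' median and interquartile range of the ELN count overall and per year group.
#'
#' @param records cohort `data.frame`.
#' @return an object of class `eln_cohort_summary`.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("cannot summarize an empty cohort", call. = FALSE)
  }
  eln_q <- function(x) {
    # order-statistic quantiles (type 1), the registry-table convention
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 1)
    c(q25 = q[1], median = q[2], q75 = q[3])
  }
  by_year <- NULL
  if ("year_group" %in% names(records)) {
    groups <- sort(unique(records$year_group))
    by_year <- data.frame(
      year_group = groups,
      n = as.integer(table(records$year_group)[groups]),
      t(vapply(groups,
               function(g) eln_q(records$eln_count[records$year_group == g]),
               numeric(3))),
      row.names = NULL
    )
  }
  tab_or_null <- function(col) {
    if (col %in% names(records)) table(records[[col]]) else NULL
  }
  structure(list(
    n = nrow(records),
    by_sex = tab_or_null("sex"),
    by_histology = tab_or_null("histology"),
    by_t_stage = tab_or_null("t_stage"),
    by_n_stage = tab_or_null("observed_n_stage"),
    by_year_group = tab_or_null("year_group"),
    eln_overall = eln_q(records$eln_count),
    eln_by_year_group = by_year
  ), class = "eln_cohort_summary")
}

#' @export
print.eln_cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n, "patients\n")
  cat(sprintf("ELN count: median %.0f (IQR %.0f-%.0f)\n",
              x$eln_overall[["median"]], x$eln_overall[["q25"]],
              x$eln_overall[["q75"]]))
  if (!is.null(x$eln_by_year_group)) {
    cat("By year group:\n")
    print(x$eln_by_year_group, row.names = FALSE)
  }
  invisible(x)
}

#' Write / read a cohort CSV
#'
#' Plain-text interchange for cohort tables in the schema produced by
#' [generate_cohort()]. Writing is byte-deterministic for a given cohort.
#'
#' @param records cohort `data.frame`.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort `data.frame`.
#' @export
write_cohort <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
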