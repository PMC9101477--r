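# elncut

How many lymph nodes must be examined at esophagectomy, after neoadjuvant
chemoradiotherapy (nCRT), before the pathological nodal stage can be
trusted — and once staging is adequate, does dissecting more nodes still
improve survival? `elncut` implements the registry-analysis pipeline that
answers both questions from a patient-level cohort table, for
surgeons/epidemiologists working with cancer-registry extracts and for
methodologists who want the cutpoint machinery itself.

## The method

For patients with ELN count *n* (examined lymph nodes), the pipeline:

1. **Stage migration.** Fits the logistic model
   `logit P(node-positive) = β·n + T-stage terms` (continuous gradient) and
   the dummy-coded per-count model giving OR(*n*) versus a one-node
   reference — the Will Rogers curve: more nodes examined, more positives
   found.
2. **Cutpoint.** Smooths the per-count log-OR curve with Cleveland's LOWESS
   (span 2/3) for display, and scans the raw series with a Chow structural
   break test: at each candidate *k*, F compares one pooled line with two
   segment regressions (segments `x ≤ k` and `x ≥ k`, sharing the kink
   point), `F = [(RSSp − RSS₁ − RSS₂)/2] / [(RSS₁+RSS₂)/(n₁+n₂−4)]`.
   The argmax locates the minimum adequate lymphadenectomy n\*; the
   significance decision is Bonferroni-adjusted across candidates.
3. **Validation.** Kaplan–Meier curves and the log-rank test at the n\*
   split within nodal strata, Cox models of overall survival per ELN count
   (Efron ties), and beyond-cutoff HR curves with n\* as reference — flat
   curves mean no extra survival from dissecting past n\*.

Registry microdata cannot be shipped, so the package includes a seeded
synthetic cohort generator with registry-like marginals (median 12 ELN,
IQR 7–19-style, drifting 9→15 across year groups; 38%-ish observed
node-positivity; exponential proportional-hazards survival) and a
**plantable breakpoint**, making the whole pipeline testable by parameter
recovery. See `vignettes/eln-cutpoint-methods.Rmd` for the models,
defaults, and numerical decisions.

## Worked example

Plant a breakpoint at 16 nodes and recover it end to end:

```r
library(elncut)
config <- eln_generator_config(
  n_patients = 20000, seed = 7, mode = "piecewise",
  piecewise = list(alpha = -1.2, beta1 = 0.08, beta2 = 0, n_star = 16))
cohort <- generate_cohort(config)

summarize_cohort(cohort)
#> Cohort of 20000 patients
#> ELN count: median 12 (IQR 7-20)
#> By year group:
#>  year_group    n q25 median q75
#>   2001-2004 3004   5      9  14
#>   2005-2008 4410   5     10  17
#>   2009-2012 5490   7     13  21
#>   2013-2016 7096  10     15  22

fit_continuous_or(cohort)
#> Stage migration: OR per ELN 1.030 (95% CI 1.027-1.033), P <2e-16, n = 20000

cutpoint <- find_cutpoint(cohort)
cutpoint
#> Structural break at 16 (F = 119, pointwise P <2e-16,
#>   bonferroni-adjusted P <2e-16, significant at alpha = 0.05)

km_compare_at_cutoff(cohort, cutpoint$k_hat, stratum = "node-negative")
#> Survival at the 16-ELN cutoff (node-negative stratum):
#> KM [ELN >= 16]: n = 3615, events = 2447, median 64.3 months (61.0-68.0), 5-year 52.1%
#> KM [ELN < 16]: n = 7751, events = 5617, median 50.5 months (48.7-52.2), 5-year 44.1%
#> Log-rank: chi-square 64.057 on 1 df, P 1.21e-15

fit_cox_continuous(subset(cohort, eln_count >= cutpoint$k_hat),
                   stratum = "node-negative")
#> OS (node-negative): HR per ELN 1.001 (95% CI 0.997-1.006), P 0.527, n = 3615, events = 2447
```

Read: the per-node odds of a node-positive call rise 3%/node (stage
migration is real), the OR curve's structure breaks exactly at the planted
16; "node-negative" patients staged with ≥16 nodes survive markedly longer
than those staged with fewer (their N0 label is more believable); and above
the cutoff, extra nodes no longer move the hazard (HR ≈ 1.00, flat).

`run_full_analysis(cohort)` packages all of the above (plus per-histology
fits and an attrition ledger) into one provenance-tagged report;
`inst/cli/elncut.R` exposes `simulate | filter | migration | survival |
cutpoint | report` subcommands for shell use.

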