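#' Analysis configuration for the end-to-end pipeline
#'
#' @param codes A [code_set()] (default [default_code_set()]).
#' @param index_period Admissible first-diagnosis dates.
#' @param washout_days,baseline_days,followup_days Window lengths in days.
#' @param ratio Coarse-match ratio (default 30).
#' @param caliper_sd 1:1 caliper in pooled logit-SD units (default 0.2;
#'   `NULL` disables).
#' @param grid An [interval_grid()].
#' @param bootstrap A [bootstrap_config()]; its seed is overridden by `seed`.
#' @param seed Global seed propagated to every stochastic step.
#' @param study_end Administrative end of data (default: latest enrollment
#'   end observed).
#' @param sensitivity Run the two sensitivity analyses (default TRUE).
#' @param stratify_cox Stratify the Cox model on matched pairs (default
#'   FALSE).
#' @param currency Label used when printing cost tables (default `"¥"`).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(codes = default_code_set(),
                            index_period = as.Date(c("2012-01-01",
                                                     "2016-12-31")),
                            washout_days = 360, baseline_days = 360,
                            followup_days = 360, ratio = 30,
                            caliper_sd = 0.2, grid = interval_grid(),
                            bootstrap = bootstrap_config(), seed = 1L,
                            study_end = NULL, sensitivity = TRUE,
                            stratify_cox = FALSE, currency = "¥") {
  structure(list(codes = codes, index_period = as.Date(index_period),
                 washout_days = washout_days, baseline_days = baseline_days,
                 followup_days = followup_days, ratio = ratio,
                 caliper_sd = caliper_sd, grid = grid, bootstrap = bootstrap,
                 seed = as.integer(seed), study_end = study_end,
                 sensitivity = sensitivity, stratify_cox = stratify_cox,
                 currency = currency),
            class = "analysis_config")
}

# Survival + KMSA + subgroup analysis of a set of matched pairs; shared by
# the main analysis and both sensitivity re-runs.
analyze_pairs <- function(pairs, members, data, config) {
  matched <- members %>%
    filter(.data$patient_id %in% c(pairs$hk_id, pairs$control_id))
  s12 <- surv_sample(matched, horizon_days = config$followup_days)
  sfull <- surv_sample(matched, horizon_days = NULL)

  mortality <- tibble(
    horizon = c("12m", "full"),
    mortality_hk = c(mean(filter(s12, .data$cohort == "HK")$event),
                     mean(filter(sfull, .data$cohort == "HK")$event)),
    mortality_control = c(mean(filter(s12, .data$cohort != "HK")$event),
                          mean(filter(sfull, .data$cohort != "HK")$event)))
  # the Cox HR is undefined (monotone likelihood) when a cohort has no events
  safe_cox <- function(s) {
    ev <- tapply(s$event, s$cohort == "HK", sum)
    if (length(ev) < 2 || any(ev == 0)) return(NULL)
    cox_fit(s, stratify_pairs = config$stratify_cox)
  }
  cox12 <- safe_cox(s12)
  coxfull <- safe_cox(sfull)
  cox_field <- function(fit, f) if (is.null(fit)) NA_real_ else f(fit)
  mortality <- mortality %>%
    mutate(hr = c(cox_field(cox12, function(x) x$hr),
                  cox_field(coxfull, function(x) x$hr)),
           hr_lo = c(cox_field(cox12, function(x) x$ci95[1]),
                     cox_field(coxfull, function(x) x$ci95[1])),
           hr_hi = c(cox_field(cox12, function(x) x$ci95[2]),
                     cox_field(coxfull, function(x) x$ci95[2])),
           p_value = c(cox_field(cox12, function(x) x$p_value),
                       cox_field(coxfull, function(x) x$p_value)))

  outcomes <- accrue_intervals(matched, data, config$grid)
  boot <- paired_bootstrap(pairs, outcomes, config$bootstrap)

  km_hk <- km_estimate(s12, group = "HK")
  km_ct <- km_estimate(s12, group = "non-HK")
  est_hk <- kmsa_point_estimate(outcomes, cohort_label = "HK")
  est_ct <- kmsa_point_estimate(outcomes, cohort_label = "non-HK")

  monthly <- bind_rows(
    monthly_series(est_hk, "HK"),
    monthly_series(est_ct, "non-HK"))

  list(pairs = pairs, members = matched,
       survival = list(sample_12m = s12, sample_full = sfull,
                       km_hk = km_hk, km_control = km_ct,
                       logrank_12m = logrank_test(s12),
                       logrank_full = logrank_test(sfull),
                       cox_12m = cox12, cox_full = coxfull),
       mortality = mortality,
       outcomes = outcomes,
       kmsa = boot,
       subgroup_inpatient = summarize_subgroup(pairs, outcomes,
                                               "hospitalized"),
       subgroup_outpatient = summarize_subgroup(pairs, outcomes,
                                                "outpatient"),
       pct_any_admission = pct_any_use(pairs, outcomes, "n_admissions"),
       pct_any_outpatient = pct_any_use(pairs, outcomes, "n_outpatient"),
       monthly = monthly)
}

monthly_series <- function(est, cohort) {
  d <- attr(est, "detail")
  j <- match(c("cost_total", "cost_inpatient", "cost_outpatient"),
             est$outcome)
  tibble(cohort = cohort, interval = seq_along(d$S),
         survival_weight = d$S, n_at_risk = d$n_at,
         cost_total = d$cbar[j[1], ],
         cost_inpatient = d$cbar[j[2], ],
         cost_outpatient = d$cbar[j[3], ],
         weighted_cost_total = d$S * d$cbar[j[1], ])
}

pct_any_use <- function(pairs, outcomes, col) {
  per_pat <- outcomes %>%
    group_by(.data$patient_id) %>%
    summarise(n = sum(.data[[col]]), .groups = "drop")
  any_use <- function(ids) per_pat$n[match(ids, per_pat$patient_id)] >= 1
  x <- any_use(pairs$hk_id); y <- any_use(pairs$control_id)
  tibble(pct_hk = 100 * mean(x), pct_control = 100 * mean(y),
         p_value = balance_p_value(as.numeric(x), as.numeric(y), "binary"))
}

#' Run the full matched-cohort burden-of-illness pipeline
#'
#' Executes, in order: new-onset CKD identification, HK / non-HK cohort
#' assignment, enrollment filtering, coarse 1:30 matching, covariate
#' construction, propensity fitting, 1:1 matching, balance diagnostics
#' (pre and post match), Kaplan-Meier / log-rank / Cox mortality analysis at
#' the 12-month and full-follow-up horizons, KMSA cost and HRU estimation
#' with paired-bootstrap CIs, matched-service-user summaries, the monthly
#' cost series, and (optionally) the malignancy-exclusion and survivors-only
#' sensitivity analyses. Identical data, config and seed give an identical
#' report.
#'
#' @param data A [claims_dataset()] (or a directory readable by
#'   [read_claims()]).
#' @param config An [analysis_config()].
#' @return A `study_report` list: `attrition`, `balance_pre`, `balance_post`,
#'   `propensity`, `pairs`, `mortality`, `kmsa`, `subgroup_inpatient`,
#'   `subgroup_outpatient`, `monthly`, `survival`, `sensitivity` (list), and
#'   `manifest`.
#' @export
run_pipeline <- function(data, config = analysis_config()) {
  if (is.character(data)) data <- read_claims(data)
  stopifnot(inherits(data, "claims_dataset"),
            inherits(config, "analysis_config"))
  config$bootstrap$seed <- config$seed
  attrition <- list()
  note <- function(step, n) {
    attrition[[length(attrition) + 1]] <<- tibble(step = step, n = n)
  }

  ckd <- find_new_onset_ckd(data, config$codes, config$index_period,
                            washout_days = config$washout_days)
  note("new_onset_ckd", nrow(ckd))
  if (nrow(ckd) == 0) abort("pipeline halted at cohort stage: no new-onset CKD patients")

  cohorts <- assign_cohorts(ckd, data, config$codes)
  note("hk_with_event", nrow(cohorts$hk_members))
  note("non_hk_candidates", nrow(cohorts$non_hk_candidates))
  if (nrow(cohorts$hk_members) == 0) {
    abort("pipeline halted at cohort stage: empty HK cohort")
  }

  hk <- apply_enrollment_filter(cohorts$hk_members, data,
                                baseline_days = config$baseline_days,
                                followup_days = config$followup_days,
                                study_end = config$study_end)
  note("hk_enrollment_filtered", nrow(hk))
  if (nrow(hk) == 0) abort("pipeline halted: no HK member passes the enrollment filter")

  cm <- coarse_match(hk, cohorts$non_hk_candidates, data,
                     ratio = config$ratio,
                     baseline_days = config$baseline_days,
                     followup_days = config$followup_days,
                     study_end = config$study_end)
  note("coarse_pool_controls", nrow(cm$controls))
  note("hk_with_coarse_controls",
       length(unique(cm$pool_map$hk_id)))

  hk_in_pool <- hk %>% filter(.data$patient_id %in% cm$pool_map$hk_id) %>%
    mutate(cohort = "HK")
  controls <- cm$controls %>% mutate(cohort = "non-HK")
  pool_members <- bind_rows(hk_in_pool,
                            controls %>% select(-"hk_partner"))

  cov <- build_covariates(pool_members, data,
                          baseline_days = config$baseline_days) %>%
    left_join(pool_members %>%
                transmute(.data$patient_id, hk = .data$cohort == "HK"),
              by = "patient_id")
  balance_pre <- balance_report(cov)

  model <- fit_propensity(cov)
  pairs <- match_1to1(model, caliper_sd = config$caliper_sd)
  note("matched_pairs", nrow(pairs))
  if (nrow(pairs) == 0) abort("pipeline halted: 1:1 matching produced no pairs")

  matched_ids <- c(pairs$hk_id, pairs$control_id)
  balance_post <- balance_report(cov %>%
                                   filter(.data$patient_id %in% matched_ids))

  main <- analyze_pairs(pairs, pool_members, data, config)

  sens <- list()
  if (isTRUE(config$sensitivity)) {
    sens$no_malignancy <- sensitivity_no_malignancy(
      pairs, pool_members, data, config)
    sens$survivors <- sensitivity_survivors(
      pairs, pool_members, data, config)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("kmsacohort")),
    seed = config$seed,
    index_period = format(config$index_period),
    windows = c(washout = config$washout_days,
                baseline = config$baseline_days,
                followup = config$followup_days),
    matching = list(ratio = config$ratio, caliper_sd = config$caliper_sd,
                    caliper_logit = attr(pairs, "caliper"),
                    n_pairs = nrow(pairs),
                    unmatched_hk = length(attr(pairs, "unmatched_hk"))),
    bootstrap = unclass(config$bootstrap),
    assumptions = paste("greedy nearest-neighbor 1:1 matching without",
                        "replacement, descending-PS order, logit caliper;",
                        "order and caliper are analyst choices"))

  structure(
    c(list(attrition = bind_rows(attrition),
           balance_pre = balance_pre, balance_post = balance_post,
           propensity = model, config = config, data_tables = NULL,
           manifest = manifest),
      main,
      list(sensitivity = sens)),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$attrition, n = Inf)
  m <- x$mortality
  cat(sprintf("  12m mortality: HK %.1f%% vs control %.1f%%, HR %.2f [%.2f, %.2f]\n",
              100 * m$mortality_hk[1], 100 * m$mortality_control[1],
              m$hr[1], m$hr_lo[1], m$hr_hi[1]))
  tot <- x$kmsa %>% filter(.data$outcome == "cost_total")
  cat(sprintf("  annual cost (KMSA): HK %s%.0f [%.0f, %.0f] vs control %s%.0f [%.0f, %.0f]; diff %s%.0f\n",
              x$config$currency, tot$est_hk, tot$lo_hk, tot$hi_hk,
              x$config$currency, tot$est_control, tot$lo_control,
              tot$hi_control, x$config$currency, tot$diff))
  cat(sprintf("  balance: %d/%d covariates |d| <= 0.10 post-match\n",
              sum(x$balance_post$balanced), nrow(x$balance_post)))
  invisible(x)
}
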