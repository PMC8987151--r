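#' Configuration for the synthetic claims generator
#'
#' Bundles every parameter of the generative model behind
#' [simulate_population()]. Defaults describe a desk-scale urban
#' employee-insurance population of new-onset CKD patients: a five-year index
#' window, elderly age mix, comorbidity and drug-class prevalences in the
#' range reported for such cohorts, a hyperkalemia (HK) arm whose death hazard
#' is five-fold the non-HK hazard, and a cost process with a sharp inpatient
#' spike in the first month after the HK index event. Proportions are
#' unitless, hazards are per person-month, costs are unitless currency.
#'
#' @param n_patients Number of simulated patients (>= 2).
#' @param index_period Length-2 date vector: first/last admissible first-CKD
#'   diagnosis date.
#' @param data_start,study_end Boundaries of the observable claims window.
#' @param age_distribution `c(mean, sd)` of age (years) at CKD diagnosis.
#' @param female_fraction Proportion female.
#' @param comorbidity_prevalences Named proportions of baseline comorbidity
#'   flags (names must be flags of [default_comorbidity_map()] plus
#'   `"dialysis"`).
#' @param drug_class_prevalences Named proportions of baseline drug classes
#'   (names must be flags of [default_drug_map()]).
#' @param hk_fraction Target marginal proportion of patients who experience an
#'   HK event after CKD diagnosis.
#' @param hk_logit_effects Named log-odds shifts of HK membership per
#'   comorbidity/drug flag (confounding knob).
#' @param hazard_log_hr_effects Named log hazard-ratio shifts of the death
#'   hazard per comorbidity flag.
#' @param baseline_hazard Death hazard, deaths per person-month, for a patient
#'   with no flagged comorbidity in the non-HK arm (> 0).
#' @param hk_log_hazard_ratio Log hazard ratio of death for the HK arm,
#'   applied from the HK index date.
#' @param monthly_outpatient_rate,admission_rate Expected outpatient visits /
#'   inpatient admissions per 30-day month while enrolled and alive.
#' @param index_month_inpatient_cost `c(mean, sd)` of the cost of the index
#'   hospitalization (the month-1 inpatient spike, HK arm only).
#' @param index_admission_los `c(mean, sd)` days of the index admission stay.
#' @param steady_monthly_cost Named list `list(hk = c(mean, sd), control =
#'   c(mean, sd))`: steady-state total monthly cost per arm (excluding the
#'   index spike); `sd` controls per-claim dispersion via the coefficient of
#'   variation.
#' @param inpatient_cost_share Share of steady monthly cost carried by
#'   inpatient admissions.
#' @param admission_los `c(mean, sd)` days of an ordinary admission stay.
#' @param cost_component_shares Named length-6 proportions (medication,
#'   examination, treatment, surgery, consumable, other) summing to 1; every
#'   claim's total is split deterministically by these shares.
#' @param enrollment_gap_prob Probability that a patient's enrollment span
#'   fails to cover the full baseline or follow-up window.
#' @param prior_ckd_fraction Fraction with a CKD-coded claim before the index
#'   period (excluded by the new-onset washout).
#' @param minor_fraction Fraction aged under 18 at diagnosis (excluded by the
#'   adult filter).
#' @param malignancy_monthly_cost_extra Additional monthly outpatient cost for
#'   patients carrying the malignancy flag (0 keeps the closed-form cost truth
#'   free of malignancy terms).
#' @param code_attach_prob Per-claim probability that a patient's comorbidity
#'   code is recorded on that claim.
#' @param ckd_code_prob Per-claim probability that a post-diagnosis claim
#'   carries a CKD code.
#' @param monthly_prescription_rate Prescriptions per month and drug class
#'   held.
#' @param ckd_to_hk_delay_mean Mean (days) of the truncated-exponential delay
#'   from CKD diagnosis to the HK index event.
#' @param rng_seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A validated `sim_config` list.
#' @seealso [simulate_population()], [truth_mean_annual_cost()]
#' @export
sim_config <- function(n_patients = 20000,
                       index_period = as.Date(c("2012-01-01", "2016-12-31")),
                       data_start = as.Date("2011-01-01"),
                       study_end = as.Date("2017-12-31"),
                       age_distribution = c(mean = 67, sd = 14),
                       female_fraction = 0.40,
                       comorbidity_prevalences = c(
                         hypertension = 0.75, dyslipidemia = 0.45,
                         t2dm = 0.40, heart_failure = 0.17,
                         arrhythmia = 0.28, angina = 0.19, mi = 0.10,
                         other_cvd = 0.39, stroke = 0.30, tia = 0.035,
                         other_cbd = 0.12, pvd = 0.15, peptic_ulcer = 0.09,
                         copd = 0.06, rheumatic = 0.05, malignancy = 0.20,
                         dialysis = 0.02),
                       drug_class_prevalences = c(
                         arb = 0.48, mra = 0.31, acei = 0.23, ccb = 0.64,
                         loop_diuretic = 0.54, nsaid = 0.53,
                         antiplatelet = 0.48, beta_blocker = 0.43,
                         anti_dyslipidemia = 0.40, insulin = 0.37,
                         oad = 0.28, bronchodilator = 0.27,
                         antihypertension = 0.22),
                       hk_fraction = 0.05,
                       hk_logit_effects = c(
                         hypertension = 0.3, t2dm = 0.3, heart_failure = 0.5,
                         dyslipidemia = 0.2, stroke = 0.2,
                         arb = 0.4, mra = 0.3, acei = 0.2),
                       hazard_log_hr_effects = c(
                         hypertension = 0.10, t2dm = 0.10, heart_failure = 0.20,
                         stroke = 0.10, malignancy = 0.25),
                       baseline_hazard = 0.00695,
                       hk_log_hazard_ratio = log(5),
                       monthly_outpatient_rate = 3,
                       admission_rate = 0.08,
                       index_month_inpatient_cost = c(mean = 22000, sd = 15000),
                       index_admission_los = c(mean = 15, sd = 8),
                       steady_monthly_cost = list(hk = c(mean = 3800, sd = 4500),
                                                  control = c(mean = 1800, sd = 2200)),
                       inpatient_cost_share = 0.5,
                       admission_los = c(mean = 12, sd = 6),
                       cost_component_shares = c(
                         medication = 0.50, examination = 0.15,
                         treatment = 0.17, surgery = 0.01,
                         consumable = 0.10, other = 0.07),
                       enrollment_gap_prob = 0.05,
                       prior_ckd_fraction = 0.02,
                       minor_fraction = 0.01,
                       malignancy_monthly_cost_extra = 0,
                       code_attach_prob = 0.15,
                       ckd_code_prob = 0.5,
                       monthly_prescription_rate = 0.25,
                       ckd_to_hk_delay_mean = 390,
                       rng_seed = 1L) {
  cfg <- structure(
    list(n_patients = n_patients,
         index_period = as.Date(index_period),
         data_start = as.Date(data_start), study_end = as.Date(study_end),
         age_distribution = age_distribution,
         female_fraction = female_fraction,
         comorbidity_prevalences = comorbidity_prevalences,
         drug_class_prevalences = drug_class_prevalences,
         hk_fraction = hk_fraction,
         hk_logit_effects = hk_logit_effects,
         hazard_log_hr_effects = hazard_log_hr_effects,
         baseline_hazard = baseline_hazard,
         hk_log_hazard_ratio = hk_log_hazard_ratio,
         monthly_outpatient_rate = monthly_outpatient_rate,
         admission_rate = admission_rate,
         index_month_inpatient_cost = index_month_inpatient_cost,
         index_admission_los = index_admission_los,
         steady_monthly_cost = steady_monthly_cost,
         inpatient_cost_share = inpatient_cost_share,
         admission_los = admission_los,
         cost_component_shares = cost_component_shares,
         enrollment_gap_prob = enrollment_gap_prob,
         prior_ckd_fraction = prior_ckd_fraction,
         minor_fraction = minor_fraction,
         malignancy_monthly_cost_extra = malignancy_monthly_cost_extra,
         code_attach_prob = code_attach_prob,
         ckd_code_prob = ckd_code_prob,
         monthly_prescription_rate = monthly_prescription_rate,
         ckd_to_hk_delay_mean = ckd_to_hk_delay_mean,
         rng_seed = as.integer(rng_seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      cfg$n_patients < 2) {
    abort("`n_patients` must be a single number >= 2")
  }
  if (length(cfg$index_period) != 2 || anyNA(cfg$index_period) ||
      cfg$index_period[1] >= cfg$index_period[2]) {
    abort("`index_period` must be two ordered dates")
  }
  if (cfg$data_start > cfg$index_period[1] || cfg$study_end < cfg$index_period[2]) {
    abort("`index_period` must lie inside [data_start, study_end]")
  }
  check_prob(cfg$female_fraction, "female_fraction")
  check_prob(cfg$hk_fraction, "hk_fraction")
  check_prob(cfg$comorbidity_prevalences, "comorbidity_prevalences")
  check_prob(cfg$drug_class_prevalences, "drug_class_prevalences")
  check_prob(cfg$enrollment_gap_prob, "enrollment_gap_prob")
  check_prob(cfg$prior_ckd_fraction, "prior_ckd_fraction")
  check_prob(cfg$minor_fraction, "minor_fraction")
  check_prob(cfg$code_attach_prob, "code_attach_prob")
  check_prob(cfg$ckd_code_prob, "ckd_code_prob")
  check_prob(cfg$inpatient_cost_share, "inpatient_cost_share")
  check_pos(cfg$baseline_hazard, "baseline_hazard", strict = TRUE)
  check_pos(cfg$monthly_outpatient_rate, "monthly_outpatient_rate")
  check_pos(cfg$admission_rate, "admission_rate")
  check_pos(cfg$monthly_prescription_rate, "monthly_prescription_rate")
  check_pos(cfg$malignancy_monthly_cost_extra, "malignancy_monthly_cost_extra")
  check_pos(cfg$ckd_to_hk_delay_mean, "ckd_to_hk_delay_mean", strict = TRUE)
  shares <- cfg$cost_component_shares
  if (length(shares) != 6 || abs(sum(shares) - 1) > 1e-9 || any(shares < 0)) {
    abort("`cost_component_shares` must be six non-negative proportions summing to 1")
  }
  if (!setequal(names(shares),
                c("medication", "examination", "treatment", "surgery",
                  "consumable", "other"))) {
    abort("`cost_component_shares` must be named medication/examination/treatment/surgery/consumable/other")
  }
  for (arm in c("hk", "control")) {
    x <- cfg$steady_monthly_cost[[arm]]
    if (is.null(x) || length(x) != 2 || x[["mean"]] <= 0 || x[["sd"]] < 0) {
      abort(sprintf("`steady_monthly_cost$%s` must be c(mean > 0, sd >= 0)", arm))
    }
  }
  for (f in c("index_month_inpatient_cost", "index_admission_los",
              "admission_los", "age_distribution")) {
    x <- cfg[[f]]
    if (length(x) != 2 || x[["mean"]] <= 0 || x[["sd"]] < 0) {
      abort(sprintf("`%s` must be c(mean > 0, sd >= 0)", f))
    }
  }
  flag_names <- c(names(cfg$comorbidity_prevalences),
                  names(cfg$drug_class_prevalences))
  for (f in c("hk_logit_effects", "hazard_log_hr_effects")) {
    bad <- setdiff(names(cfg[[f]]), flag_names)
    if (length(bad)) {
      abort(sprintf("`%s` names not among configured flags: %s",
                    f, paste(bad, collapse = ", ")))
    }
  }
  if (!is.finite(cfg$rng_seed)) abort("`rng_seed` must be a finite integer")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  patients:", x$n_patients,
      " index period:", format(x$index_period[1]), "..",
      format(x$index_period[2]), "\n")
  cat("  hk_fraction:", x$hk_fraction,
      " true HR:", round(exp(x$hk_log_hazard_ratio), 3),
      " baseline hazard (/person-month):", x$baseline_hazard, "\n")
  cat("  steady monthly cost: hk",
      x$steady_monthly_cost$hk[["mean"]], "/ control",
      x$steady_monthly_cost$control[["mean"]],
      "; index spike:", x$index_month_inpatient_cost[["mean"]], "\n")
  invisible(x)
}
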