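#' Build baseline covariate vectors for cohort members
#'
#' Computes, strictly from claims and prescriptions dated in the 360-day
#' half-open window `[index - baseline_days, index)`, the matching covariates:
#' age at index, sex, Charlson Comorbidity Index (Quan ICD-10 mapping,
#' original weights), CKD duration, comorbidity flags, dialysis and drug-class
#' flags, and baseline healthcare use (hospitalizations, length of stay,
#' outpatient visits, total cost).
#'
#' @param members Tibble with `patient_id`, `index_date`,
#'   `ckd_duration_months` (as from [apply_enrollment_filter()]).
#' @param data A [claims_dataset()].
#' @param baseline_days Baseline window length in days (default 360).
#' @param comorbidity_map,drug_map,cci_map Code maps; see
#'   [default_comorbidity_map()], [default_drug_map()], [charlson_map()].
#' @return A tibble with one row per member: `patient_id`, `age_at_index`,
#'   `female`, `cci`, `ckd_duration_months`, one logical column per
#'   comorbidity and drug flag, `dialysis`, `baseline_n_hospitalizations`,
#'   `baseline_los`, `baseline_n_outpatient`, `baseline_total_cost`.
#' @export
build_covariates <- function(members, data, baseline_days = 360,
                             comorbidity_map = default_comorbidity_map(),
                             drug_map = default_drug_map(),
                             cci_map = charlson_map()) {
  stopifnot(inherits(data, "claims_dataset"))
  base <- members %>%
    select("patient_id", "index_date", "ckd_duration_months") %>%
    left_join(data$patients %>% select("patient_id", "sex", "birth_date"),
              by = "patient_id") %>%
    mutate(age_at_index = floor(days_between(.data$birth_date,
                                             .data$index_date) / 365.25),
           female = .data$sex == "F")

  # claims in the half-open baseline window (inpatient dated by admission)
  bl <- data$claims %>%
    inner_join(base %>% select("patient_id", "index_date"),
               by = "patient_id") %>%
    filter(.data$service_date >= .data$index_date - baseline_days,
           .data$service_date < .data$index_date)

  hru <- bl %>%
    group_by(.data$patient_id) %>%
    summarise(
      baseline_n_hospitalizations = sum(.data$setting == "inpatient"),
      baseline_los = sum(ifelse(.data$setting == "inpatient",
                                days_between(.data$admission_date,
                                             .data$discharge_date) + 1, 0)),
      baseline_n_outpatient = sum(.data$setting == "outpatient"),
      baseline_total_cost = sum(.data$cost_medication + .data$cost_examination +
                                  .data$cost_treatment + .data$cost_surgery +
                                  .data$cost_consumable + .data$cost_other),
      .groups = "drop")

  # long (patient, code) pairs for flagging and CCI
  codes_long <- bl %>%
    select("patient_id", "diagnosis") %>%
    mutate(code = split_codes(.data$diagnosis)) %>%
    select(-"diagnosis") %>%
    tidyr::unnest("code")

  flag_tbl <- tibble(patient_id = base$patient_id)
  for (i in seq_len(nrow(comorbidity_map))) {
    f <- comorbidity_map$flag[i]
    hit <- codes_long$patient_id[
      code_has_prefix(codes_long$code, comorbidity_map$prefixes[[i]])]
    flag_tbl[[f]] <- base$patient_id %in% hit
  }
  flag_tbl$dialysis <- base$patient_id %in%
    codes_long$patient_id[code_has_prefix(codes_long$code,
                                          dialysis_prefixes())]

  rx <- data$prescriptions %>%
    inner_join(base %>% select("patient_id", "index_date"),
               by = "patient_id") %>%
    filter(.data$date >= .data$index_date - baseline_days,
           .data$date < .data$index_date)
  for (i in seq_len(nrow(drug_map))) {
    f <- drug_map$flag[i]
    hit <- unique(rx$patient_id[rx$drug_class %in% drug_map$classes[[i]]])
    flag_tbl[[f]] <- base$patient_id %in% hit
  }

  cci <- if (nrow(codes_long)) {
    charlson_scores(codes_long$patient_id, codes_long$code, cci_map)
  } else {
    tibble(patient_id = integer(), cci = integer())
  }

  base %>%
    left_join(cci, by = "patient_id") %>%
    left_join(flag_tbl, by = "patient_id") %>%
    left_join(hru, by = "patient_id") %>%
    mutate(cci = coalesce(.data$cci, 0L),
           across(starts_with("baseline_"), ~coalesce(.x, 0))) %>%
    select(-"index_date", -"sex", -"birth_date") %>%
    relocate("patient_id", "age_at_index", "female", "cci",
             "ckd_duration_months")
}

# The covariate columns entering the propensity model / balance report.
covariate_columns <- function(covariates) {
  setdiff(names(covariates), c("patient_id", "cohort", "hk", "pair_id"))
}
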