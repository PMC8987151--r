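# Long view of claim diagnoses restricted to codes matching any prefix;
# inpatient claims are dated by admission.
claims_with_code <- function(claims, prefixes) {
  hit <- diag_matches_prefix(claims$diagnosis, prefixes)
  claims[hit, c("patient_id", "setting", "service_date")]
}

#' Identify new-onset CKD patients
#'
#' A patient qualifies when their earliest CKD-coded inpatient or outpatient
#' claim falls inside the index period, they are an adult (>= `min_age`) on
#' that date, no CKD-coded claim precedes the index period (washout), and
#' their enrollment provides at least `washout_days` of lookback before the
#' diagnosis so "new onset" is observable.
#'
#' @param data A [claims_dataset()].
#' @param codes A [code_set()].
#' @param index_period Length-2 date vector of admissible diagnosis dates.
#' @param washout_days Required clean lookback coverage, days (default 360).
#' @param min_age Minimum age in whole years at diagnosis (default 18).
#' @return A tibble `(patient_id, ckd_diagnosis_date)`, one row per
#'   qualifying patient, with an `exclusions` attribute counting the drops.
#' @export
find_new_onset_ckd <- function(data, codes, index_period,
                               washout_days = 360, min_age = 18) {
  stopifnot(inherits(data, "claims_dataset"))
  if (!inherits(codes, "code_set") || length(codes$ckd_codes) == 0) {
    abort("`codes` must be a code_set with non-empty ckd_codes")
  }
  index_period <- as.Date(index_period)
  ckd_claims <- claims_with_code(data$claims, codes$ckd_codes)
  first_ckd <- ckd_claims %>%
    group_by(.data$patient_id) %>%
    summarise(ckd_diagnosis_date = min(.data$service_date), .groups = "drop")

  info <- first_ckd %>%
    left_join(data$patients, by = "patient_id") %>%
    mutate(
      age_at_dx = floor(days_between(.data$birth_date,
                                     .data$ckd_diagnosis_date) / 365.25),
      pre_period = .data$ckd_diagnosis_date < index_period[1],
      post_period = .data$ckd_diagnosis_date > index_period[2],
      minor = .data$age_at_dx < min_age,
      no_lookback = .data$enroll_start >
        .data$ckd_diagnosis_date - washout_days)

  excl <- c(ckd_before_index_period = sum(info$pre_period),
            ckd_after_index_period = sum(!info$pre_period & info$post_period),
            under_min_age = sum(!info$pre_period & !info$post_period &
                                  info$minor),
            insufficient_lookback = sum(!info$pre_period & !info$post_period &
                                          !info$minor & info$no_lookback))
  out <- info %>%
    filter(!.data$pre_period, !.data$post_period, !.data$minor,
           !.data$no_lookback) %>%
    select("patient_id", "ckd_diagnosis_date") %>%
    arrange(.data$patient_id)
  attr(out, "exclusions") <- excl
  out
}

#' Split new-onset CKD patients into HK and non-HK cohorts
#'
#' HK members have at least one HK-coded claim on or after their CKD
#' diagnosis; their index date is the earliest such claim. Non-HK candidates
#' are free of HK-coded claims anywhere in the data window; patients whose
#' only HK claims precede CKD diagnosis belong to neither set.
#'
#' @inheritParams find_new_onset_ckd
#' @param ckd_table Output of [find_new_onset_ckd()].
#' @return A list of tibbles `hk_members` (`patient_id`,
#'   `ckd_diagnosis_date`, `index_date`) and `non_hk_candidates`
#'   (`patient_id`, `ckd_diagnosis_date`); the two sets are disjoint.
#' @export
assign_cohorts <- function(ckd_table, data, codes) {
  stopifnot(inherits(data, "claims_dataset"), inherits(codes, "code_set"))
  hk_claims <- claims_with_code(data$claims, codes$hk_codes) %>%
    semi_join(ckd_table, by = "patient_id")
  post_dx_hk <- hk_claims %>%
    inner_join(ckd_table, by = "patient_id") %>%
    filter(.data$service_date >= .data$ckd_diagnosis_date)
  first_hk <- if (nrow(post_dx_hk) == 0) {
    tibble(patient_id = integer(), index_date = as.Date(character()))
  } else {
    post_dx_hk %>%
      group_by(.data$patient_id) %>%
      summarise(index_date = min(.data$service_date), .groups = "drop")
  }
  any_hk <- unique(hk_claims$patient_id)

  hk_members <- ckd_table %>%
    inner_join(first_hk, by = "patient_id") %>%
    arrange(.data$patient_id)
  non_hk <- ckd_table %>%
    filter(!.data$patient_id %in% any_hk) %>%
    arrange(.data$patient_id)
  list(hk_members = hk_members, non_hk_candidates = non_hk)
}

#' Apply the continuous-enrollment filter and set follow-up fields
#'
#' Members are retained when their enrollment span covers the full baseline
#' window `[index - baseline_days, index]` and either the full follow-up
#' window `[index, index + followup_days]` or, when death occurs first,
#' enrollment through the death date (discontinuation due to death is
#' allowed). Members dead or unenrolled at index are dropped. Sets
#' `followup_end = min(enroll_end, death_date, study_end)`,
#' `died_within_12m`, and `ckd_duration_months = floor((index - dx)/30)`.
#'
#' @param members Tibble with `patient_id`, `ckd_diagnosis_date`,
#'   `index_date` (plus any other columns, preserved).
#' @param data A [claims_dataset()].
#' @param baseline_days,followup_days Window lengths in days (default 360).
#' @param study_end Administrative end of data; defaults to the latest
#'   enrollment end in `data`.
#' @return Filtered members with `death_date`, `followup_end`,
#'   `died_within_12m`, `ckd_duration_months` added, and an `exclusions`
#'   attribute counting the drops by reason.
#' @export
apply_enrollment_filter <- function(members, data, baseline_days = 360,
                                    followup_days = 360, study_end = NULL) {
  stopifnot(inherits(data, "claims_dataset"))
  study_end <- as.Date(study_end %||% max(data$patients$enroll_end))
  info <- members %>%
    select(-any_of(c("death_date", "followup_end", "died_within_12m",
                     "ckd_duration_months"))) %>%
    left_join(data$patients %>%
                select("patient_id", "death_date", "enroll_start",
                       "enroll_end"),
              by = "patient_id") %>%
    mutate(
      dead_at_index = !is.na(.data$death_date) &
        .data$death_date < .data$index_date,
      baseline_ok = .data$enroll_start <= .data$index_date - baseline_days,
      death_in_followup = !is.na(.data$death_date) &
        .data$death_date <= .data$index_date + followup_days,
      followup_ok = .data$enroll_end >= .data$index_date + followup_days |
        (.data$death_in_followup & .data$enroll_end >= .data$death_date))

  excl <- c(dead_at_index = sum(info$dead_at_index),
            baseline_gap = sum(!info$dead_at_index & !info$baseline_ok),
            followup_gap = sum(!info$dead_at_index & info$baseline_ok &
                                 !info$followup_ok))
  out <- info %>%
    filter(!.data$dead_at_index, .data$baseline_ok, .data$followup_ok) %>%
    mutate(
      followup_end = pmin(.data$enroll_end,
                          coalesce(.data$death_date, study_end), study_end),
      died_within_12m = !is.na(.data$death_date) &
        days_between(.data$index_date, .data$death_date) < followup_days,
      ckd_duration_months = floor(days_between(.data$ckd_diagnosis_date,
                                               .data$index_date) /
                                    DAYS_PER_MONTH)) %>%
    select(-"enroll_start", -"enroll_end", -"dead_at_index", -"baseline_ok",
           -"death_in_followup", -"followup_ok") %>%
    arrange(.data$patient_id)
  attr(out, "exclusions") <- excl
  out
}
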