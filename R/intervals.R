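#' Follow-up interval grid
#'
#' The follow-up year is divided into `n_intervals` fixed-width windows;
#' interval k is the half-open `[width * (k-1), width * k)` days after index.
#' With the defaults that is twelve 30-day "months".
#'
#' @param n_intervals Number of intervals (default 12).
#' @param width_days Interval width in days (default 30).
#' @return An `interval_grid` list with `n_intervals`, `width_days`, and the
#'   interval start offsets.
#' @export
interval_grid <- function(n_intervals = 12, width_days = DAYS_PER_MONTH) {
  stopifnot(n_intervals >= 1, width_days >= 1)
  structure(list(n_intervals = as.integer(n_intervals),
                 width_days = width_days,
                 starts = (seq_len(n_intervals) - 1) * width_days),
            class = "interval_grid")
}

# Outcome columns produced by accrue_intervals, in reporting order.
interval_outcome_columns <- function() {
  comps <- c("medication", "examination", "treatment", "surgery",
             "consumable", "other")
  c("cost_total", "cost_inpatient", "cost_outpatient",
    paste0("cost_total_", comps),
    paste0("cost_inpatient_", comps),
    paste0("cost_outpatient_", comps),
    "n_admissions", "los_days", "n_outpatient")
}

#' Accrue per-patient, per-interval outcomes
#'
#' Assigns each follow-up claim to the interval containing its service date
#' (inpatient claims by admission date, so an admission's full cost and
#' length of stay belong to its admission interval; the index
#' hospitalization falls in interval 1). Outcomes are the six cost
#' components split by setting, setting totals, the overall total, admission
#' and outpatient counts, and length of stay (discharge - admission + 1
#' days). Claims outside the follow-up window or after `followup_end` are
#' ignored. Rows are complete over members x intervals (zeros where nothing
#' was accrued), with at-risk flags `alive_at_start` and `enrolled_at_start`.
#'
#' @param members Filtered members (with `cohort`, `index_date`,
#'   `death_date`, `followup_end`).
#' @param data A [claims_dataset()].
#' @param grid An [interval_grid()].
#' @return An `interval_outcomes` tibble keyed by (`patient_id`,
#'   `interval`), carrying the member fields needed downstream
#'   (`cohort`, `time`, `event` at the grid horizon) as attributes
#'   `members`.
#' @export
accrue_intervals <- function(members, data, grid = interval_grid()) {
  stopifnot(inherits(data, "claims_dataset"), inherits(grid, "interval_grid"))
  horizon <- grid$n_intervals * grid$width_days

  cl <- data$claims %>%
    inner_join(members %>%
                 select("patient_id", "index_date", "followup_end"),
               by = "patient_id") %>%
    mutate(event_date = if_else(.data$setting == "inpatient",
                                .data$admission_date, .data$service_date),
           off = days_between(.data$index_date, .data$event_date)) %>%
    filter(.data$off >= 0, .data$off < horizon,
           .data$event_date <= .data$followup_end) %>%
    mutate(interval = floor(.data$off / grid$width_days) + 1,
           ip = .data$setting == "inpatient",
           cost_claim = .data$cost_medication + .data$cost_examination +
             .data$cost_treatment + .data$cost_surgery +
             .data$cost_consumable + .data$cost_other,
           los = ifelse(.data$ip,
                        days_between(.data$admission_date,
                                     .data$discharge_date) + 1, 0))

  sum_ip <- function(x, ip) sum(x * ip)
  acc <- cl %>%
    group_by(.data$patient_id, .data$interval) %>%
    summarise(
      cost_total = sum(.data$cost_claim),
      cost_inpatient = sum_ip(.data$cost_claim, .data$ip),
      cost_total_medication = sum(.data$cost_medication),
      cost_total_examination = sum(.data$cost_examination),
      cost_total_treatment = sum(.data$cost_treatment),
      cost_total_surgery = sum(.data$cost_surgery),
      cost_total_consumable = sum(.data$cost_consumable),
      cost_total_other = sum(.data$cost_other),
      cost_inpatient_medication = sum_ip(.data$cost_medication, .data$ip),
      cost_inpatient_examination = sum_ip(.data$cost_examination, .data$ip),
      cost_inpatient_treatment = sum_ip(.data$cost_treatment, .data$ip),
      cost_inpatient_surgery = sum_ip(.data$cost_surgery, .data$ip),
      cost_inpatient_consumable = sum_ip(.data$cost_consumable, .data$ip),
      cost_inpatient_other = sum_ip(.data$cost_other, .data$ip),
      n_admissions = sum(.data$ip),
      los_days = sum(.data$los),
      n_outpatient = sum(!.data$ip),
      .groups = "drop")

  full <- tidyr::expand_grid(patient_id = members$patient_id,
                             interval = seq_len(grid$n_intervals)) %>%
    left_join(acc, by = c("patient_id", "interval")) %>%
    mutate(across(-c("patient_id", "interval"), ~coalesce(.x, 0)),
           cost_outpatient = .data$cost_total - .data$cost_inpatient,
           cost_outpatient_medication = .data$cost_total_medication -
             .data$cost_inpatient_medication,
           cost_outpatient_examination = .data$cost_total_examination -
             .data$cost_inpatient_examination,
           cost_outpatient_treatment = .data$cost_total_treatment -
             .data$cost_inpatient_treatment,
           cost_outpatient_surgery = .data$cost_total_surgery -
             .data$cost_inpatient_surgery,
           cost_outpatient_consumable = .data$cost_total_consumable -
             .data$cost_inpatient_consumable,
           cost_outpatient_other = .data$cost_total_other -
             .data$cost_inpatient_other)

  info <- members %>%
    mutate(
      death_off = ifelse(is.na(.data$death_date), Inf,
                         days_between(.data$index_date, .data$death_date)),
      enroll_off = days_between(.data$index_date, .data$followup_end)) %>%
    select("patient_id", any_of("cohort"), "death_off", "enroll_off")

  out <- full %>%
    left_join(info, by = "patient_id") %>%
    mutate(start = (.data$interval - 1) * grid$width_days,
           alive_at_start = .data$death_off > .data$start,
           enrolled_at_start = .data$enroll_off > .data$start,
           # a patient outside the at-risk set contributes nothing to the
           # interval (e.g. claims dated on the death day itself when death
           # falls exactly on an interval boundary)
           across(all_of(interval_outcome_columns()),
                  ~.x * (.data$alive_at_start & .data$enrolled_at_start))) %>%
    select(-"death_off", -"enroll_off", -"start") %>%
    relocate("patient_id", any_of("cohort"), "interval",
             "alive_at_start", "enrolled_at_start",
             all_of(interval_outcome_columns()))

  structure(out, class = c("interval_outcomes", class(out)),
            grid = grid, members = members)
}
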