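#' Per-admission / per-visit metrics among matched service users
#'
#' Raw (unweighted) follow-up summaries restricted to pairs in which *both*
#' members used the service: `rule = "hospitalized"` keeps pairs where both
#' members have >= 1 admission in the follow-up year, `rule = "outpatient"`
#' pairs where both have >= 1 outpatient visit. Reports mean +/- SD (median)
#' of the usage count and of per-admission length of stay and per-admission /
#' per-visit cost, by cohort, with Student's t-test p-values. An empty
#' qualifying subset returns an empty report.
#'
#' @param pairs A [match_1to1()] result.
#' @param outcomes An [accrue_intervals()] result covering the matched
#'   members.
#' @param rule `"hospitalized"` or `"outpatient"`.
#' @return A `subgroup_summary` tibble: `metric`, `mean_hk`, `sd_hk`,
#'   `median_hk`, `mean_control`, `sd_control`, `median_control`,
#'   `difference`, `p_value`, with attribute `n_pairs`.
#' @export
summarize_subgroup <- function(pairs, outcomes,
                               rule = c("hospitalized", "outpatient")) {
  rule <- match.arg(rule)
  stopifnot(inherits(pairs, "matched_pairs"),
            inherits(outcomes, "interval_outcomes"))
  per_pat <- outcomes %>%
    group_by(.data$patient_id) %>%
    summarise(n_admissions = sum(.data$n_admissions),
              los_days = sum(.data$los_days),
              n_outpatient = sum(.data$n_outpatient),
              cost_inpatient = sum(.data$cost_inpatient),
              cost_outpatient = sum(.data$cost_outpatient),
              .groups = "drop")
  uses <- function(id) {
    x <- per_pat[match(id, per_pat$patient_id), ]
    if (rule == "hospitalized") x$n_admissions >= 1 else x$n_outpatient >= 1
  }
  keep <- uses(pairs$hk_id) & uses(pairs$control_id)
  kept <- pairs[which(keep), , drop = FALSE]
  if (nrow(kept) == 0) {
    out <- tibble(metric = character(), mean_hk = double(), sd_hk = double(),
                  median_hk = double(), mean_control = double(),
                  sd_control = double(), median_control = double(),
                  difference = double(), p_value = double())
    return(structure(out, class = c("subgroup_summary", class(out)),
                     n_pairs = 0L, rule = rule))
  }
  hk <- per_pat[match(kept$hk_id, per_pat$patient_id), ]
  ct <- per_pat[match(kept$control_id, per_pat$patient_id), ]

  metrics <- if (rule == "hospitalized") {
    list(n_admissions = function(d) d$n_admissions,
         los_per_admission = function(d) d$los_days / d$n_admissions,
         cost_per_admission = function(d) d$cost_inpatient / d$n_admissions)
  } else {
    list(n_outpatient_visits = function(d) d$n_outpatient,
         cost_per_visit = function(d) d$cost_outpatient / d$n_outpatient)
  }
  rows <- purrr::imap(metrics, function(f, nm) {
    x <- f(hk); y <- f(ct)
    tibble(metric = nm,
           mean_hk = mean(x), sd_hk = sd(x), median_hk = median(x),
           mean_control = mean(y), sd_control = sd(y),
           median_control = median(y),
           difference = mean(x) - mean(y),
           p_value = if (length(x) < 2) {
             NA_real_
           } else if (sd(x) == 0 && sd(y) == 0) {
             if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
           } else unname(t.test(x, y, var.equal = TRUE)$p.value))
  })
  out <- bind_rows(rows)
  structure(out, class = c("subgroup_summary", class(out)),
            n_pairs = nrow(kept), rule = rule)
}
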