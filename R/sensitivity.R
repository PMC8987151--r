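#' Sensitivity analysis: exclude pairs touched by malignant disease
#'
#' Drops every matched pair in which either member has a malignancy-coded
#' claim at any time in the data window, then re-runs the survival and KMSA
#' analyses on the surviving pairs (no re-matching, preserving the matched
#' design). An empty surviving set is reported, not fatal.
#'
#' @param pairs A [match_1to1()] result.
#' @param members The matched members table (with cohort and follow-up
#'   fields).
#' @param data A [claims_dataset()].
#' @param config An [analysis_config()] with non-empty
#'   `codes$malignancy_codes`.
#' @return A list like the main analysis (`pairs`, `mortality`, `kmsa`, ...)
#'   plus `n_pairs_dropped`, or a stub with `n_pairs = 0`.
#' @export
sensitivity_no_malignancy <- function(pairs, members, data, config) {
  if (length(config$codes$malignancy_codes) == 0) {
    abort("no malignancy codes configured")
  }
  malig_ids <- unique(
    claims_with_code(data$claims, config$codes$malignancy_codes)$patient_id)
  keep <- !(pairs$hk_id %in% malig_ids | pairs$control_id %in% malig_ids)
  kept <- pairs[which(keep), , drop = FALSE]
  attr(kept, "caliper") <- attr(pairs, "caliper")
  class(kept) <- class(pairs)
  if (nrow(kept) == 0) {
    return(list(n_pairs = 0L, n_pairs_dropped = nrow(pairs),
                note = "no pairs free of malignancy"))
  }
  out <- analyze_pairs(kept, members, data, config)
  out$n_pairs <- nrow(kept)
  out$n_pairs_dropped <- nrow(pairs) - nrow(kept)
  out
}

#' Sensitivity analysis: 12-month survivors only
#'
#' Restricts to pairs in which both members are alive and enrolled through
#' the full follow-up year. Within this subset no deaths occur before the
#' horizon, every KMSA survival weight is 1, and the estimates equal the
#' plain arithmetic means of patient annual totals.
#'
#' @inheritParams sensitivity_no_malignancy
#' @return As [sensitivity_no_malignancy()].
#' @export
sensitivity_survivors <- function(pairs, members, data, config) {
  horizon <- config$followup_days
  info <- members %>%
    mutate(survived = (is.na(.data$death_date) |
                         days_between(.data$index_date, .data$death_date) >=
                         horizon) &
             days_between(.data$index_date, .data$followup_end) >= horizon)
  surv_ids <- info$patient_id[info$survived]
  keep <- pairs$hk_id %in% surv_ids & pairs$control_id %in% surv_ids
  kept <- pairs[which(keep), , drop = FALSE]
  attr(kept, "caliper") <- attr(pairs, "caliper")
  class(kept) <- class(pairs)
  if (nrow(kept) == 0) {
    return(list(n_pairs = 0L, n_pairs_dropped = nrow(pairs),
                note = "no fully-surviving pairs"))
  }
  out <- analyze_pairs(kept, members, data, config)
  out$n_pairs <- nrow(kept)
  out$n_pairs_dropped <- nrow(pairs) - nrow(kept)
  out
}
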