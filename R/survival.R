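#' Build a survival sample from cohort members
#'
#' Time is days from the index date to death, disenrollment, or the analysis
#' horizon, whichever comes first; the event indicator marks death before
#' censoring. With `horizon_days = 360` this is the 12-month analysis; with
#' `horizon_days = NULL` follow-up runs to each member's `followup_end`
#' (index date to end of study).
#'
#' @param members Filtered members with `cohort`, `index_date`, `death_date`,
#'   `followup_end`.
#' @param horizon_days Truncation horizon in days, or `NULL` for full
#'   follow-up.
#' @return A tibble `(patient_id, cohort, time, event)` with `time > 0`.
#' @export
surv_sample <- function(members, horizon_days = 360) {
  stopifnot(all(c("index_date", "followup_end") %in% names(members)))
  horizon <- horizon_days %||% Inf
  members %>%
    transmute(
      .data$patient_id,
      cohort = .data$cohort,
      death_off = ifelse(is.na(.data$death_date), Inf,
                         days_between(.data$index_date, .data$death_date)),
      cens_off = pmin(days_between(.data$index_date, .data$followup_end),
                      horizon),
      time = pmax(1, pmin(.data$death_off, .data$cens_off)),
      # a death on the horizon day itself counts as surviving the window
      event = .data$death_off <= .data$cens_off & .data$death_off < horizon) %>%
    select(-"death_off", -"cens_off")
}

#' Kaplan-Meier product-limit estimate
#'
#' Computed by [survival::survfit()]; ties between deaths and censorings at
#' the same time are resolved deaths-first (the product-limit convention).
#'
#' @param sample A [surv_sample()] tibble (or any tibble with `time`,
#'   `event`, optionally `cohort`).
#' @param group Optional cohort label to restrict to one group.
#' @return A `km_curve` tibble `(time, n_risk, n_event, n_censor, survival)`
#'   containing the distinct observed times.
#' @export
km_estimate <- function(sample, group = NULL) {
  if (!is.null(group)) sample <- filter(sample, .data$cohort == group)
  if (nrow(sample) == 0) abort("empty group in km_estimate")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sample)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, survival = fit$surv)
  structure(out, class = c("km_curve", class(out)), group = group,
            n = nrow(sample))
}

# Step-function lookup: S(t) with S(0) = 1, right-continuous.
km_survival_at <- function(km, times) {
  vapply(times, function(t) {
    i <- which(km$time <= t)
    if (!length(i)) 1 else km$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard O-E log-rank statistic on 1 degree of freedom, via
#' [survival::survdiff()].
#'
#' @param sample A [surv_sample()] tibble with exactly two cohort levels.
#' @return A tibble `(statistic, df, p_value)`.
#' @export
logrank_test <- function(sample) {
  if (length(unique(sample$cohort)) != 2 ||
      any(table(sample$cohort) == 0)) {
    abort("logrank_test needs two non-empty groups")
  }
  if (sum(sample$event) == 0) {
    return(tibble(statistic = 0, df = 1, p_value = 1))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ cohort,
                            data = sample)
  tibble(statistic = fit$chisq, df = length(fit$n) - 1,
         p_value = stats::pchisq(fit$chisq, length(fit$n) - 1,
                                 lower.tail = FALSE))
}

#' Cox proportional-hazards estimate of the HK mortality effect
#'
#' Single binary covariate (HK indicator), partial likelihood with Breslow
#' tie handling (Efron available via `ties`), Wald 95% CI and p-value.
#' When one group has no events the partial likelihood is monotone; a
#' warning is raised and a penalized (ridge) fit reported instead.
#'
#' @param sample A [surv_sample()] tibble with a `cohort` column; the
#'   `"HK"` level is the exposure.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param stratify_pairs If `TRUE` and a `pair_id` column is present, the
#'   baseline hazard is stratified on matched pairs.
#' @return A `cox_result` list: `log_hr`, `se`, `hr`, `ci95`, `p_value`,
#'   `n`, `n_events`. Has [tidy()] and [glance()] methods.
#' @export
cox_fit <- function(sample, ties = "breslow", stratify_pairs = FALSE) {
  sample <- mutate(sample, hk_ind = as.numeric(.data$cohort == "HK"))
  monotone <- sum(sample$event & sample$hk_ind == 1) == 0 ||
    sum(sample$event & sample$hk_ind == 0) == 0
  form <- if (stratify_pairs && "pair_id" %in% names(sample)) {
    survival::Surv(time, event) ~ hk_ind + survival::strata(pair_id)
  } else {
    survival::Surv(time, event) ~ hk_ind
  }
  if (monotone) {
    warn("a group has no events: monotone partial likelihood, reporting penalized fit")
    fit <- suppressWarnings(survival::coxph(
      update(form, . ~ . - hk_ind + survival::ridge(hk_ind, theta = 1)),
      data = sample, ties = ties))
    log_hr <- unname(coef(fit)[1])
    se <- sqrt(fit$var[1, 1])
  } else {
    fit <- survival::coxph(form, data = sample, ties = ties,
                           control = survival::coxph.control(eps = 1e-10,
                                                             iter.max = 50))
    log_hr <- unname(coef(fit)[["hk_ind"]])
    se <- sqrt(fit$var[1, 1])
  }
  structure(
    list(log_hr = log_hr, se = se, hr = exp(log_hr),
         ci95 = exp(log_hr + c(-1, 1) * 1.96 * se),
         p_value = 2 * stats::pnorm(-abs(log_hr / se)),
         n = nrow(sample), n_events = sum(sample$event),
         ties = ties, penalized = monotone),
    class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> HR %.3f [%.3f, %.3f], p = %.3g (%d events / %d)\n",
              x$hr, x$ci95[1], x$ci95[2], x$p_value, x$n_events, x$n))
  invisible(x)
}
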