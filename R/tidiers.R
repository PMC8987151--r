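#' Broom-style tidiers
#'
#' `tidy()` returns the per-term / per-interval detail of a fitted object as
#' a tibble; `glance()` returns a one-row model summary.
#'
#' @param x A `propensity_model`, `cox_result`, `kmsa_estimate`, or
#'   `matched_pairs` object.
#' @param ... Unused.
#' @name kmsacohort-tidiers
NULL

#' @rdname kmsacohort-tidiers
#' @exportS3Method generics::tidy
tidy.propensity_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname kmsacohort-tidiers
#' @exportS3Method generics::glance
glance.propensity_model <- function(x, ...) {
  tibble(n = nrow(x$scores), n_hk = sum(x$scores$hk),
         n_covariates = length(x$coefficients),
         auc = propensity_auc(x), separation = x$separation)
}

#' @rdname kmsacohort-tidiers
#' @exportS3Method generics::tidy
tidy.cox_result <- function(x, ...) {
  tibble(term = "hk", estimate = x$log_hr, std.error = x$se,
         hr = x$hr, conf.low = x$ci95[1], conf.high = x$ci95[2],
         p.value = x$p_value)
}

#' @rdname kmsacohort-tidiers
#' @exportS3Method generics::glance
glance.cox_result <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, ties = x$ties,
         penalized = x$penalized)
}

#' @rdname kmsacohort-tidiers
#' @exportS3Method generics::tidy
tidy.kmsa_estimate <- function(x, ...) {
  d <- attr(x, "detail")
  tidyr::expand_grid(outcome = x$outcome,
                     interval = seq_along(d$S)) %>%
    mutate(survival_weight = d$S[.data$interval],
           n_at_risk = d$n_at[.data$interval],
           conditional_mean = as.vector(t(d$cbar))[
             (match(.data$outcome, x$outcome) - 1) * length(d$S) +
               .data$interval])
}

#' @rdname kmsacohort-tidiers
#' @exportS3Method generics::glance
glance.kmsa_estimate <- function(x, ...) {
  d <- attr(x, "detail")
  tibble(n_outcomes = nrow(x), n_intervals = length(d$S),
         n_members = max(d$n_at))
}

#' @rdname kmsacohort-tidiers
#' @exportS3Method generics::glance
glance.matched_pairs <- function(x, ...) {
  tibble(n_pairs = nrow(x), caliper = attr(x, "caliper"),
         n_unmatched_hk = length(attr(x, "unmatched_hk")))
}
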