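#' Bootstrap configuration for KMSA confidence intervals
#'
#' @param n_iterations Bootstrap iterations (default 1000).
#' @param pairs_per_iteration Matched pairs drawn (with replacement) per
#'   iteration, or `NULL` (default) for full-n resampling (as many pairs as
#'   exist). Setting a value below the number of pairs gives the
#'   m-out-of-n variant.
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed; resampling is deterministic given it.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_iterations = 1000, pairs_per_iteration = NULL,
                             ci_level = 0.95, seed = 1L) {
  if (n_iterations < 1) abort("`n_iterations` must be >= 1")
  check_prob(ci_level, "ci_level")
  if (n_iterations < 100 && ci_level >= 0.9) {
    warn("fewer than 100 bootstrap iterations: percentile CIs will be unstable")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 pairs_per_iteration = pairs_per_iteration,
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "bootstrap_config")
}

# members x (outcome, interval) matrix in fixed column order, plus the
# member's 12-month survival time/event, aligned to `ids`.
kmsa_arrays <- function(outcomes, ids, cols, grid) {
  K <- grid$n_intervals
  sub <- outcomes[outcomes$patient_id %in% ids, , drop = FALSE]
  ord <- order(match(sub$patient_id, ids), sub$interval)
  sub <- sub[ord, , drop = FALSE]
  n <- length(ids)
  stopifnot(nrow(sub) == n * K)
  M <- matrix(0, n, K * length(cols))
  for (j in seq_along(cols)) {
    M[, (j - 1) * K + seq_len(K)] <-
      matrix(sub[[cols[j]]], n, K, byrow = TRUE)
  }
  mem <- attr(outcomes, "members")
  mem <- mem[match(ids, mem$patient_id), , drop = FALSE]
  horizon <- K * grid$width_days
  death_off <- ifelse(is.na(mem$death_date), Inf,
                      days_between(mem$index_date, mem$death_date))
  cens_off <- pmin(days_between(mem$index_date, mem$followup_end), horizon)
  time <- pmax(1, pmin(death_off, cens_off))
  event <- death_off <= cens_off & death_off < horizon
  list(M = M, time = time, event = event, cols = cols, K = K,
       starts = grid$starts)
}

# Weighted product-limit survival evaluated at the interval starts, plus the
# weighted at-risk mass at each start. Censoring-and-death ties resolve
# deaths-first; weights are resampling multiplicities.
km_weights_at_starts <- function(time, event, w, starts) {
  n_at <- vapply(starts, function(s) sum(w[time > s]), numeric(1))
  dd <- time[event]
  wd <- w[event]
  if (!length(dd) || all(wd == 0)) {
    return(list(S = rep(1, length(starts)), n_at = n_at))
  }
  agg <- rowsum(wd, dd)
  days <- as.numeric(rownames(agg))
  o <- order(days)
  days <- days[o]; deaths <- agg[o]
  # weighted at-risk mass at each death day: total minus everyone (dead or
  # censored) who left strictly before it; censored-at-d stay at risk
  agg_all <- rowsum(w, time)
  t_all <- as.numeric(rownames(agg_all))
  oo <- order(t_all)
  t_all <- t_all[oo]
  cum_le <- cumsum(agg_all[oo])
  total <- sum(w)
  pos <- match(days, t_all)
  at_risk <- total - c(0, cum_le)[pos]
  surv_steps <- cumprod(ifelse(at_risk > 0, 1 - deaths / at_risk, 1))
  S <- vapply(starts, function(s) {
    i <- which(days <= s)
    if (!length(i)) 1 else surv_steps[max(i)]
  }, numeric(1))
  list(S = S, n_at = n_at)
}

# Core KMSA reduction: for each outcome, sum_k S(t_{k-1}) * Cbar_k where
# Cbar_k = (weighted sum of interval-k outcomes) / (weighted at-risk mass at
# the interval start). Returns the estimate vector (and details on request).
kmsa_core <- function(arr, w = NULL, detail = FALSE) {
  n <- nrow(arr$M)
  if (is.null(w)) w <- rep(1, n)
  km <- km_weights_at_starts(arr$time, arr$event, w, arr$starts)
  sums <- drop(w %*% arr$M)
  K <- arr$K
  denom <- ifelse(km$n_at > 0, km$n_at, NA)
  est <- numeric(length(arr$cols))
  cbar_all <- matrix(0, length(arr$cols), K)
  for (j in seq_along(arr$cols)) {
    cbar <- sums[(j - 1) * K + seq_len(K)] / denom
    cbar[is.na(cbar)] <- 0  # interval with zero at-risk mass
    cbar_all[j, ] <- cbar
    est[j] <- sum(km$S * cbar)
  }
  names(est) <- arr$cols
  if (!detail) return(est)
  list(estimate = est, S = km$S, n_at = km$n_at, cbar = cbar_all)
}

#' KMSA point estimate of annual outcomes for one cohort
#'
#' The Kaplan-Meier sample average: the probability of surviving to the start
#' of each time interval, multiplied by the mean outcome incurred during that
#' interval among patients alive (and enrolled) at its start, summed over the
#' twelve post-index months. Patients dying mid-interval contribute their
#' observed partial-interval outcomes to that interval's conditional mean.
#' With no deaths and full enrollment every weight is 1 and the estimate
#' reduces exactly to the plain mean of patient annual totals.
#'
#' @param outcomes An [accrue_intervals()] result (one cohort's members, or
#'   filtered with `cohort_label`).
#' @param km Optional [km_estimate()] curve for the same cohort; by default
#'   the curve is estimated from the members behind `outcomes`. Supplying a
#'   curve allows externally-fixed survival weights.
#' @param grid The [interval_grid()] used for accrual.
#' @param outcome_cols Outcome columns to estimate (default: all).
#' @param cohort_label Optional cohort to restrict to.
#' @return A `kmsa_estimate` tibble `(outcome, estimate)` with per-interval
#'   detail (survival weights, conditional means, at-risk counts) in
#'   `attr(, "detail")`. Interval conditional means with zero at-risk
#'   patients are set to 0 with a warning.
#' @export
kmsa_point_estimate <- function(outcomes, km = NULL, grid = NULL,
                                outcome_cols = NULL, cohort_label = NULL) {
  stopifnot(inherits(outcomes, "interval_outcomes"))
  grid <- grid %||% attr(outcomes, "grid")
  members <- attr(outcomes, "members")
  if (!is.null(cohort_label)) {
    members <- filter(members, .data$cohort == cohort_label)
  }
  if (nrow(members) == 0) abort("no members in the requested cohort")
  cols <- outcome_cols %||% interval_outcome_columns()
  arr <- kmsa_arrays(outcomes, members$patient_id, cols, grid)
  if (!is.null(km)) {
    res <- kmsa_fixed_km(arr, km)
  } else {
    res <- kmsa_core(arr, detail = TRUE)
  }
  if (any(res$n_at == 0)) {
    warn("interval(s) with zero at-risk patients: conditional mean set to 0")
  }
  out <- tibble(outcome = cols, estimate = unname(res$estimate))
  structure(out, class = c("kmsa_estimate", class(out)),
            detail = list(S = res$S, n_at = res$n_at, cbar = res$cbar,
                          grid = grid, cohort = cohort_label))
}

# Same reduction but with survival weights read off a supplied KM curve.
kmsa_fixed_km <- function(arr, km) {
  S <- km_survival_at(km, arr$starts)
  n_at <- vapply(arr$starts, function(s) sum(arr$time > s), numeric(1))
  sums <- colSums(arr$M)
  K <- arr$K
  denom <- ifelse(n_at > 0, n_at, NA)
  est <- numeric(length(arr$cols))
  cbar_all <- matrix(0, length(arr$cols), K)
  for (j in seq_along(arr$cols)) {
    cbar <- sums[(j - 1) * K + seq_len(K)] / denom
    cbar[is.na(cbar)] <- 0
    cbar_all[j, ] <- cbar
    est[j] <- sum(S * cbar)
  }
  names(est) <- arr$cols
  list(estimate = est, S = S, n_at = n_at, cbar = cbar_all)
}

#' Paired-bootstrap confidence intervals for KMSA estimates
#'
#' The matched pair is the resampling unit: each iteration draws pairs with
#' replacement (all pairs by default; `pairs_per_iteration` gives the
#' m-out-of-n variant), re-estimates each cohort's Kaplan-Meier curve and
#' KMSA outcome estimates on the resample, and records the per-cohort
#' estimates and their difference. Percentile intervals at `ci_level` are
#' reported together with a two-sided bootstrap p-value for the difference
#' (the proportion of resampled differences crossing zero, doubled and
#' add-one smoothed). Deterministic given the config seed.
#'
#' @param pairs A [match_1to1()] result.
#' @param outcomes An [accrue_intervals()] result covering all matched
#'   members.
#' @param config A [bootstrap_config()].
#' @param outcome_cols Outcome columns (default: all).
#' @return A `kmsa_bootstrap` tibble with one row per outcome: point
#'   estimates `est_hk`, `est_control`, `diff`, percentile bounds
#'   `lo_hk/hi_hk`, `lo_control/hi_control`, `lo_diff/hi_diff`, and
#'   `p_boot`.
#' @export
paired_bootstrap <- function(pairs, outcomes, config = bootstrap_config(),
                             outcome_cols = NULL) {
  stopifnot(inherits(pairs, "matched_pairs"),
            inherits(outcomes, "interval_outcomes"),
            inherits(config, "bootstrap_config"))
  if (nrow(pairs) == 0) abort("no matched pairs to bootstrap")
  grid <- attr(outcomes, "grid")
  cols <- outcome_cols %||% interval_outcome_columns()
  m <- config$pairs_per_iteration %||% nrow(pairs)
  if (m > nrow(pairs)) {
    abort("`pairs_per_iteration` exceeds the number of matched pairs")
  }

  arr_hk <- kmsa_arrays(outcomes, pairs$hk_id, cols, grid)
  arr_ct <- kmsa_arrays(outcomes, pairs$control_id, cols, grid)
  n_pairs <- nrow(pairs)

  point_hk <- kmsa_core(arr_hk)
  point_ct <- kmsa_core(arr_ct)

  B <- config$n_iterations
  boot_hk <- matrix(NA_real_, B, length(cols))
  boot_ct <- matrix(NA_real_, B, length(cols))
  withr::with_seed(config$seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n_pairs, m, replace = TRUE)
      w <- tabulate(idx, n_pairs)  # the estimator is scale-invariant in w
      boot_hk[b, ] <- kmsa_core(arr_hk, w)
      boot_ct[b, ] <- kmsa_core(arr_ct, w)
    }
  })
  boot_diff <- boot_hk - boot_ct

  a <- (1 - config$ci_level) / 2
  qs <- function(mat) apply(mat, 2, quantile, probs = c(a, 1 - a),
                            names = FALSE)
  q_hk <- qs(boot_hk); q_ct <- qs(boot_ct); q_d <- qs(boot_diff)
  p_boot <- vapply(seq_along(cols), function(j) {
    d <- boot_diff[, j]
    min(1, 2 * min((sum(d <= 0) + 1) / (B + 1),
                   (sum(d >= 0) + 1) / (B + 1)))
  }, numeric(1))

  out <- tibble(outcome = cols,
                est_hk = unname(point_hk), est_control = unname(point_ct),
                diff = unname(point_hk - point_ct),
                lo_hk = q_hk[1, ], hi_hk = q_hk[2, ],
                lo_control = q_ct[1, ], hi_control = q_ct[2, ],
                lo_diff = q_d[1, ], hi_diff = q_d[2, ],
                p_boot = p_boot)
  structure(out, class = c("kmsa_bootstrap", class(out)),
            config = config, n_pairs = n_pairs)
}
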