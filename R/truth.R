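# Closed-form ground truth of the generator.
#
# HK membership: logit P(HK | z) = alpha + sum_j beta_j z_j over the flagged
# covariates, with alpha solved so the marginal equals hk_fraction.
# Death: exponential from the (arm-specific) time origin with per-day hazard
#   h(z, arm) = baseline_hazard/30 * exp(gamma' z + hk_log_hazard_ratio * HK).
# Costs: claims arrive as a Poisson process while alive, so the expected cost
# accrued in 30-day interval k given survival to its start is
#   steady_mean * (1 - exp(-30 h)) / (30 h),
# and the survival-weighted annual mean is a finite mixture of geometric-like
# sums over the flag combinations z.

# Flags that enter the HK logit, the hazard, or the malignancy cost bump.
truth_effect_flags <- function(cfg) {
  fl <- union(names(cfg$hk_logit_effects)[cfg$hk_logit_effects != 0],
              names(cfg$hazard_log_hr_effects)[cfg$hazard_log_hr_effects != 0])
  if (cfg$malignancy_monthly_cost_extra > 0) fl <- union(fl, "malignancy")
  fl
}

# Enumerate all combinations of the effect-bearing flags with their joint
# probability (flags are independent Bernoulli in the generator).
truth_flag_grid <- function(cfg) {
  flags <- truth_effect_flags(cfg)
  prev <- c(cfg$comorbidity_prevalences, cfg$drug_class_prevalences)[flags]
  if (length(flags) == 0) {
    return(list(z = matrix(0, 1, 0), prob = 1, flags = character()))
  }
  z <- as.matrix(expand.grid(rep(list(0:1), length(flags))))
  colnames(z) <- flags
  prob <- apply(z, 1, function(r) prod(ifelse(r == 1, prev, 1 - prev)))
  list(z = z, prob = prob, flags = flags)
}

effect_vector <- function(effects, flags) {
  out <- setNames(numeric(length(flags)), flags)
  common <- intersect(names(effects), flags)
  out[common] <- effects[common]
  out
}

# Intercept of the HK logit hitting the configured marginal hk_fraction.
solve_hk_intercept <- function(cfg, grid = truth_flag_grid(cfg)) {
  eta <- drop(grid$z %*% effect_vector(cfg$hk_logit_effects, grid$flags))
  if (cfg$hk_fraction == 0) return(-Inf)
  if (cfg$hk_fraction == 1) return(Inf)
  f <- function(a) sum(grid$prob * plogis(a + eta)) - cfg$hk_fraction
  uniroot(f, c(-30, 30), tol = 1e-12)$root
}

# P(z | arm) and per-day hazards for each flag combination.
truth_arm_mixture <- function(cfg, arm) {
  grid <- truth_flag_grid(cfg)
  alpha <- solve_hk_intercept(cfg, grid)
  eta <- drop(grid$z %*% effect_vector(cfg$hk_logit_effects, grid$flags))
  q <- plogis(alpha + eta)
  w <- if (arm == "HK") grid$prob * q else grid$prob * (1 - q)
  if (sum(w) == 0) abort(sprintf("arm '%s' has zero probability mass", arm))
  hz <- drop(grid$z %*% effect_vector(cfg$hazard_log_hr_effects, grid$flags))
  h_day <- cfg$baseline_hazard / DAYS_PER_MONTH *
    exp(hz + if (arm == "HK") cfg$hk_log_hazard_ratio else 0)
  malig <- if ("malignancy" %in% grid$flags) grid$z[, "malignancy"] else
    rep(0, length(w))
  list(w = w / sum(w), h_day = h_day, malignant = malig == 1)
}

match_arm <- function(arm) {
  a <- tolower(arm)
  if (a %in% c("hk", "hyperkalemia")) return("HK")
  if (a %in% c("control", "non-hk", "nonhk", "non_hk")) return("control")
  abort(sprintf("unknown arm label '%s' (use \"HK\" or \"control\")", arm))
}

# E[cost over one interval of `width` days | alive at its start], divided by
# the steady monthly mean: the expected fraction of the interval spent alive.
interval_alive_fraction <- function(h_day, width = DAYS_PER_MONTH) {
  ifelse(h_day == 0, 1, (1 - exp(-h_day * width)) / (h_day * width))
}

#' Closed-form survival-weighted mean annual cost of the generator
#'
#' Returns the analytic expectation of the 12-month Kaplan-Meier
#' sample-average (KMSA) cost estimand under the generator's own hazard and
#' cost process: `sum_k S(t_{k-1}) * E[cost in interval k | alive at start]`,
#' where S mixes the per-flag-combination exponential survival curves and the
#' HK arm additionally carries the index-month inpatient spike. Used as the
#' recovery-test oracle for the whole pipeline.
#'
#' @param config A [sim_config()].
#' @param arm `"HK"` or `"control"`.
#' @param n_intervals Number of 30-day intervals (default 12).
#' @return A single number (currency units of the config).
#' @examples
#' cfg <- sim_config(baseline_hazard = 1e-9, hk_fraction = 0.5,
#'                   hazard_log_hr_effects = c(hypertension = 0),
#'                   hk_log_hazard_ratio = 0)
#' # with a negligible hazard the control truth is 12 * steady monthly mean
#' truth_mean_annual_cost(cfg, "control")
#' @export
truth_mean_annual_cost <- function(config, arm, n_intervals = 12) {
  stopifnot(inherits(config, "sim_config"))
  arm <- match_arm(arm)
  mix <- truth_arm_mixture(config, arm)
  steady <- config$steady_monthly_cost[[if (arm == "HK") "hk" else "control"]][["mean"]]
  starts <- (seq_len(n_intervals) - 1) * DAYS_PER_MONTH
  total <- 0
  for (k in seq_len(n_intervals)) {
    s_k <- exp(-mix$h_day * starts[k])              # per-combination survival
    frac <- interval_alive_fraction(mix$h_day)
    monthly <- steady +
      config$malignancy_monthly_cost_extra * mix$malignant
    total <- total + sum(mix$w * s_k * frac * monthly)
  }
  if (arm == "HK") total <- total + config$index_month_inpatient_cost[["mean"]]
  total
}

# Arm-level true survival S(t) in days, mixing the exponential components.
truth_survival <- function(config, arm, t_days) {
  mix <- truth_arm_mixture(config, match_arm(arm))
  vapply(t_days, function(t) sum(mix$w * exp(-mix$h_day * t)), numeric(1))
}
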