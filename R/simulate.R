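# ICD-10 / drug-class codes the generator stamps onto claims for each
# configured flag. The covariate builder re-detects the flags from these codes
# through default_comorbidity_map(), so generation and measurement stay
# decoupled.
sim_comorbidity_codes <- function() {
  c(hypertension = "I10", dyslipidemia = "E78.5", t2dm = "E11.9",
    heart_failure = "I50.0", arrhythmia = "I48", angina = "I20.0",
    mi = "I21.9", other_cvd = "I25.1", stroke = "I63.9", tia = "G45.9",
    other_cbd = "I67.9", pvd = "I73.9", peptic_ulcer = "K27",
    copd = "J44.9", rheumatic = "M06.9", malignancy = "C34.9",
    dialysis = "Z49.0")
}

sim_ckd_code <- function() "N18.9"
sim_hk_code <- function() "E87.5"

#' Simulate a synthetic claims population with known ground truth
#'
#' Generates the three claims tables (patients/enrollment, itemized claims,
#' prescriptions) with the statistical structure the matched-cohort analysis
#' assumes: continuous enrollment spans with a death mechanism, ICD-10-coded
#' CKD and hyperkalemia diagnoses, comorbidity and drug-class covariates that
#' shift hyperkalemia membership (so cohorts are imbalanced before matching),
#' an exponential post-index death hazard elevated by
#' `exp(hk_log_hazard_ratio)` in the HK arm, and a cost process with a sharp
#' inpatient spike in the first post-index month. Identical config and seed
#' give byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `data`: a `claims_dataset` (list of tibbles `patients`, `claims`,
#'     `prescriptions`),
#'   * `truth`: a `ground_truth` list (`true_hr`,
#'     `true_mean_annual_cost_hk`, `true_mean_annual_cost_control`, and the
#'     per-patient latent arm/hazard/death table).
#' @examples
#' sim <- simulate_population(sim_config(n_patients = 200, rng_seed = 7))
#' sim$truth$true_hr
#' dplyr::count(sim$data$claims, setting)
#' @export
simulate_population <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$rng_seed, simulate_population_impl(config))
}

simulate_population_impl <- function(cfg) {
  n <- as.integer(cfg$n_patients)
  ids <- seq_len(n)
  day0 <- as.Date("1970-01-01")

  female <- runif(n) < cfg$female_fraction
  minor <- runif(n) < cfg$minor_fraction
  age <- rnorm(n, cfg$age_distribution[["mean"]], cfg$age_distribution[["sd"]])
  age[!minor] <- pmax(age[!minor], 18.5)
  age[minor] <- runif(sum(minor), 8, 17.4)

  cm_names <- names(cfg$comorbidity_prevalences)
  dr_names <- names(cfg$drug_class_prevalences)
  Zc <- vapply(cm_names,
               function(f) runif(n) < cfg$comorbidity_prevalences[[f]],
               logical(n))
  Zd <- vapply(dr_names,
               function(f) runif(n) < cfg$drug_class_prevalences[[f]],
               logical(n))
  if (n == 1) { Zc <- matrix(Zc, 1); Zd <- matrix(Zd, 1) }
  colnames(Zc) <- cm_names; colnames(Zd) <- dr_names
  Z <- cbind(Zc, Zd)

  # HK membership with confounding through the flagged covariates
  alpha <- solve_hk_intercept(cfg)
  eta <- drop(Z[, names(cfg$hk_logit_effects), drop = FALSE] %*%
                cfg$hk_logit_effects)
  p_hk <- plogis(alpha + eta)
  hk_assigned <- runif(n) < p_hk

  # first CKD diagnosis date, uniform over the index period
  p_len <- days_between(cfg$index_period[1], cfg$index_period[2])
  ckd_date <- cfg$index_period[1] + floor(runif(n) * (p_len + 1))
  birth_date <- ckd_date - round(age * 365.25)

  # CKD -> HK delay: truncated exponential on [1, days to end of period]
  max_delay <- days_between(ckd_date, cfg$index_period[2])
  rate <- 1 / cfg$ckd_to_hk_delay_mean
  can_hk <- hk_assigned & max_delay >= 2
  d_lo <- pexp(1, rate)
  d_hi <- pexp(pmax(max_delay, 2), rate)
  delay <- round(qexp(d_lo + runif(n) * (d_hi - d_lo), rate))
  delay <- pmax(1, pmin(delay, max_delay))
  hk_date <- dplyr::if_else(can_hk, ckd_date + delay, as.Date(NA))

  # enrollment spans; a small fraction has gaps that break the 12-month
  # baseline or follow-up coverage and is removed by the enrollment filter
  enroll_start <- ckd_date - 360 - floor(runif(n) * 361)
  enroll_end <- rep(cfg$study_end, n)
  gap <- runif(n) < cfg$enrollment_gap_prob
  gap_pre <- gap & runif(n) < 0.5
  gap_post <- gap & !gap_pre
  enroll_start[gap_pre] <- ckd_date[gap_pre] - floor(runif(sum(gap_pre)) * 201)
  enroll_end[gap_post] <- ckd_date[gap_post] +
    floor(runif(sum(gap_post), 200, 701))
  enroll_start <- pmax(enroll_start, cfg$data_start)
  enroll_end <- pmin(enroll_end, cfg$study_end)

  hk_eff <- can_hk & !is.na(hk_date) & hk_date <= enroll_end

  # death: exponential hazard from the arm-specific origin (HK index date for
  # the HK arm, CKD diagnosis otherwise; the exponential is memoryless, so a
  # control's residual survival from any later assigned index keeps the rate)
  gamma <- effect_vector(cfg$hazard_log_hr_effects, colnames(Z))
  h_day <- cfg$baseline_hazard / DAYS_PER_MONTH *
    exp(drop(Z %*% gamma) + cfg$hk_log_hazard_ratio * hk_eff)
  origin <- dplyr::if_else(hk_eff, hk_date, ckd_date)
  death_off <- pmax(1, ceiling(rexp(n, rate = h_day)))
  death_latent <- origin + death_off
  active_end <- pmin(enroll_end, death_latent)
  death_date <- dplyr::if_else(death_latent <= active_end, death_latent,
                               as.Date(NA))

  prior_ckd <- runif(n) < cfg$prior_ckd_fraction &
    enroll_start < cfg$index_period[1]

  span_days <- days_between(enroll_start, active_end) + 1

  steady <- cfg$steady_monthly_cost
  cv <- c(hk = steady$hk[["sd"]] / steady$hk[["mean"]],
          control = steady$control[["sd"]] / steady$control[["mean"]])
  lam_o <- cfg$monthly_outpatient_rate
  lam_a <- cfg$admission_rate
  if (cfg$malignancy_monthly_cost_extra > 0 && lam_o <= 0) {
    abort("`malignancy_monthly_cost_extra` requires `monthly_outpatient_rate` > 0")
  }

  claim_cost <- function(is_hk_claim, base_per_claim) {
    # base_per_claim: named c(hk=, control=) per-claim means
    out <- numeric(length(is_hk_claim))
    for (arm in c(TRUE, FALSE)) {
      sel <- is_hk_claim == arm
      if (!any(sel)) next
      a <- if (arm) "hk" else "control"
      out[sel] <- rlnorm_mean(sum(sel), base_per_claim[[a]],
                              base_per_claim[[a]] * cv[[a]])
    }
    out
  }

  ## ---- outpatient claims -------------------------------------------------
  out_list <- NULL
  if (lam_o > 0) {
    n_out <- rpois(n, lam_o / DAYS_PER_MONTH * span_days)
    pat <- rep(ids, n_out)
    day <- rep(enroll_start, n_out) +
      floor(runif(length(pat)) * rep(span_days, n_out))
    post <- hk_eff[pat] & !is.na(hk_date[pat]) & day >= hk_date[pat]
    c_out <- c(hk = (1 - cfg$inpatient_cost_share) * steady$hk[["mean"]] / lam_o,
               control = (1 - cfg$inpatient_cost_share) *
                 steady$control[["mean"]] / lam_o)
    cost <- claim_cost(post, c_out)
    if (cfg$malignancy_monthly_cost_extra > 0) {
      malig <- Zc[, "malignancy"][pat]
      cost[malig] <- cost[malig] + cfg$malignancy_monthly_cost_extra / lam_o
    }
    out_list <- tibble(patient_id = pat, setting = "outpatient",
                       service_date = day,
                       admission_date = as.Date(NA), discharge_date = as.Date(NA),
                       cost_total = cost)
  }

  # guaranteed outpatient claim on the CKD diagnosis date (the claim that
  # defines new onset); prior-CKD patients get an extra pre-period CKD claim
  dx_claim <- tibble(patient_id = ids, setting = "outpatient",
                     service_date = ckd_date,
                     admission_date = as.Date(NA), discharge_date = as.Date(NA),
                     cost_total = claim_cost(rep(FALSE, n), c(
                       hk = (1 - cfg$inpatient_cost_share) * steady$hk[["mean"]] /
                         max(lam_o, 1),
                       control = (1 - cfg$inpatient_cost_share) *
                         steady$control[["mean"]] / max(lam_o, 1))))
  pre_ids <- ids[prior_ckd]
  prior_claim <- NULL
  if (length(pre_ids)) {
    lead <- days_between(cfg$data_start, cfg$index_period[1])
    prior_claim <- tibble(
      patient_id = pre_ids, setting = "outpatient",
      service_date = cfg$data_start +
        floor(runif(length(pre_ids)) * max(lead, 1)),
      admission_date = as.Date(NA), discharge_date = as.Date(NA),
      cost_total = claim_cost(rep(FALSE, length(pre_ids)),
                              c(hk = 100, control = 100)))
  }

  ## ---- ordinary admissions ----------------------------------------------
  adm_list <- NULL
  if (lam_a > 0) {
    n_adm <- rpois(n, lam_a / DAYS_PER_MONTH * span_days)
    pat <- rep(ids, n_adm)
    day <- rep(enroll_start, n_adm) +
      floor(runif(length(pat)) * rep(span_days, n_adm))
    post <- hk_eff[pat] & !is.na(hk_date[pat]) & day >= hk_date[pat]
    c_adm <- c(hk = cfg$inpatient_cost_share * steady$hk[["mean"]] / lam_a,
               control = cfg$inpatient_cost_share *
                 steady$control[["mean"]] / lam_a)
    los <- pmax(1, round(rlnorm_mean(length(pat),
                                     cfg$admission_los[["mean"]],
                                     cfg$admission_los[["sd"]])))
    discharge <- pmin(day + los - 1, active_end[pat])
    adm_list <- tibble(patient_id = pat, setting = "inpatient",
                       service_date = day, admission_date = day,
                       discharge_date = discharge,
                       cost_total = claim_cost(post, c_adm))
  }

  ## ---- HK index hospitalization (month-1 spike) --------------------------
  hk_ids <- ids[hk_eff]
  idx_claim <- NULL
  if (length(hk_ids)) {
    los <- pmax(1, round(rlnorm_mean(length(hk_ids),
                                     cfg$index_admission_los[["mean"]],
                                     cfg$index_admission_los[["sd"]])))
    day <- hk_date[hk_eff]
    discharge <- pmin(day + los - 1, active_end[hk_eff])
    idx_claim <- tibble(
      patient_id = hk_ids, setting = "inpatient",
      service_date = day, admission_date = day, discharge_date = discharge,
      cost_total = rlnorm_mean(length(hk_ids),
                               cfg$index_month_inpatient_cost[["mean"]],
                               cfg$index_month_inpatient_cost[["sd"]]),
      is_hk_index = TRUE)
  }

  claims <- bind_rows(out_list, dx_claim, prior_claim, adm_list, idx_claim)
  if (!"is_hk_index" %in% names(claims)) claims$is_hk_index <- FALSE
  claims$is_hk_index <- !is.na(claims$is_hk_index) & claims$is_hk_index
  is_dx_claim <- c(rep(FALSE, NROW(out_list)),
                   rep(TRUE, n),
                   rep(FALSE, NROW(prior_claim)),
                   rep(FALSE, NROW(adm_list)),
                   rep(FALSE, NROW(idx_claim)))
  is_prior_claim <- c(rep(FALSE, NROW(out_list)),
                      rep(FALSE, n),
                      rep(TRUE, NROW(prior_claim)),
                      rep(FALSE, NROW(adm_list)),
                      rep(FALSE, NROW(idx_claim)))

  ## ---- diagnosis strings --------------------------------------------------
  pat <- claims$patient_id
  post_dx <- claims$service_date >= ckd_date[pat]
  diagnosis <- ifelse(post_dx & runif(nrow(claims)) < cfg$ckd_code_prob,
                      sim_ckd_code(), "Z00.0")
  diagnosis[is_dx_claim | is_prior_claim] <- sim_ckd_code()
  diagnosis[claims$is_hk_index] <- paste(sim_hk_code(), sim_ckd_code(),
                                         sep = ";")
  codes <- sim_comorbidity_codes()
  for (f in cm_names) {
    if (!f %in% names(codes)) next
    carrier <- Zc[, f][pat]
    if (f == "dialysis") carrier <- carrier & post_dx
    sel <- which(carrier & runif(nrow(claims)) <
                   (if (f == "dialysis") 0.3 else cfg$code_attach_prob))
    if (length(sel)) {
      diagnosis[sel] <- paste(diagnosis[sel], codes[[f]], sep = ";")
    }
  }
  claims$diagnosis <- diagnosis

  ## ---- component split ----------------------------------------------------
  sh <- cfg$cost_component_shares
  claims <- claims %>%
    mutate(cost_medication = .data$cost_total * sh[["medication"]],
           cost_examination = .data$cost_total * sh[["examination"]],
           cost_treatment = .data$cost_total * sh[["treatment"]],
           cost_surgery = .data$cost_total * sh[["surgery"]],
           cost_consumable = .data$cost_total * sh[["consumable"]],
           cost_other = .data$cost_total * sh[["other"]]) %>%
    select(-"cost_total", -"is_hk_index") %>%
    arrange(.data$patient_id, .data$service_date, .data$setting) %>%
    mutate(claim_id = row_number(), .before = 1)

  ## ---- prescriptions -------------------------------------------------------
  drug_classes <- setNames(default_drug_map()$classes, default_drug_map()$flag)
  rx <- NULL
  if (cfg$monthly_prescription_rate > 0) {
    rx_parts <- purrr::map(dr_names, function(f) {
      holders <- ids[Zd[, f]]
      if (!length(holders)) return(NULL)
      n_rx <- rpois(length(holders),
                    cfg$monthly_prescription_rate / DAYS_PER_MONTH *
                      span_days[holders])
      p <- rep(holders, n_rx)
      if (!length(p)) return(NULL)
      tibble(patient_id = p,
             date = rep(enroll_start[holders], n_rx) +
               floor(runif(length(p)) * rep(span_days[holders], n_rx)),
             drug_class = drug_classes[[f]] %||% toupper(f))
    })
    rx <- bind_rows(rx_parts)
  }
  if (is.null(rx) || nrow(rx) == 0) {
    rx <- tibble(patient_id = integer(), date = as.Date(character()),
                 drug_class = character())
  }
  rx <- arrange(rx, .data$patient_id, .data$date)

  patients <- tibble(patient_id = ids,
                     sex = ifelse(female, "F", "M"),
                     birth_date = birth_date,
                     death_date = death_date,
                     enroll_start = enroll_start,
                     enroll_end = enroll_end)

  data <- new_claims_dataset(patients, claims, rx)

  truth <- structure(
    list(true_hr = exp(cfg$hk_log_hazard_ratio),
         true_mean_annual_cost_hk =
           if (any(hk_eff)) truth_mean_annual_cost(cfg, "HK") else NA_real_,
         true_mean_annual_cost_control = truth_mean_annual_cost(cfg, "control"),
         latent = tibble(patient_id = ids, hk = hk_eff,
                         hazard_per_day = h_day,
                         origin_date = origin,
                         death_date_latent = death_latent)),
    class = "ground_truth")

  list(data = data, truth = truth)
}
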