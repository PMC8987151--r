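# Hand-built fixture constructors and independent oracles used across tests.

fx_patient <- function(patient_id, sex = "M", birth = "1950-06-01",
                       death = NA, start = "2011-01-01", end = "2017-12-31") {
  tibble::tibble(patient_id = as.integer(patient_id), sex = sex,
                 birth_date = as.Date(birth),
                 death_date = as.Date(death),
                 enroll_start = as.Date(start), enroll_end = as.Date(end))
}

fx_claim <- function(patient_id, date, diagnosis = "Z00.0",
                     setting = "outpatient", cost = 0,
                     admission = NA, discharge = NA) {
  tibble::tibble(
    patient_id = as.integer(patient_id), setting = setting,
    service_date = as.Date(date),
    admission_date = as.Date(admission), discharge_date = as.Date(discharge),
    diagnosis = diagnosis,
    cost_medication = cost, cost_examination = 0, cost_treatment = 0,
    cost_surgery = 0, cost_consumable = 0, cost_other = 0)
}

fx_dataset <- function(patients, claims = NULL, prescriptions = NULL) {
  if (is.null(claims)) claims <- fx_claim(integer(), as.Date(character()))[0, ]
  claims <- dplyr::mutate(claims, claim_id = dplyr::row_number(), .before = 1)
  if (is.null(prescriptions)) {
    prescriptions <- tibble::tibble(patient_id = integer(),
                                    date = as.Date(character()),
                                    drug_class = character())
  }
  claims_dataset(patients, claims, prescriptions)
}

fx_members <- function(patient_id, cohort, index, death = NA,
                       followup_end = NULL, ckd = NULL) {
  index <- as.Date(index)
  tibble::tibble(
    patient_id = as.integer(patient_id), cohort = cohort,
    ckd_diagnosis_date = as.Date(ckd %||% (index - 100)),
    index_date = index,
    death_date = as.Date(death),
    followup_end = as.Date(followup_end %||%
                             dplyr::coalesce(as.Date(death), index + 720)))
}

fx_pairs <- function(hk_id, control_id) {
  structure(
    tibble::tibble(pair_id = seq_along(hk_id),
                   hk_id = as.integer(hk_id),
                   control_id = as.integer(control_id),
                   ps_hk = 0.5, ps_control = 0.5, logit_diff = 0),
    class = c("matched_pairs", class(tibble::tibble())),
    caliper = Inf, unmatched_hk = integer())
}

# ---------------------------------------------------------------------------
# Independent brute-force transcription of the KMSA estimator definition:
# naive loops over patients, days and intervals; shares no code with the
# implementation.
oracle_kmsa <- function(members, claims, outcome = "cost", K = 12, width = 30) {
  n <- nrow(members)
  death_off <- rep(Inf, n)
  for (i in seq_len(n)) {
    if (!is.na(members$death_date[i])) {
      death_off[i] <- as.numeric(members$death_date[i]) -
        as.numeric(members$index_date[i])
    }
  }
  fe_off <- as.numeric(members$followup_end) - as.numeric(members$index_date)
  horizon <- K * width
  time <- pmax(1, pmin(death_off, pmin(fe_off, horizon)))
  event <- death_off <= pmin(fe_off, horizon) & death_off < horizon

  # product-limit survival, deaths-first at ties
  dtimes <- sort(unique(time[event]))
  S_at <- function(t) {
    s <- 1
    for (d in dtimes[dtimes <= t]) {
      at_risk <- sum(time >= d)
      deaths <- sum(time == d & event)
      s <- s * (1 - deaths / at_risk)
    }
    s
  }

  # per-patient per-interval outcome accrual
  val <- matrix(0, n, K)
  for (j in seq_len(nrow(claims))) {
    i <- match(claims$patient_id[j], members$patient_id)
    if (is.na(i)) next
    d0 <- if (claims$setting[j] == "inpatient") claims$admission_date[j] else
      claims$service_date[j]
    off <- as.numeric(d0) - as.numeric(members$index_date[i])
    if (off < 0 || off >= horizon) next
    if (as.numeric(d0) > as.numeric(members$followup_end[i])) next
    k <- floor(off / width) + 1
    v <- switch(outcome,
                cost = claims$cost_medication[j] + claims$cost_examination[j] +
                  claims$cost_treatment[j] + claims$cost_surgery[j] +
                  claims$cost_consumable[j] + claims$cost_other[j],
                admissions = as.numeric(claims$setting[j] == "inpatient"),
                los = if (claims$setting[j] == "inpatient") {
                  as.numeric(claims$discharge_date[j]) -
                    as.numeric(claims$admission_date[j]) + 1
                } else 0)
    val[i, k] <- val[i, k] + v
  }

  est <- 0
  for (k in seq_len(K)) {
    start <- (k - 1) * width
    at_risk <- death_off > start & fe_off > start
    cbar <- if (any(at_risk)) mean(val[at_risk, k]) else 0
    est <- est + S_at(start) * cbar
  }
  est
}

# Random tiny cohort + claims for oracle-equivalence checks.
random_kmsa_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(2:10, 1)
  index <- as.Date("2014-01-01")
  death_off <- ifelse(runif(n) < 0.4, sample(1:400, n, replace = TRUE), NA)
  fe_off <- ifelse(!is.na(death_off), death_off, 360 + sample(0:200, n, TRUE))
  members <- fx_members(seq_len(n), cohort = "HK", index = index,
                        death = index + death_off,
                        followup_end = index + fe_off)
  n_claims <- sample(5:25, 1)
  pid <- sample(seq_len(n), n_claims, replace = TRUE)
  off <- sample(-30:420, n_claims, replace = TRUE)
  max_off <- ifelse(is.na(death_off[pid]), fe_off[pid], death_off[pid])
  off <- pmin(off, max_off)
  ip <- runif(n_claims) < 0.3
  claims <- fx_claim(pid, index + off,
                     setting = ifelse(ip, "inpatient", "outpatient"),
                     cost = round(runif(n_claims, 10, 2000), 2),
                     admission = dplyr::if_else(ip, index + off, as.Date(NA)),
                     discharge = dplyr::if_else(ip, index + off +
                                                  sample(0:20, n_claims, TRUE),
                                                as.Date(NA)))
  patients <- fx_patient(seq_len(n), death = index + death_off,
                         start = "2012-01-01", end = "2017-12-31")
  list(members = members,
       data = fx_dataset(patients, claims))
}

small_sim <- function(n = 800, seed = 1, ...) {
  simulate_population(sim_config(n_patients = n, rng_seed = seed, ...))
}
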