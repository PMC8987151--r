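test_that("claims land in the interval containing their (admission) date", {
  index <- as.Date("2014-01-01")
  members <- fx_members(1:3, "HK", index)
  claims <- dplyr::bind_rows(
    fx_claim(1, index, cost = 10),                              # day 0 -> k1
    fx_claim(1, index + 29, cost = 20),                         # day 29 -> k1
    fx_claim(1, index + 30, cost = 40),                         # day 30 -> k2
    # admission day 29, discharge day 45: all cost and LOS in interval 1
    fx_claim(2, index + 29, setting = "inpatient", cost = 1000,
             admission = index + 29, discharge = index + 45),
    fx_claim(2, index + 360, cost = 99),                        # beyond year
    fx_claim(3, index - 5, cost = 77))                          # pre-index
  patients <- fx_patient(1:3)
  out <- accrue_intervals(members, fx_dataset(patients, claims))
  g <- function(id, k, col) out[[col]][out$patient_id == id & out$interval == k]
  expect_equal(g(1, 1, "cost_total"), 30)
  expect_equal(g(1, 2, "cost_total"), 40)
  expect_equal(g(2, 1, "cost_total"), 1000)
  expect_equal(g(2, 1, "los_days"), 17)
  expect_equal(g(2, 1, "n_admissions"), 1)
  expect_equal(sum(out$cost_total[out$patient_id == 2]), 1000)
  expect_equal(sum(out$cost_total[out$patient_id == 3]), 0)
  expect_equal(g(1, 1, "n_outpatient"), 2)
})

test_that("with no deaths the KMSA estimate is the plain mean (1200)", {
  index <- as.Date("2014-01-01")
  members <- fx_members(1:4, "HK", index)
  claims <- dplyr::bind_rows(lapply(1:4, function(i) {
    dplyr::bind_rows(lapply(0:11, function(k) {
      fx_claim(i, index + k * 30 + 5, cost = 100)
    }))
  }))
  out <- accrue_intervals(members, fx_dataset(fx_patient(1:4), claims))
  est <- kmsa_point_estimate(out)
  expect_equal(est$estimate[est$outcome == "cost_total"], 1200)
  d <- attr(est, "detail")
  expect_equal(d$S, rep(1, 12))
})

test_that("the two-patient worked example gives 85", {
  index <- as.Date("2014-01-01")
  members <- fx_members(1:2, "HK", index,
                        death = c(NA, as.character(index + 15)))
  claims <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(0:11, function(k)
      fx_claim(1, index + k * 30 + 2, cost = 10))),
    fx_claim(2, index + 3, cost = 50))
  patients <- dplyr::bind_rows(fx_patient(1),
                               fx_patient(2, death = index + 15))
  out <- accrue_intervals(members, fx_dataset(patients, claims))
  est <- kmsa_point_estimate(out)
  d <- attr(est, "detail")
  expect_equal(d$S, c(1, rep(0.5, 11)))
  expect_equal(est$estimate[est$outcome == "cost_total"],
               1 * 30 + sum(rep(0.5 * 10, 11)))  # = 85
})

test_that("KMSA equals the brute-force oracle on random small fixtures", {
  for (seed in 1:12) {
    fx <- random_kmsa_fixture(seed)
    out <- accrue_intervals(fx$members, fx$data)
    est <- kmsa_point_estimate(out)
    expect_equal(est$estimate[est$outcome == "cost_total"],
                 oracle_kmsa(fx$members, fx$data$claims, "cost"),
                 tolerance = 1e-10)
    expect_equal(est$estimate[est$outcome == "n_admissions"],
                 oracle_kmsa(fx$members, fx$data$claims, "admissions"),
                 tolerance = 1e-10)
    expect_equal(est$estimate[est$outcome == "los_days"],
                 oracle_kmsa(fx$members, fx$data$claims, "los"),
                 tolerance = 1e-10)
  }
})

test_that("component estimates decompose exactly into setting totals", {
  s <- small_sim(n = 700, seed = 23, hk_fraction = 0.3)
  lat <- s$truth$latent
  members <- fx_members(
    lat$patient_id, ifelse(lat$hk, "HK", "non-HK"),
    index = lat$origin_date,
    death = dplyr::if_else(lat$death_date_latent <= as.Date("2017-12-31"),
                           lat$death_date_latent, as.Date(NA)),
    followup_end = pmin(lat$death_date_latent, as.Date("2017-12-31")))
  out <- accrue_intervals(members, s$data)
  for (lab in c("HK", "non-HK")) {
    est <- kmsa_point_estimate(out, cohort_label = lab)
    v <- setNames(est$estimate, est$outcome)
    comps <- c("medication", "examination", "treatment", "surgery",
               "consumable", "other")
    expect_equal(sum(v[paste0("cost_total_", comps)]), v[["cost_total"]],
                 tolerance = 1e-6)
    expect_equal(sum(v[paste0("cost_inpatient_", comps)]),
                 v[["cost_inpatient"]], tolerance = 1e-6)
    expect_equal(v[["cost_inpatient"]] + v[["cost_outpatient"]],
                 v[["cost_total"]], tolerance = 1e-6)
  }
})

test_that("heavier mortality never increases the estimate (fixed outcomes)", {
  fx <- random_kmsa_fixture(101)
  out <- accrue_intervals(fx$members, fx$data)
  mk_km <- function(surv) {
    structure(tibble::tibble(time = seq(30, 360, 30), n_risk = 10,
                             n_event = 1, n_censor = 0, survival = surv),
              class = c("km_curve", "tbl_df", "tbl", "data.frame"))
  }
  light <- mk_km(seq(0.98, 0.76, length.out = 12))
  heavy <- mk_km(seq(0.90, 0.30, length.out = 12))
  e_light <- kmsa_point_estimate(out, km = light)
  e_heavy <- kmsa_point_estimate(out, km = heavy)
  expect_true(all(e_heavy$estimate <= e_light$estimate + 1e-12))
})

test_that("paired bootstrap is deterministic and degenerates to zero width", {
  index <- as.Date("2014-01-01")
  members <- fx_members(1:8, rep(c("HK", "non-HK"), each = 4), index)
  claims <- dplyr::bind_rows(lapply(1:8, function(i)
    fx_claim(i, index + 10, cost = ifelse(i <= 4, 200, 100))))
  out <- accrue_intervals(members, fx_dataset(fx_patient(1:8), claims))
  pairs <- fx_pairs(1:4, 5:8)
  cfg <- bootstrap_config(n_iterations = 150, seed = 7)
  b1 <- paired_bootstrap(pairs, out, cfg, outcome_cols = "cost_total")
  b2 <- paired_bootstrap(pairs, out, cfg, outcome_cols = "cost_total")
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  # all patients identical within cohort, no deaths -> zero-width CI
  expect_equal(b1$lo_hk, b1$hi_hk)
  expect_equal(b1$est_hk, 200)
  expect_equal(b1$est_control, 100)
  expect_equal(b1$lo_diff, b1$hi_diff)
})

test_that("bootstrap point estimates agree with kmsa_point_estimate", {
  s <- small_sim(n = 900, seed = 31, hk_fraction = 0.3)
  lat <- s$truth$latent
  members <- fx_members(
    lat$patient_id, ifelse(lat$hk, "HK", "non-HK"),
    index = lat$origin_date,
    death = dplyr::if_else(lat$death_date_latent <= as.Date("2017-12-31"),
                           lat$death_date_latent, as.Date(NA)),
    followup_end = pmin(lat$death_date_latent, as.Date("2017-12-31")))
  out <- accrue_intervals(members, s$data)
  hk_ids <- members$patient_id[members$cohort == "HK"]
  ct_ids <- members$patient_id[members$cohort != "HK"]
  k <- min(length(hk_ids), length(ct_ids))
  pairs <- fx_pairs(hk_ids[seq_len(k)], ct_ids[seq_len(k)])
  b <- paired_bootstrap(pairs, out, bootstrap_config(n_iterations = 100,
                                                     seed = 3),
                        outcome_cols = c("cost_total", "n_admissions"))
  sub_out_hk <- accrue_intervals(
    members[members$patient_id %in% pairs$hk_id, ], s$data)
  est_hk <- kmsa_point_estimate(sub_out_hk,
                                outcome_cols = c("cost_total", "n_admissions"))
  expect_equal(b$est_hk, est_hk$estimate, tolerance = 1e-12)
})

test_that("pairs_per_iteration above the pair count is rejected", {
  index <- as.Date("2014-01-01")
  members <- fx_members(1:4, rep(c("HK", "non-HK"), each = 2), index)
  out <- accrue_intervals(members, fx_dataset(fx_patient(1:4)))
  pairs <- fx_pairs(1:2, 3:4)
  expect_error(
    paired_bootstrap(pairs, out,
                     bootstrap_config(n_iterations = 100,
                                      pairs_per_iteration = 10)),
    "exceeds")
})

test_that("subgroup summaries apply the both-members rule", {
  index <- as.Date("2014-01-01")
  members <- fx_members(1:6, rep(c("HK", "non-HK"), 3), index)
  claims <- dplyr::bind_rows(
    # pair (1,2): both admitted; HK has stays of 10 and 20 days
    fx_claim(1, index + 5, setting = "inpatient", cost = 300,
             admission = index + 5, discharge = index + 14),
    fx_claim(1, index + 60, setting = "inpatient", cost = 500,
             admission = index + 60, discharge = index + 79),
    fx_claim(2, index + 9, setting = "inpatient", cost = 400,
             admission = index + 9, discharge = index + 12),
    # pair (3,4): only the HK member admitted -> excluded
    fx_claim(3, index + 5, setting = "inpatient", cost = 100,
             admission = index + 5, discharge = index + 6),
    fx_claim(4, index + 5, cost = 50),
    # pair (5,6): no admissions
    fx_claim(5, index + 5, cost = 10), fx_claim(6, index + 6, cost = 10))
  out <- accrue_intervals(members, fx_dataset(fx_patient(1:6), claims))
  pairs <- fx_pairs(c(1, 3, 5), c(2, 4, 6))
  got <- summarize_subgroup(pairs, out, "hospitalized")
  expect_equal(attr(got, "n_pairs"), 1L)
  expect_equal(got$mean_hk[got$metric == "los_per_admission"], 15)
  expect_equal(got$mean_hk[got$metric == "n_admissions"], 2)
  expect_equal(got$mean_control[got$metric == "cost_per_admission"], 400)

  # outpatient rule: pairs (3,4) fails (HK member has no visit), (5,6) holds
  got_op <- summarize_subgroup(pairs, out, "outpatient")
  expect_equal(attr(got_op, "n_pairs"), 1L)
  expect_equal(got_op$mean_hk[got_op$metric == "cost_per_visit"], 10)

  empty <- summarize_subgroup(fx_pairs(3, 4), out, "hospitalized")
  expect_equal(nrow(empty), 0)
})

test_that("three qualifying pairs reproduce hand-computed subgroup stats", {
  index <- as.Date("2014-01-01")
  members <- fx_members(1:6, rep(c("HK", "non-HK"), 3), index)
  adm <- function(id, day, cost, los) {
    fx_claim(id, index + day, setting = "inpatient", cost = cost,
             admission = index + day, discharge = index + day + los - 1)
  }
  claims <- dplyr::bind_rows(
    adm(1, 5, 100, 5), adm(2, 5, 200, 4),
    adm(3, 5, 300, 10), adm(3, 50, 500, 6), adm(4, 5, 150, 8),
    adm(5, 5, 250, 12), adm(6, 5, 600, 2))
  out <- accrue_intervals(members, fx_dataset(fx_patient(1:6), claims))
  got <- summarize_subgroup(fx_pairs(c(1, 3, 5), c(2, 4, 6)), out,
                            "hospitalized")
  # HK per-patient admissions: 1, 2, 1; LOS/adm: 5, 8, 12; cost/adm: 100, 400, 250
  r <- function(m, col) got[[col]][got$metric == m]
  expect_equal(r("n_admissions", "mean_hk"), mean(c(1, 2, 1)))
  expect_equal(r("n_admissions", "median_hk"), 1)
  expect_equal(r("los_per_admission", "mean_hk"), mean(c(5, 8, 12)))
  expect_equal(r("cost_per_admission", "mean_hk"), mean(c(100, 400, 250)))
  expect_equal(r("cost_per_admission", "mean_control"), mean(c(200, 150, 600)))
  expect_equal(r("los_per_admission", "median_control"), 4)
})
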