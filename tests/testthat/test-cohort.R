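codes <- default_code_set()
period <- as.Date(c("2012-01-01", "2016-12-31"))

test_that("new-onset identification applies washout, age and lookback rules", {
  patients <- dplyr::bind_rows(
    fx_patient(1),                              # prior CKD claim in 2011
    fx_patient(2),                              # CKD only before period
    fx_patient(3, birth = "1997-06-01"),        # 16 years old at diagnosis
    fx_patient(4),                              # qualifies
    fx_patient(5),                              # qualifies (different code)
    fx_patient(6),                              # qualifies late in period
    fx_patient(7, start = "2013-06-01"))        # < 360 d lookback coverage
  claims <- dplyr::bind_rows(
    fx_claim(1, "2011-05-01", "N18.5"), fx_claim(1, "2013-02-01", "N18.5"),
    fx_claim(2, "2011-08-01", "I12"),
    fx_claim(3, "2014-01-10", "N03.1"),
    fx_claim(4, "2013-03-15", "N18.9"),
    fx_claim(5, "2014-07-01", "Z99.2"),
    fx_claim(6, "2016-11-30", "E11.2"),
    fx_claim(7, "2013-09-01", "N18.9"))
  got <- find_new_onset_ckd(fx_dataset(patients, claims), codes, period)
  expect_equal(got$patient_id, c(4L, 5L, 6L))
  expect_equal(got$ckd_diagnosis_date,
               as.Date(c("2013-03-15", "2014-07-01", "2016-11-30")))
  excl <- attr(got, "exclusions")
  expect_equal(unname(excl["ckd_before_index_period"]), 2)
  expect_equal(unname(excl["under_min_age"]), 1)
  expect_equal(unname(excl["insufficient_lookback"]), 1)
})

test_that("code sets reject empty or malformed prefixes", {
  expect_error(code_set(character(), "E87.5"), "ckd_codes")
  expect_error(code_set("N18", "e87.5"), "uppercase")
})

test_that("cohort assignment partitions patients as expected", {
  patients <- dplyr::bind_rows(lapply(1:5, fx_patient))
  claims <- dplyr::bind_rows(
    # A: CKD then HK -> HK member with index at first HK claim
    fx_claim(1, "2013-01-01", "N18.9"), fx_claim(1, "2013-05-01", "E87.5"),
    # B: two HK claims -> index at the earlier
    fx_claim(2, "2013-02-01", "N18.9"), fx_claim(2, "2014-01-01", "E87.5"),
    fx_claim(2, "2013-08-01", "E87.5"),
    # C: HK before CKD only -> excluded from both cohorts
    fx_claim(3, "2013-01-01", "E87.5"), fx_claim(3, "2013-06-01", "N18.9"),
    # D, E: CKD only -> non-HK candidates
    fx_claim(4, "2014-01-01", "N18.9"),
    fx_claim(5, "2015-01-01", "I13"))
  data <- fx_dataset(patients, claims)
  ckd <- find_new_onset_ckd(data, codes, period)
  got <- assign_cohorts(ckd, data, codes)
  expect_equal(got$hk_members$patient_id, c(1L, 2L))
  expect_equal(got$hk_members$index_date,
               as.Date(c("2013-05-01", "2013-08-01")))
  expect_equal(got$non_hk_candidates$patient_id, c(4L, 5L))
  expect_length(intersect(got$hk_members$patient_id,
                          got$non_hk_candidates$patient_id), 0)
})

test_that("enrollment filter keeps death-truncated follow-up but not gaps", {
  index <- as.Date("2014-06-01")
  members <- tibble::tibble(
    patient_id = 1:4, ckd_diagnosis_date = index - 200, index_date = index)
  patients <- dplyr::bind_rows(
    fx_patient(1, start = "2014-01-01"),             # baseline gap
    fx_patient(2, end = "2014-09-01"),               # alive, ends 3m post
    fx_patient(3, death = "2014-09-01"),             # dies 3m post, enrolled
    fx_patient(4))                                   # full coverage
  got <- apply_enrollment_filter(members, fx_dataset(patients),
                                 study_end = as.Date("2017-12-31"))
  expect_equal(got$patient_id, c(3L, 4L))
  expect_equal(got$died_within_12m, c(TRUE, FALSE))
  expect_equal(got$followup_end[1], as.Date("2014-09-01"))
  expect_equal(got$ckd_duration_months, c(6, 6))
  excl <- attr(got, "exclusions")
  expect_equal(unname(excl["baseline_gap"]), 1)
  expect_equal(unname(excl["followup_gap"]), 1)
})

test_that("every HK index date carries an HK claim; cohorts stay disjoint", {
  s <- small_sim(n = 1200, seed = 14, hk_fraction = 0.2)
  ckd <- find_new_onset_ckd(s$data, codes, period)
  got <- assign_cohorts(ckd, s$data, codes)
  expect_gt(nrow(got$hk_members), 10)
  hk_claims <- s$data$claims[grepl("E87.5", s$data$claims$diagnosis,
                                   fixed = TRUE), ]
  has_claim <- mapply(function(id, idx) {
    any(hk_claims$patient_id == id & hk_claims$service_date == idx)
  }, got$hk_members$patient_id, got$hk_members$index_date)
  expect_true(all(has_claim))
  expect_length(intersect(got$hk_members$patient_id,
                          got$non_hk_candidates$patient_id), 0)
  filtered <- apply_enrollment_filter(got$hk_members, s$data)
  expect_true(all(filtered$ckd_duration_months >= 0))
})

test_that("covariates come strictly from the 360-day pre-index window", {
  index <- as.Date("2015-01-01")
  members <- tibble::tibble(patient_id = 1:3, index_date = index,
                            ckd_duration_months = c(3, 3, 3))
  patients <- dplyr::bind_rows(
    fx_patient(1, sex = "F", birth = "1955-01-01"),
    fx_patient(2), fx_patient(3))
  claims <- dplyr::bind_rows(
    # patient 2: one 10-day admission plus an out-of-window claim
    fx_claim(2, "2014-06-01", "N18.9", setting = "inpatient", cost = 500,
             admission = "2014-06-01", discharge = "2014-06-10"),
    fx_claim(2, "2013-01-01", "I10", cost = 999),    # before the window
    fx_claim(2, index, "I10", cost = 999),           # on index: excluded
    # patient 3: diabetes with complication + mild liver disease
    fx_claim(3, "2014-08-01", "E11.2;K70.3", cost = 40))
  rx <- tibble::tibble(patient_id = c(2L, 2L),
                       date = as.Date(c("2014-05-01", "2012-01-01")),
                       drug_class = c("ARB", "MRA"))
  cov <- build_covariates(members, fx_dataset(patients, claims, rx))
  cov1 <- cov[cov$patient_id == 1, ]
  expect_true(cov1$female)
  expect_equal(cov1$cci, 0L)
  expect_equal(cov1$baseline_total_cost, 0)
  expect_equal(cov1$baseline_n_outpatient, 0)
  cov2 <- cov[cov$patient_id == 2, ]
  expect_equal(cov2$baseline_n_hospitalizations, 1)
  expect_equal(cov2$baseline_los, 10)
  expect_equal(cov2$baseline_total_cost, 500)
  expect_false(cov2$hypertension)   # both I10 claims fall outside the window
  expect_true(cov2$arb)
  expect_false(cov2$mra)            # prescription outside the window
  expect_equal(cov2$cci, 2L)        # N18.9 -> renal disease
  # Charlson: diabetes w/ complication (2) + mild liver (1)
  expect_equal(cov[cov$patient_id == 3, ]$cci, 3L)
  expect_equal(cov[cov$patient_id == 3, ]$age_at_index,
               floor(as.numeric(index - as.Date("1950-06-01")) / 365.25))
})

test_that("Charlson scoring applies weights and severity hierarchies", {
  expect_equal(charlson_index(character()), 0L)
  expect_equal(charlson_index("N18.9"), 2L)
  expect_equal(charlson_index(c("E11.2", "K70.3")), 3L)
  # metastatic disease supersedes the primary malignancy weight
  expect_equal(charlson_index(c("C34.9", "C78.0")), 6L)
  expect_equal(charlson_index(c("I21.0", "I50.9", "J44.9")), 3L)
})
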