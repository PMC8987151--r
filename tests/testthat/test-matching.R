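fake_model <- function(ids_hk, ps_hk, ids_ct, ps_ct) {
  ps <- c(ps_hk, ps_ct)
  structure(
    list(scores = tibble::tibble(
      patient_id = as.integer(c(ids_hk, ids_ct)),
      hk = rep(c(TRUE, FALSE), c(length(ids_hk), length(ids_ct))),
      ps = ps, logit_ps = qlogis(ps))),
    class = "propensity_model")
}

test_that("coarse match selects same-sex same-year age-nearest candidates", {
  # HK member 1 (M, 2013, age ~60); 40 male 2013 candidates ages 30..69
  hk <- fx_members(1, "HK", "2013-09-01", ckd = "2013-06-01")
  patients <- dplyr::bind_rows(
    fx_patient(1, birth = "1953-06-01"),
    dplyr::bind_rows(lapply(2:41, function(i)
      fx_patient(i, birth = sprintf("%d-06-01", 2013 - (28 + i))))),
    fx_patient(42, sex = "F", birth = "1953-06-01"))   # opposite sex
  cand <- tibble::tibble(patient_id = 2:42,
                         ckd_diagnosis_date = as.Date("2013-06-01"))
  got <- coarse_match(hk, cand, fx_dataset(patients), ratio = 30)
  expect_equal(nrow(got$pool_map), 30)
  expect_false(42 %in% got$pool_map$control_id)
  # candidate i (2..41) is aged 28+i at diagnosis; target age 60 -> the 30
  # age-nearest are those aged 40..69, i.e. ids 12..41
  expect_equal(sort(got$pool_map$control_id), 12:41)
  # controls inherit the HK index date
  expect_true(all(got$controls$index_date == as.Date("2013-09-01")))
})

test_that("coarse match pools rank hand-computed age gaps", {
  hk <- fx_members(c(1, 2, 3), "HK", "2014-06-01", ckd = "2014-01-01")
  # HK ages at dx: 70, 50, 30
  patients <- dplyr::bind_rows(
    fx_patient(1, birth = "1944-01-01"), fx_patient(2, birth = "1964-01-01"),
    fx_patient(3, birth = "1984-01-01"),
    # candidates aged 72, 69, 52, 49, 31, 28, plus one from another year
    fx_patient(11, birth = "1942-01-01"), fx_patient(12, birth = "1945-01-01"),
    fx_patient(13, birth = "1962-01-01"), fx_patient(14, birth = "1965-01-01"),
    fx_patient(15, birth = "1983-01-01"), fx_patient(16, birth = "1986-01-01"),
    fx_patient(17, birth = "1944-01-01"))
  cand <- tibble::tibble(
    patient_id = c(11:16, 17L),
    ckd_diagnosis_date = as.Date(c(rep("2014-01-01", 6), "2013-06-01")))
  got <- coarse_match(hk, cand, fx_dataset(patients), ratio = 2)
  pools <- split(got$pool_map$control_id, got$pool_map$hk_id)
  expect_equal(sort(pools[["1"]]), c(11L, 12L))
  expect_equal(sort(pools[["2"]]), c(13L, 14L))
  expect_equal(sort(pools[["3"]]), c(15L, 16L))
  expect_false(17 %in% got$pool_map$control_id)  # different diagnosis year
})

test_that("logistic propensity recovers the 2x2 closed-form log odds ratio", {
  x <- rep(c(1, 0, 1, 0), c(30, 70, 20, 80))
  hk <- rep(c(TRUE, FALSE), c(100, 100))
  cov <- tibble::tibble(patient_id = 1:200, exposure = x, hk = hk)
  fit <- fit_propensity(cov)
  log_or <- log((30 / 70) / (20 / 80))
  expect_equal(unname(fit$coefficients["exposure"]), log_or,
               tolerance = 1e-6)
})

test_that("null covariates give near-zero slopes; confounding gives AUC > 0.5", {
  set.seed(5)
  n <- 3000
  cov <- tibble::tibble(patient_id = seq_len(n), x1 = rnorm(n),
                        x2 = runif(n) < 0.5, hk = runif(n) < 0.3)
  fit <- fit_propensity(cov)
  se <- sqrt(diag(vcov(fit$fit)))[-1]
  expect_true(all(abs(fit$coefficients) / se < 4))

  s <- small_sim(n = 2000, seed = 8, hk_fraction = 0.25)
  ckd <- find_new_onset_ckd(s$data, default_code_set(),
                            as.Date(c("2012-01-01", "2016-12-31")))
  coh <- assign_cohorts(ckd, s$data, default_code_set())
  hk <- apply_enrollment_filter(coh$hk_members, s$data)
  cm <- coarse_match(hk, coh$non_hk_candidates, s$data)
  members <- dplyr::bind_rows(
    dplyr::mutate(hk, cohort = "HK"),
    dplyr::mutate(dplyr::select(cm$controls, -hk_partner), cohort = "non-HK"))
  cov2 <- build_covariates(members, s$data) |>
    dplyr::left_join(
      dplyr::transmute(members, patient_id, hk = cohort == "HK"),
      by = "patient_id")
  fit2 <- fit_propensity(cov2)
  expect_gt(glance(fit2)$auc, 0.55)
})

test_that("greedy 1:1 matching follows the hand-run algorithm", {
  # 2 HK + 1 control: one pair, one unmatched
  m <- fake_model(c(1, 2), c(0.8, 0.6), 11, 0.61)
  pairs <- match_1to1(m, caliper_sd = NULL)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$hk_id, 1L)       # processed first (higher PS)
  expect_equal(attr(pairs, "unmatched_hk"), 2L)

  # identical scores match at distance zero
  m0 <- fake_model(1, 0.5, 11, 0.5)
  p0 <- match_1to1(m0)
  expect_equal(p0$logit_diff, 0)

  # 5x5 with hand-assigned scores, no caliper: descending-PS greedy
  m5 <- fake_model(1:5, c(0.90, 0.70, 0.50, 0.30, 0.10),
                   11:15, c(0.88, 0.72, 0.49, 0.29, 0.52))
  p5 <- match_1to1(m5, caliper_sd = NULL)
  # hand-run: hk1->11 (.88), hk2->12 (.72), hk3->13 (.49), hk4->14 (.29),
  # hk5 takes the leftover 15 (.52)
  expect_equal(p5$control_id[match(1:5, p5$hk_id)],
               c(11L, 12L, 13L, 14L, 15L))
  expect_false(any(duplicated(p5$control_id)))

  # caliper excludes distant leftovers
  pc <- match_1to1(m5, caliper_sd = 0.2)
  expect_false(5 %in% pc$hk_id)
})

test_that("matching is deterministic and without replacement on generator data", {
  set.seed(2)
  n <- 400
  cov <- tibble::tibble(patient_id = seq_len(n), x = rnorm(n))
  cov$hk <- runif(n) < plogis(-1 + 0.8 * cov$x)
  fit <- fit_propensity(cov)
  p1 <- match_1to1(fit)
  p2 <- match_1to1(fit)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_false(any(duplicated(p1$control_id)))
  expect_true(all(abs(p1$logit_diff) <= attr(p1, "caliper")))
})

test_that("standardized differences reproduce printed balance-table values", {
  bin <- function(k, n) rep(c(1, 0), c(k, n - k))
  # Female 407 vs 404 of 1003 -> 0.01; Hypertension 796 vs 821 -> -0.06;
  # T2DM 440 vs 428 -> 0.02; Dialysis 21 vs 13 -> 0.06
  expect_equal(round(standardized_difference(bin(407, 1003), bin(404, 1003)), 2), 0.01)
  expect_equal(round(standardized_difference(bin(796, 1003), bin(821, 1003)), 2), -0.06)
  expect_equal(round(standardized_difference(bin(440, 1003), bin(428, 1003)), 2), 0.02)
  expect_equal(round(standardized_difference(bin(21, 1003), bin(13, 1003)), 2), 0.06)
})

test_that("standardized difference handles degenerate inputs", {
  x <- c(1, 2, 3, 4)
  expect_equal(standardized_difference(x, x), 0)
  expect_equal(standardized_difference(rep(0, 5), rep(0, 5), "binary"), 0)
  # means 1 and 0, both sample SDs exactly 1
  expect_equal(standardized_difference(c(0, 1, 2), c(-1, 0, 1)), 1.0)
  expect_error(standardized_difference(rep(1, 3), rep(2, 3)),
               "zero pooled variance")
})

test_that("balance report flags imbalance and improves after matching", {
  grp <- rep(c(TRUE, FALSE), each = 50)
  cov_same <- tibble::tibble(patient_id = 1:100, hk = grp,
                             a = rep(c(1, 0), 50), b = rep(2.5, 100))
  rep_same <- balance_report(cov_same)
  expect_true(all(rep_same$std_diff == 0))
  expect_true(all(rep_same$p_value == 1))

  s <- small_sim(n = 2500, seed = 13, hk_fraction = 0.25)
  ckd <- find_new_onset_ckd(s$data, default_code_set(),
                            as.Date(c("2012-01-01", "2016-12-31")))
  coh <- assign_cohorts(ckd, s$data, default_code_set())
  hk <- apply_enrollment_filter(coh$hk_members, s$data)
  cm <- coarse_match(hk, coh$non_hk_candidates, s$data)
  members <- dplyr::bind_rows(
    dplyr::mutate(hk, cohort = "HK"),
    dplyr::mutate(dplyr::select(cm$controls, -hk_partner), cohort = "non-HK"))
  cov <- build_covariates(members, s$data) |>
    dplyr::left_join(
      dplyr::transmute(members, patient_id, hk = cohort == "HK"),
      by = "patient_id")
  fit <- fit_propensity(cov)
  pairs <- match_1to1(fit)
  pre <- balance_report(cov)
  post <- balance_report(
    dplyr::filter(cov, patient_id %in% c(pairs$hk_id, pairs$control_id)))
  expect_lt(mean(abs(post$std_diff_raw)), mean(abs(pre$std_diff_raw)))
  expect_gte(mean(post$balanced), mean(pre$balanced))
})
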