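#' Coarse 1:30 matching on sex, diagnosis year, and age
#'
#' First-stage candidate selection: each HK member is matched to its up-to-
#' `ratio` nearest non-HK candidates by age at diagnosis among those of the
#' same sex and CKD-diagnosis calendar year (ties broken by smaller candidate
#' `patient_id`). Candidate pools may overlap; a control selected by several
#' HK members inherits the index date of its nearest selector (ties by
#' smaller HK `patient_id`), and uniqueness is enforced later by the 1:1
#' stage. After index-date inheritance the enrollment filter is re-applied to
#' the controls; controls that fail it are dropped without backfilling.
#'
#' @param hk_members Filtered HK members (from [apply_enrollment_filter()]).
#' @param non_hk_candidates Tibble `(patient_id, ckd_diagnosis_date)`.
#' @param data A [claims_dataset()].
#' @param ratio Maximum controls per HK member (default 30).
#' @inheritParams apply_enrollment_filter
#' @return A list: `controls` (filtered control members with inherited
#'   `index_date` and `hk_partner`), `pool_map` (tibble `hk_id`,
#'   `control_id`, `age_diff`), `unmatched_hk` (HK ids with zero eligible
#'   controls after the filter).
#' @export
coarse_match <- function(hk_members, non_hk_candidates, data, ratio = 30,
                         baseline_days = 360, followup_days = 360,
                         study_end = NULL) {
  stopifnot(inherits(data, "claims_dataset"))
  pat <- data$patients %>% select("patient_id", "sex", "birth_date")
  hk <- hk_members %>%
    left_join(pat, by = "patient_id") %>%
    mutate(dx_year = as.integer(format(.data$ckd_diagnosis_date, "%Y")),
           age_dx = days_between(.data$birth_date,
                                 .data$ckd_diagnosis_date) / 365.25) %>%
    arrange(.data$patient_id)
  cand <- non_hk_candidates %>%
    left_join(pat, by = "patient_id") %>%
    mutate(dx_year = as.integer(format(.data$ckd_diagnosis_date, "%Y")),
           age_dx = days_between(.data$birth_date,
                                 .data$ckd_diagnosis_date) / 365.25)

  cells <- split(cand, paste(cand$sex, cand$dx_year))
  picks <- vector("list", nrow(hk))
  for (i in seq_len(nrow(hk))) {
    key <- paste(hk$sex[i], hk$dx_year[i])
    d <- cells[[key]]
    if (is.null(d) || nrow(d) == 0) next
    gap <- abs(d$age_dx - hk$age_dx[i])
    take <- order(gap, d$patient_id)[seq_len(min(ratio, nrow(d)))]
    picks[[i]] <- tibble(hk_id = hk$patient_id[i],
                         control_id = d$patient_id[take],
                         age_diff = gap[take])
  }
  pool_map <- bind_rows(picks)
  if (nrow(pool_map) == 0) {
    abort("coarse matching produced an empty candidate pool")
  }

  # a control in several pools inherits the index date of its nearest selector
  assignment <- pool_map %>%
    arrange(.data$control_id, .data$age_diff, .data$hk_id) %>%
    distinct(.data$control_id, .keep_all = TRUE)

  controls <- assignment %>%
    select(hk_partner = "hk_id", patient_id = "control_id") %>%
    left_join(hk_members %>% select(hk_partner = "patient_id", "index_date"),
              by = "hk_partner") %>%
    left_join(non_hk_candidates, by = "patient_id") %>%
    apply_enrollment_filter(data, baseline_days = baseline_days,
                            followup_days = followup_days,
                            study_end = study_end)
  pool_map <- pool_map %>%
    semi_join(controls, by = c(control_id = "patient_id"))
  matched_hk <- unique(pool_map$hk_id)
  unmatched <- setdiff(hk_members$patient_id, matched_hk)
  list(controls = controls, pool_map = pool_map, unmatched_hk = unmatched)
}

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of HK-cohort membership on the
#' baseline covariates (age, sex, CKD duration, CCI, comorbidity flags,
#' medication flags, baseline HRU and cost). Covariates constant across the
#' pool are dropped with a message. If the fit separates (fitted
#' probabilities numerically 0/1 or non-convergence), a small ridge penalty
#' (1e-6) is applied and a warning raised.
#'
#' @param covariates Covariate tibble from [build_covariates()] with an added
#'   logical column `hk` labelling HK membership.
#' @return A `propensity_model`: list with `coefficients`, `intercept`,
#'   `scores` (tibble `patient_id`, `hk`, `ps`, `logit_ps`), `separation`
#'   flag, and `dropped` covariates. Has [tidy()] and [glance()] methods.
#' @export
fit_propensity <- function(covariates) {
  if (!"hk" %in% names(covariates)) {
    abort("`covariates` must carry a logical `hk` column")
  }
  if (nrow(covariates) == 0) abort("empty covariate pool")
  vars <- covariate_columns(covariates)
  const <- vars[vapply(covariates[vars],
                       function(x) length(unique(x)) < 2, logical(1))]
  if (length(const)) {
    inform(paste("dropping constant covariates:",
                 paste(const, collapse = ", ")))
    vars <- setdiff(vars, const)
  }
  if (!length(vars)) abort("no non-constant covariates to fit")

  df <- covariates
  df[] <- lapply(df, function(col) if (is.logical(col)) as.numeric(col) else col)
  form <- as.formula(paste("hk ~", paste(vars, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = df,
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  eps <- 1e-10
  if (separation || any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)) {
    separation <- TRUE
    warn("possible separation in the propensity model; refitting with a small ridge penalty")
    x <- as.matrix(df[vars])
    rf <- glmnet::glmnet(x, df$hk, family = "binomial", alpha = 0,
                         lambda = 1e-6, standardize = FALSE, thresh = 1e-12)
    beta <- as.numeric(coef(rf))
    names(beta) <- rownames(coef(rf))
    ps <- drop(plogis(beta[1] + x %*% beta[-1]))
    coefs <- beta[-1]; intercept <- beta[1]
  } else {
    coefs <- coef(fit)[-1]
    intercept <- coef(fit)[1]
    ps <- fit$fitted.values
  }
  ps <- pmin(pmax(ps, 1e-12), 1 - 1e-12)
  structure(
    list(coefficients = coefs, intercept = unname(intercept),
         covariates = vars, dropped = const, separation = separation,
         fit = if (!separation) fit else NULL,
         scores = tibble(patient_id = covariates$patient_id,
                         hk = covariates$hk, ps = unname(ps),
                         logit_ps = unname(qlogis(ps)))),
    class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model>", length(x$coefficients), "covariates,",
      sum(x$scores$hk), "HK /", sum(!x$scores$hk), "controls\n")
  cat("  AUC:", round(propensity_auc(x), 3),
      if (x$separation) " (ridge fallback)" else "", "\n")
  invisible(x)
}

# Rank-based (Mann-Whitney) AUC of the scores.
propensity_auc <- function(model) {
  s <- model$scores
  r <- rank(s$ps)
  n1 <- sum(s$hk); n0 <- sum(!s$hk)
  (sum(r[s$hk]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Greedy 1:1 propensity-score matching without replacement
#'
#' HK members are processed in descending propensity-score order (ties by
#' ascending `patient_id`); each is paired with the unused control nearest on
#' the logit propensity scale within the caliper (ties by smaller control
#' `patient_id`). The default caliper is `caliper_sd` times the pooled SD of
#' the logit scores; `caliper_sd = NULL` disables the caliper. Matching is
#' fully deterministic.
#'
#' @param model A [fit_propensity()] result.
#' @param caliper_sd Caliper width in pooled logit-SD units (default 0.2), or
#'   `NULL` for no caliper.
#' @return A `matched_pairs` tibble `(pair_id, hk_id, control_id, ps_hk,
#'   ps_control, logit_diff)` with attributes `caliper` and `unmatched_hk`.
#' @export
match_1to1 <- function(model, caliper_sd = 0.2) {
  stopifnot(inherits(model, "propensity_model"))
  s <- model$scores
  hk <- s %>% filter(.data$hk) %>%
    arrange(desc(.data$ps), .data$patient_id)
  ct <- s %>% filter(!.data$hk) %>% arrange(.data$patient_id)
  caliper <- if (is.null(caliper_sd)) Inf else
    caliper_sd * sd(s$logit_ps)
  if (!is.finite(caliper)) caliper <- Inf

  free <- rep(TRUE, nrow(ct))
  ct_logit <- ct$logit_ps
  res <- vector("list", nrow(hk))
  for (i in seq_len(nrow(hk))) {
    idx <- which(free)
    if (!length(idx)) break
    dist <- abs(ct_logit[idx] - hk$logit_ps[i])
    j <- idx[order(dist, ct$patient_id[idx])[1]]
    if (abs(ct_logit[j] - hk$logit_ps[i]) <= caliper) {
      free[j] <- FALSE
      res[[i]] <- tibble(hk_id = hk$patient_id[i],
                         control_id = ct$patient_id[j],
                         ps_hk = hk$ps[i], ps_control = ct$ps[j],
                         logit_diff = hk$logit_ps[i] - ct_logit[j])
    }
  }
  pairs <- bind_rows(res)
  if (nrow(pairs)) {
    pairs <- pairs %>%
      arrange(.data$hk_id) %>%
      mutate(pair_id = row_number(), .before = 1)
  } else {
    pairs <- tibble(pair_id = integer(), hk_id = integer(),
                    control_id = integer(), ps_hk = double(),
                    ps_control = double(), logit_diff = double())
  }
  structure(pairs, class = c("matched_pairs", class(pairs)),
            caliper = caliper,
            unmatched_hk = setdiff(hk$patient_id, pairs$hk_id))
}
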