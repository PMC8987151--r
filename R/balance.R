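#' Standardized difference between two groups
#'
#' The scale-free balance diagnostic used to judge matching quality:
#' continuous `d = (m1 - m2) / sqrt((s1^2 + s2^2)/2)` with sample SDs, binary
#' `d = (p1 - p2) / sqrt((p1(1-p1) + p2(1-p2))/2)`. The sign is group 1 minus
#' group 2 (HK minus control by convention); `|d| <= 0.10` is conventionally
#' regarded as inconsequential imbalance. A degenerate `0/0` returns 0; zero
#' pooled variance with unequal means is undefined and raises an error.
#'
#' @param x,y Numeric (or logical) samples for the two groups. For
#'   `kind = "binary"` these are 0/1 indicators.
#' @param kind `"auto"` (binary when both samples only take values 0/1),
#'   `"continuous"`, or `"binary"`.
#' @return Signed standardized difference (a single number).
#' @examples
#' standardized_difference(rep(c(1, 0), c(407, 596)),
#'                         rep(c(1, 0), c(404, 599)))  # ~0.01
#' @export
standardized_difference <- function(x, y,
                                    kind = c("auto", "continuous", "binary")) {
  kind <- match.arg(kind)
  x <- as.numeric(x); y <- as.numeric(y)
  if (kind == "auto") {
    kind <- if (all(c(x, y) %in% c(0, 1))) "binary" else "continuous"
  }
  if (kind == "binary") {
    p1 <- mean(x); p2 <- mean(y)
    v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
    if (v == 0) {
      if (p1 == p2) return(0)
      abort("standardized difference undefined: zero pooled variance with unequal proportions")
    }
    return((p1 - p2) / sqrt(v))
  }
  m1 <- mean(x); m2 <- mean(y)
  v <- (var(x) + var(y)) / 2
  if (is.na(v) || v == 0) {
    if (isTRUE(all.equal(m1, m2))) return(0)
    abort("standardized difference undefined: zero pooled variance with unequal means")
  }
  (m1 - m2) / sqrt(v)
}

# Two-sided p-value: Student's t for continuous, Pearson chi-square (no
# continuity correction) for binary. Degenerate inputs give p = 1.
balance_p_value <- function(x, y, kind) {
  if (kind == "binary") {
    tab <- rbind(c(sum(x), length(x) - sum(x)),
                 c(sum(y), length(y) - sum(y)))
    if (any(colSums(tab) == 0)) return(1)
    out <- suppressWarnings(chisq.test(tab, correct = FALSE))
    return(unname(out$p.value))
  }
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  unname(t.test(x, y, var.equal = TRUE)$p.value)
}

#' Covariate balance report
#'
#' One row per covariate with HK and control means (proportions for binary
#' covariates), a two-sided p-value (Student's t-test for continuous,
#' chi-square for binary; reported descriptively, never used for selection),
#' and the signed standardized difference (HK minus control). Rows with
#' `|d| > 0.10` are flagged as imbalanced.
#'
#' @param covariates Covariate tibble (from [build_covariates()]) with a
#'   logical `hk` column.
#' @param digits Decimal places for the reported standardized difference
#'   (default 2, matching the conventional presentation); the unrounded value
#'   is kept in `std_diff_raw`.
#' @return A `balance_report` tibble: `covariate`, `kind`, `mean_hk`,
#'   `mean_control`, `p_value`, `std_diff`, `std_diff_raw`, `balanced`.
#' @export
balance_report <- function(covariates, digits = 2) {
  if (!"hk" %in% names(covariates)) {
    abort("`covariates` must carry a logical `hk` column")
  }
  vars <- covariate_columns(covariates)
  rows <- purrr::map(vars, function(v) {
    x <- as.numeric(covariates[[v]][covariates$hk])
    y <- as.numeric(covariates[[v]][!covariates$hk])
    kind <- if (all(c(x, y) %in% c(0, 1))) "binary" else "continuous"
    d <- standardized_difference(x, y, kind)
    tibble(covariate = v, kind = kind,
           mean_hk = mean(x), mean_control = mean(y),
           p_value = balance_p_value(x, y, kind),
           std_diff = round(d, digits), std_diff_raw = d)
  })
  out <- bind_rows(rows) %>%
    mutate(balanced = abs(.data$std_diff_raw) <= 0.10)
  class(out) <- c("balance_report", class(out))
  out
}
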