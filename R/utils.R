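# Interval arithmetic is done on integer day offsets; a "month" is a fixed
# 30-day window throughout the package.
DAYS_PER_MONTH <- 30

as_date_scalar <- function(x, field) {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(out) != 1 || is.na(out)) {
    abort(sprintf("`%s` must be a single parseable date, got %s",
                  field, deparse(substitute(x))))
  }
  out
}

days_between <- function(from, to) as.numeric(to) - as.numeric(from)

# mean/sd of a lognormal on the natural scale -> (meanlog, sdlog)
lnorm_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  sdlog2 <- log1p((sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

rlnorm_mean <- function(n, mean, sd) {
  p <- lnorm_params(mean, sd)
  if (p[["sdlog"]] == 0) return(rep(mean, n))
  rlnorm(n, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]])
}

# Split ";"-separated ICD-10 strings into individual codes.
split_codes <- function(x) strsplit(x, ";", fixed = TRUE)

# TRUE where a single code starts with any of the prefixes.
code_has_prefix <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

# Vectorised prefix match on ";"-separated diagnosis strings. Matching is done
# on the (few) unique strings and joined back, so cost is independent of the
# number of claims.
diag_matches_prefix <- function(diagnosis, prefixes) {
  u <- unique(diagnosis)
  hit <- vapply(split_codes(u), function(cs) any(code_has_prefix(cs, prefixes)),
                logical(1))
  unname(hit[match(diagnosis, u)])
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must be a proportion in [0, 1]", field))
  }
  invisible(x)
}

check_pos <- function(x, field, strict = FALSE) {
  ok <- is.numeric(x) && !anyNA(x) && all(if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be %s", field,
                  if (strict) "strictly positive" else "non-negative"))
  }
  invisible(x)
}
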