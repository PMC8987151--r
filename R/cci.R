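#' Charlson Comorbidity Index from ICD-10 codes
#'
#' The package ships the Quan ICD-10 coding algorithm for the 17 Charlson
#' conditions with the original Charlson weights as an editable CSV
#' (`system.file("extdata", "charlson_icd10_quan.csv", package = "kmsacohort")`).
#' `charlson_map()` loads it; `charlson_index()` scores a set of diagnosis
#' codes. The usual severity hierarchies are applied: diabetes with
#' complication supersedes uncomplicated diabetes, moderate/severe liver
#' disease supersedes mild, and metastatic solid tumor supersedes any
#' malignancy.
#'
#' @param map A data frame with columns `condition`, `weight`, `prefixes`
#'   (space-separated ICD-10 prefixes), as returned by `charlson_map()`.
#' @return `charlson_map()`: a tibble of conditions, weights and prefix lists.
#' @export
charlson_map <- function() {
  path <- system.file("extdata", "charlson_icd10_quan.csv",
                      package = "kmsacohort", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE) %>%
    mutate(prefixes = strsplit(.data$prefixes, " ", fixed = TRUE))
}

hierarchy_pairs <- function() {
  list(c("diabetes_with_complication", "diabetes_without_complication"),
       c("moderate_severe_liver_disease", "mild_liver_disease"),
       c("metastatic_solid_tumor", "any_malignancy"))
}

#' @rdname charlson_map
#' @param codes Character vector of individual ICD-10 codes (one code per
#'   element, not ";"-separated strings).
#' @return `charlson_index()`: a single integer score.
#' @examples
#' charlson_index(c("E11.2", "K70.3"))  # diabetes w/ complication + mild liver
#' @export
charlson_index <- function(codes, map = charlson_map()) {
  if (length(codes) == 0) return(0L)
  present <- vapply(map$prefixes, function(p) any(code_has_prefix(codes, p)),
                    logical(1))
  names(present) <- map$condition
  for (h in hierarchy_pairs()) {
    if (isTRUE(present[h[1]])) present[h[2]] <- FALSE
  }
  as.integer(sum(map$weight[present]))
}

# Vectorised scoring: one CCI per patient from a long (patient, code) table.
# Works on unique codes so cost is independent of claim volume.
charlson_scores <- function(patient_id, code, map = charlson_map()) {
  u <- unique(code)
  cond <- matrix(FALSE, length(u), nrow(map),
                 dimnames = list(NULL, map$condition))
  for (j in seq_len(nrow(map))) {
    cond[, j] <- code_has_prefix(u, map$prefixes[[j]])
  }
  idx <- match(code, u)
  has <- rowsum(cond[idx, , drop = FALSE] + 0, patient_id) > 0
  for (h in hierarchy_pairs()) {
    has[, h[2]] <- has[, h[2]] & !has[, h[1]]
  }
  tibble(patient_id = rownames(has) %>% type.convert(as.is = TRUE),
         cci = as.integer(has %*% map$weight))
}
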