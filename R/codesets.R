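#' Diagnosis code sets for cohort identification
#'
#' A code set bundles the ICD-10 prefixes that identify the chronic kidney
#' disease (CKD) base cohort, the hyperkalemia (HK) exposure, and (for the
#' sensitivity analysis) malignant disease. Matching is prefix-based, so
#' `"N18"` matches `"N18.5"`.
#'
#' @param ckd_codes,hk_codes,malignancy_codes Character vectors of ICD-10
#'   prefixes (uppercase alphanumeric, optionally with a dot).
#' @return A `code_set` list with elements `ckd_codes`, `hk_codes`,
#'   `malignancy_codes`.
#' @examples
#' codes <- default_code_set()
#' codes$hk_codes
#' @export
code_set <- function(ckd_codes, hk_codes, malignancy_codes = character()) {
  for (nm in c("ckd_codes", "hk_codes")) {
    x <- get(nm)
    if (!is.character(x) || length(x) == 0) {
      abort(sprintf("`%s` must be a non-empty character vector", nm))
    }
  }
  all_codes <- c(ckd_codes, hk_codes, malignancy_codes)
  if (any(!grepl("^[A-Z][A-Z0-9.]*$", all_codes))) {
    abort("ICD-10 prefixes must be uppercase alphanumeric with optional dots")
  }
  structure(
    list(ckd_codes = ckd_codes, hk_codes = hk_codes,
         malignancy_codes = malignancy_codes),
    class = "code_set"
  )
}

#' @rdname code_set
#' @export
default_code_set <- function() {
  code_set(
    ckd_codes = c("E10.2", "E11.2", "E12.2", "E13.2", "E14.2",
                  "I12", "I13", "N03", "N04", "N05", "N18", "N19",
                  "Z49", "Z99.2"),
    hk_codes = "E87.5",
    malignancy_codes = paste0("C", sprintf("%02d", 0:97))
  )
}

#' Baseline comorbidity and drug-class definitions
#'
#' `default_comorbidity_map()` returns the comorbidity flags used as matching
#' covariates, each with the ICD-10 prefixes that identify it in claims.
#' `default_drug_map()` returns the prescription drug-class flags and the
#' drug-class codes that identify them in the prescriptions table.
#'
#' @return A tibble with columns `flag` and `prefixes` (list column) for the
#'   comorbidity map; `flag` and `classes` for the drug map.
#' @export
default_comorbidity_map <- function() {
  tribble(
    ~flag,            ~prefixes,
    "hypertension",   c("I10"),
    "dyslipidemia",   c("E78"),
    "t2dm",           c("E11"),
    "heart_failure",  c("I50"),
    "arrhythmia",     c("I48", "I49"),
    "angina",         c("I20"),
    "mi",             c("I21", "I22"),
    "other_cvd",      c("I25"),
    "stroke",         c("I63", "I64"),
    "tia",            c("G45"),
    "other_cbd",      c("I67"),
    "pvd",            c("I73"),
    "peptic_ulcer",   c("K25", "K26", "K27", "K28"),
    "copd",           c("J44"),
    "rheumatic",      c("M05", "M06"),
    "malignancy",     paste0("C", sprintf("%02d", 0:97))
  )
}

#' @rdname default_comorbidity_map
#' @export
default_drug_map <- function() {
  tribble(
    ~flag,                 ~classes,
    "arb",                 "ARB",
    "mra",                 "MRA",
    "acei",                "ACEI",
    "ccb",                 "CCB",
    "loop_diuretic",       "LOOP",
    "nsaid",               "NSAID",
    "antiplatelet",        "APLT",
    "beta_blocker",        "BB",
    "anti_dyslipidemia",   "LIPID",
    "insulin",             "INS",
    "oad",                 "OAD",
    "bronchodilator",      "BRONCH",
    "antihypertension",    "AHT"
  )
}

# Dialysis is claim-based (renal replacement therapy codes), not a drug class.
dialysis_prefixes <- function() "Z49"
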