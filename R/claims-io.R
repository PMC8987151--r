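#' Claims dataset container
#'
#' A `claims_dataset` binds the three input tables of a claims analysis by
#' patient identifier:
#' * `patients`: `patient_id`, `sex` (`"F"`/`"M"`), `birth_date`,
#'   `death_date` (NA if alive), `enroll_start`, `enroll_end`;
#' * `claims`: `claim_id`, `patient_id`, `setting`
#'   (`"inpatient"`/`"outpatient"`), `service_date`,
#'   `admission_date`/`discharge_date` (inpatient only), `diagnosis`
#'   (`";"`-separated ICD-10 codes) and six non-negative cost components
#'   (`cost_medication`, `cost_examination`, `cost_treatment`,
#'   `cost_surgery`, `cost_consumable`, `cost_other`);
#' * `prescriptions`: `patient_id`, `date`, `drug_class`.
#'
#' @param patients,claims,prescriptions Data frames with the columns above.
#' @return A validated `claims_dataset` list of tibbles.
#' @export
claims_dataset <- function(patients, claims, prescriptions) {
  validate_claims_dataset(
    new_claims_dataset(as_tibble(patients), as_tibble(claims),
                       as_tibble(prescriptions)))
}

new_claims_dataset <- function(patients, claims, prescriptions) {
  structure(list(patients = patients, claims = claims,
                 prescriptions = prescriptions),
            class = "claims_dataset")
}

cost_components <- function() {
  paste0("cost_", c("medication", "examination", "treatment", "surgery",
                    "consumable", "other"))
}

#' @rdname claims_dataset
#' @param data A `claims_dataset`.
#' @export
validate_claims_dataset <- function(data) {
  stopifnot(inherits(data, "claims_dataset"))
  p <- data$patients; cl <- data$claims; rx <- data$prescriptions
  if (anyDuplicated(p$patient_id)) abort("duplicated patient_id in patients")
  if (!all(cl$patient_id %in% p$patient_id)) {
    abort("claims reference patient_id absent from patients")
  }
  if (!all(rx$patient_id %in% p$patient_id)) {
    abort("prescriptions reference patient_id absent from patients")
  }
  if (!all(cl$setting %in% c("inpatient", "outpatient"))) {
    abort("claims$setting must be 'inpatient' or 'outpatient'")
  }
  ip <- cl$setting == "inpatient"
  if (any(is.na(cl$admission_date[ip])) ||
      any(cl$discharge_date[ip] < cl$admission_date[ip], na.rm = TRUE)) {
    abort("inpatient claims need admission_date <= discharge_date")
  }
  for (comp in cost_components()) {
    if (any(cl[[comp]] < 0)) abort(sprintf("negative %s", comp))
  }
  death <- p$death_date[match(cl$patient_id, p$patient_id)]
  if (any(!is.na(death) & cl$service_date > death)) {
    abort("claims dated after death_date")
  }
  rxd <- p$death_date[match(rx$patient_id, p$patient_id)]
  if (any(!is.na(rxd) & rx$date > rxd)) {
    abort("prescriptions dated after death_date")
  }
  data
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat("  patients:     ", nrow(x$patients), "\n")
  cat("  claims:       ", nrow(x$claims), "\n")
  cat("  prescriptions:", nrow(x$prescriptions), "\n")
  invisible(x)
}

#' Read and write claims datasets as delimited text
#'
#' The three tables are written as UTF-8 CSV with a header row and ISO-8601
#' dates, plus a `manifest.json` recording the generating configuration and
#' seed when the dataset came from [simulate_population()].
#'
#' @param data A `claims_dataset`.
#' @param dir Directory to write to / read from.
#' @param config Optional [sim_config()] recorded in the manifest.
#' @return `write_claims()` returns `dir` invisibly; `read_claims()` returns a
#'   `claims_dataset`.
#' @export
write_claims <- function(data, dir, config = NULL) {
  stopifnot(inherits(data, "claims_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(data$patients, file.path(dir, "patients.csv"), na = "")
  readr::write_csv(data$claims, file.path(dir, "claims.csv"), na = "")
  readr::write_csv(data$prescriptions, file.path(dir, "prescriptions.csv"),
                   na = "")
  manifest <- list(tables = c("patients.csv", "claims.csv",
                              "prescriptions.csv"))
  if (!is.null(config)) {
    manifest$config <- unclass(config)
    manifest$seed <- config$rng_seed
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, Date = "ISO8601")
  invisible(dir)
}

#' @rdname write_claims
#' @export
read_claims <- function(dir) {
  rd <- function(f, types) {
    readr::read_csv(file.path(dir, f), col_types = types, na = "")
  }
  patients <- rd("patients.csv", readr::cols(
    patient_id = "i", sex = "c", birth_date = "D", death_date = "D",
    enroll_start = "D", enroll_end = "D"))
  claims <- rd("claims.csv", readr::cols(
    claim_id = "i", patient_id = "i", setting = "c", service_date = "D",
    admission_date = "D", discharge_date = "D", diagnosis = "c",
    .default = "d"))
  prescriptions <- rd("prescriptions.csv", readr::cols(
    patient_id = "i", date = "D", drug_class = "c"))
  claims_dataset(patients, claims, prescriptions)
}
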