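#' Patient first-diagnosis records
#'
#' The empirical substrate for the phi coefficient, the dependence screen,
#' temporal diagnosis-date correspondence and backdoor queries: a long-format
#' table of first diagnoses (one row per individual and disease category,
#' with the calendar year of first diagnosis) together with a demographics
#' table (age at baseline in years, sex). Individuals present in the
#' demographics but absent from the diagnosis rows count as having no
#' recorded disease.
#'
#' @param diagnoses data frame with columns `individual_id`, `code`
#'   (ICD-10-CM, truncated to its three-character category), `year` (integer
#'   calendar year of first diagnosis, 1900-2100).
#' @param demographics data frame with columns `individual_id`, `age`
#'   (years), `sex`.
#' @return An object of class `patient_records`.
#' @export
patient_records <- function(diagnoses, demographics) {
  stopifnot(is.data.frame(diagnoses),
            all(c("individual_id", "code", "year") %in% names(diagnoses)),
            is.data.frame(demographics),
            all(c("individual_id", "age", "sex") %in% names(demographics)))
  diagnoses$individual_id <- as.character(diagnoses$individual_id)
  demographics$individual_id <- as.character(demographics$individual_id)
  if (anyDuplicated(demographics$individual_id)) {
    abort("duplicated individual_id in demographics")
  }
  if (nrow(diagnoses)) {
    diagnoses$code <- truncate_code(as.character(diagnoses$code))
    diagnoses$year <- as.integer(diagnoses$year)
    if (any(diagnoses$year < 1900 | diagnoses$year > 2100, na.rm = TRUE)) {
      abort("diagnosis year outside [1900, 2100]")
    }
    if (anyDuplicated(paste(diagnoses$individual_id, diagnoses$code))) {
      abort("more than one first-diagnosis row per (individual, code)")
    }
    missing_demo <- setdiff(diagnoses$individual_id,
                            demographics$individual_id)
    if (length(missing_demo)) {
      abort("%d individuals in diagnoses missing from demographics",
            length(missing_demo))
    }
  }
  structure(list(diagnoses = diagnoses, demographics = demographics),
            class = "patient_records")
}

#' @export
print.patient_records <- function(x, ...) {
  cat(sprintf("<patient_records> %d individuals, %d diagnosis rows, %d codes\n",
              nrow(x$demographics), nrow(x$diagnoses),
              length(unique(x$diagnoses$code))))
  invisible(x)
}

#' Number of individuals in a record set
#' @param records a [patient_records()] object.
#' @return Integer count.
#' @export
n_individuals <- function(records) {
  stopifnot(inherits(records, "patient_records"))
  nrow(records$demographics)
}

#' Read diagnosis records and demographics from TSV
#'
#' @param diagnoses_path TSV with columns `individual_id`, `icd10_code`
#'   (or `code`), `year`.
#' @param demographics_path TSV with columns `individual_id`, `age`, `sex`.
#' @return A [patient_records()] object.
#' @export
read_records <- function(diagnoses_path, demographics_path) {
  dg <- utils::read.delim(diagnoses_path, header = TRUE, sep = "\t",
                          quote = "", stringsAsFactors = FALSE)
  names(dg)[names(dg) == "icd10_code"] <- "code"
  dm <- utils::read.delim(demographics_path, header = TRUE, sep = "\t",
                          quote = "", stringsAsFactors = FALSE)
  patient_records(dg, dm)
}

#' Write diagnosis records and demographics to TSV
#' @param records a [patient_records()] object.
#' @param diagnoses_path,demographics_path output paths.
#' @return The paths, invisibly.
#' @export
write_records <- function(records, diagnoses_path, demographics_path) {
  dg <- records$diagnoses
  names(dg)[names(dg) == "code"] <- "icd10_code"
  utils::write.table(dg, diagnoses_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(records$demographics, demographics_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(diagnoses_path, demographics_path))
}

#' Restrict records to a demographic subpopulation
#'
#' @param records a [patient_records()] object.
#' @param predicate a function of the demographics data frame returning a
#'   logical vector (e.g. `function(d) d$age >= 50`).
#' @return A [patient_records()] restricted to qualifying individuals.
#' @export
restrict_population <- function(records, predicate) {
  stopifnot(inherits(records, "patient_records"), is.function(predicate))
  keep <- predicate(records$demographics)
  if (!is.logical(keep) || length(keep) != nrow(records$demographics)) {
    abort("predicate must return one logical per individual")
  }
  keep[is.na(keep)] <- FALSE
  ids <- records$demographics$individual_id[keep]
  if (!length(ids)) warning("restriction produced an empty population")
  patient_records(
    records$diagnoses[records$diagnoses$individual_id %in% ids, ,
                      drop = FALSE],
    records$demographics[keep, , drop = FALSE])
}

# named logical disease-status vector over all individuals
disease_status <- function(records, code) {
  ids <- records$demographics$individual_id
  has <- records$diagnoses$individual_id[records$diagnoses$code == code]
  stats::setNames(ids %in% has, ids)
}
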