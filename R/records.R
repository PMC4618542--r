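#' Admission-level cohort data model
#'
#' A cohort is a tibble with one row per hospitalization and the columns
#' `institution_id` (character), `year` (integer calendar year of admission),
#' `age_years` (integer completed years at admission), `los_days` (integer
#' length of stay, >= 1), `billed_charges` (non-negative dollars) and `died`
#' (logical, `TRUE` for inpatient death). Analysis is at the admission level:
#' repeat admissions of the same patient are separate rows and are not linked.
#'
#' @name cohort
#' @keywords internal
NULL

COHORT_COLUMNS <- c("institution_id", "year", "age_years", "los_days",
                    "billed_charges", "died")

CSV_COLUMNS <- c("institution_id", "year", "age_years", "los_days",
                 "billed_charges", "discharge_status")

DIED_TOKENS  <- c("died", "dead", "inpatient_death", "1", "true")
ALIVE_TOKENS <- c("alive", "discharged", "0", "false")

#' Assemble and validate an admission cohort
#'
#' @param records data frame with the cohort columns (see [read_admissions()]).
#' @param provenance free-text label recording where the records came from.
#' @param year_range allowed admission years, inclusive.
#' @param strict abort on the first invalid record (`TRUE`) or drop invalid
#'   records and record the dropped count in the `"dropped"` attribute.
#'
#' @return A tibble of valid admission records with attributes `provenance`
#'   and `dropped` (number of invalid rows removed; 0 under `strict`).
#' @export
as_cohort <- function(records, provenance = "unspecified",
                      year_range = c(2004L, 2013L), strict = TRUE) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop("cohort is missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- records[COHORT_COLUMNS]
  records$institution_id <- as.character(records$institution_id)
  records$died <- as.logical(records$died)

  violations <- record_violations(records, year_range)
  bad <- which(lengths(violations) > 0)
  if (length(bad) > 0 && strict) {
    stop(sprintf("invalid record at row %d: %s", bad[1],
                 paste(violations[[bad[1]]], collapse = "; ")), call. = FALSE)
  }
  dropped <- length(bad)
  if (dropped > 0) records <- records[-bad, ]

  attr(records, "provenance") <- provenance
  attr(records, "dropped") <- dropped
  records
}

# Vectorised invariant checks; returns a list of character vectors, one per row.
record_violations <- function(records, year_range = c(2004L, 2013L)) {
  n <- nrow(records)
  out <- vector("list", n)
  if (n == 0) return(out)
  checks <- list(
    age_years = ifelse(
      is.na(records$age_years) | records$age_years != floor(records$age_years) |
        records$age_years < 0 | records$age_years > 21,
      "age_years must be an integer in [0, 21]", NA_character_),
    year = ifelse(
      is.na(records$year) | records$year < year_range[1] | records$year > year_range[2],
      sprintf("year must be in [%d, %d]", year_range[1], year_range[2]),
      NA_character_),
    los_days = ifelse(
      is.na(records$los_days) | records$los_days != floor(records$los_days) |
        records$los_days < 1,
      "los_days must be an integer >= 1", NA_character_),
    billed_charges = ifelse(
      is.na(records$billed_charges) | records$billed_charges < 0,
      "billed_charges must be >= 0", NA_character_),
    died = ifelse(is.na(records$died), "died must be TRUE or FALSE", NA_character_),
    institution_id = ifelse(
      is.na(records$institution_id) | records$institution_id == "",
      "institution_id must be non-empty", NA_character_)
  )
  mat <- do.call(cbind, checks)
  for (i in seq_len(n)) {
    v <- mat[i, ]
    out[[i]] <- unname(v[!is.na(v)])
  }
  out
}

#' Validate a single admission record
#'
#' Total function: never errors, returns a character vector of human-readable
#' violation descriptions (empty when the record satisfies every invariant).
#' Each message names the offending field.
#'
#' @param record a list or one-row data frame with the cohort fields
#'   `institution_id`, `year`, `age_years`, `los_days`, `billed_charges`,
#'   `died`.
#' @param year_range allowed admission years, inclusive.
#'
#' @return Character vector of violations; `character(0)` if valid.
#' @export
#'
#' @examples
#' validate_record(list(institution_id = "A", year = 2005, age_years = 0,
#'                      los_days = 12, billed_charges = 163000, died = FALSE))
validate_record <- function(record, year_range = c(2004L, 2013L)) {
  df <- tibble::as_tibble(record[COHORT_COLUMNS])
  record_violations(df, year_range)[[1]]
}

parse_discharge_status <- function(status) {
  s <- tolower(trimws(as.character(status)))
  out <- rep(NA, length(s))
  out[s %in% DIED_TOKENS] <- TRUE
  out[s %in% ALIVE_TOKENS] <- FALSE
  out
}

#' Read an admission cohort from delimited text
#'
#' Expects a comma-separated UTF-8 file with header columns `institution_id`,
#' `year`, `age_years`, `los_days`, `billed_charges`, `discharge_status`; one
#' row per hospitalization. Discharge status is mapped case-insensitively:
#' `died`/`dead`/`inpatient_death`/`1`/`true` mean inpatient death,
#' `alive`/`discharged`/`0`/`false` mean discharged alive; anything else is
#' invalid.
#'
#' @param path path to the CSV file.
#' @param strict if `TRUE` (default) any invalid row aborts with a message
#'   naming the row and the violated invariant; if `FALSE` invalid rows are
#'   dropped and counted in the returned cohort's `"dropped"` attribute.
#' @param year_range allowed admission years, inclusive.
#'
#' @return A cohort tibble (see [as_cohort()]); `attr(x, "dropped")` holds the
#'   number of rows removed in lenient mode.
#' @export
read_admissions <- function(path, strict = TRUE, year_range = c(2004L, 2013L)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  header <- if (length(first) == 0) character(0) else strsplit(first, ",")[[1]]
  missing <- setdiff(CSV_COLUMNS, trimws(header))
  if (length(missing) > 0) {
    stop("missing required columns in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      institution_id = readr::col_character(),
      year = readr::col_integer(),
      age_years = readr::col_integer(),
      los_days = readr::col_integer(),
      billed_charges = readr::col_double(),
      discharge_status = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  raw$died <- parse_discharge_status(raw$discharge_status)
  raw$discharge_status <- NULL
  as_cohort(raw, provenance = path, year_range = year_range, strict = strict)
}

#' Write an admission cohort to delimited text
#'
#' Inverse of [read_admissions()]: charges are written with two decimal places
#' (dollars and cents), so a read-back reproduces the cohort field-for-field
#' for cent-precision charges. An empty cohort produces a header-only file.
#'
#' @param cohort cohort tibble.
#' @param path output path.
#'
#' @return `path`, invisibly.
#' @export
write_admissions <- function(cohort, path) {
  out <- data.frame(
    institution_id = cohort$institution_id,
    year = cohort$year,
    age_years = cohort$age_years,
    los_days = cohort$los_days,
    billed_charges = sprintf("%.2f", cohort$billed_charges),
    discharge_status = ifelse(cohort$died, "died", "alive"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
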