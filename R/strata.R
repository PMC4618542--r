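#' Grouping conventions: age bands and hospital-volume strata
#'
#' Five age bands partition ages 0-21 and five volume strata partition the
#' non-negative total admission counts. The age bands follow the convention of
#' the published summary tables for this cohort: `<1` = age 0, `1` = age 1,
#' `2-4`, `5-12`, `>12` = ages 13-21. Both definitions are plain data frames so
#' an alternate convention (for example `5-13` / `14-21`) can be supplied as a
#' drop-in replacement and round-tripped through YAML or JSON.
#'
#' @return `age_band_defs()`: a tibble with columns `label`, `lower`, `upper`
#'   (both inclusive, years). `volume_stratum_defs()`: a tibble with columns
#'   `label`, `lower`, `upper` (inclusive bounds on total admissions over the
#'   study window; the top stratum is unbounded).
#' @export
age_band_defs <- function() {
  tibble::tibble(
    label = c("<1", "1", "2-4", "5-12", ">12"),
    lower = c(0L, 1L, 2L, 5L, 13L),
    upper = c(0L, 1L, 4L, 12L, 21L)
  )
}

#' @rdname age_band_defs
#' @export
volume_stratum_defs <- function() {
  tibble::tibble(
    label = c("<100", "100-199", "200-299", "300-499", ">=500"),
    lower = c(0, 100, 200, 300, 500),
    upper = c(99, 199, 299, 499, Inf)
  )
}

check_band_defs <- function(bands, domain) {
  stopifnot(all(c("label", "lower", "upper") %in% names(bands)))
  o <- order(bands$lower)
  lo <- bands$lower[o]; hi <- bands$upper[o]
  if (lo[1] != min(domain) || any(lo[-1] != utils::head(hi, -1) + 1)) {
    stop("band definitions must partition their domain with no gaps or overlaps",
         call. = FALSE)
  }
  invisible(bands)
}

band_lookup <- function(x, bands) {
  idx <- vapply(x, function(v) {
    which(v >= bands$lower & v <= bands$upper)[1]
  }, integer(1))
  factor(bands$label[idx], levels = bands$label)
}

#' Age band of an admission
#'
#' @param age_years integer vector of completed ages, each in 0-21.
#' @param bands band definition table, by default [age_band_defs()].
#'
#' @return Factor of band labels with levels in band order.
#' @export
#'
#' @examples
#' age_band(c(0, 3, 13))
age_band <- function(age_years, bands = age_band_defs()) {
  check_band_defs(bands, 0:21)
  if (any(is.na(age_years)) || any(age_years < 0 | age_years > 21)) {
    stop("age_years must be in [0, 21]", call. = FALSE)
  }
  band_lookup(age_years, bands)
}

#' Volume stratum of an institution
#'
#' Strata are defined on the institution's TOTAL admission count over the study
#' window (the published table's "admissions / 10 years" header), not on the
#' per-year volume used for correlations.
#'
#' @param total_admissions integer vector of total admission counts, >= 0.
#' @param bands stratum definition table, by default [volume_stratum_defs()].
#'
#' @return Factor of stratum labels with levels in stratum order.
#' @export
#'
#' @examples
#' volume_stratum(c(99, 100, 252, 500))
volume_stratum <- function(total_admissions, bands = volume_stratum_defs()) {
  if (any(is.na(total_admissions)) || any(total_admissions < 0)) {
    stop("total_admissions must be >= 0", call. = FALSE)
  }
  band_lookup(total_admissions, bands)
}

#' Per-institution admission volume and mortality
#'
#' Computes, for each distinct institution in the cohort, the total admission
#' count over the study window, the number of inpatient deaths, the volume in
#' admissions per year (total / window length) and the crude mortality rate
#' (deaths / admissions).
#'
#' @param cohort cohort tibble.
#' @param window_years length of the study window in years (default 10).
#'
#' @return A tibble with columns `institution_id`, `total_admissions`,
#'   `deaths`, `volume`, `mortality_rate`, one row per institution.
#' @export
institution_profiles <- function(cohort, window_years = 10) {
  if (window_years <= 0) stop("window_years must be positive", call. = FALSE)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  cohort |>
    dplyr::group_by(.data$institution_id) |>
    dplyr::summarise(
      total_admissions = dplyr::n(),
      deaths = sum(.data$died),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      volume = .data$total_admissions / window_years,
      mortality_rate = .data$deaths / .data$total_admissions
    )
}

#' Exclude non-representative low-volume institutions
#'
#' Removes every admission belonging to an institution whose volume
#' (admissions per year) falls below a threshold and which, if
#' `require_zero_deaths` is `TRUE`, recorded no inpatient deaths. Such
#' institutions -- seeing an HLHS admission less than once a year and never an
#' in-hospital death -- are unlikely to reflect usual patterns of care, and
#' distort volume-trend analyses.
#'
#' @param cohort cohort tibble.
#' @param profiles institution profiles from [institution_profiles()], computed
#'   from `cohort`; computed automatically if omitted.
#' @param max_volume_threshold exclude institutions with `volume <` this value
#'   (admissions per year); default 1.
#' @param require_zero_deaths if `TRUE` (default) only institutions with zero
#'   deaths are eligible for exclusion.
#' @param window_years study window length, used only when `profiles` is
#'   computed here.
#'
#' @return A list with elements `cohort` (the filtered cohort) and `excluded`
#'   (the profile rows of the removed institutions, for audit).
#' @export
exclude_nonrepresentative <- function(cohort, profiles = NULL,
                                      max_volume_threshold = 1,
                                      require_zero_deaths = TRUE,
                                      window_years = 10) {
  if (is.null(profiles)) profiles <- institution_profiles(cohort, window_years)
  drop <- profiles$volume < max_volume_threshold
  if (require_zero_deaths) drop <- drop & profiles$deaths == 0
  excluded <- profiles[drop, ]
  kept <- cohort[!(cohort$institution_id %in% excluded$institution_id), ]
  attr(kept, "provenance") <- attr(cohort, "provenance")
  list(cohort = kept, excluded = excluded)
}
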