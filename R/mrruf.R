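#' Mortality-related resource utilization fraction (MRRUF)
#'
#' The MRRUF is the share of an inpatient resource that is expended during
#' hospitalizations ending in inpatient death:
#'
#' \deqn{\mathrm{MRRUF} = \frac{\sum_{i:\ \mathrm{died}} r_i}{\sum_i r_i}}
#'
#' where \eqn{r_i} is the resource for admission \eqn{i} -- length of stay in
#' inpatient-days (`domain = "los"`) or billed charges in dollars
#' (`domain = "charges"`). Because it is normalized to total expenditure, the
#' fraction is invariant to rescaling of the resource (so charge-domain MRRUF
#' is untouched by inflation or by charge-to-cost conversion factors).
#'
#' An empty cohort or a zero resource total yields an `NA` fraction, never a
#' division error: `NA` marks "undefined", which is distinct from a true 0
#' ("decedents accrued none of the resource").
#'
#' @param cohort cohort tibble (may be empty).
#' @param domain `"los"` or `"charges"`.
#'
#' @return An object of class `mrruf_result`: a list with fields `domain`,
#'   `decedent_total`, `grand_total` and `fraction` (in `[0, 1]`, or `NA` when
#'   the grand total is zero).
#' @export
#'
#' @examples
#' cohort <- tibble::tibble(
#'   institution_id = "A", year = 2005L, age_years = 0L,
#'   los_days = c(10L, 5L, 5L), billed_charges = 1e5, died = c(FALSE, TRUE, TRUE)
#' )
#' mrruf(cohort, "los")  # 10 / 20 = 0.5
mrruf <- function(cohort, domain = c("los", "charges")) {
  domain <- match.arg(domain)
  resource <- switch(domain, los = cohort$los_days, charges = cohort$billed_charges)
  decedent_total <- sum(as.numeric(resource[cohort$died]))
  grand_total <- sum(as.numeric(resource))
  fraction <- if (grand_total > 0) decedent_total / grand_total else NA_real_
  structure(
    list(domain = domain, decedent_total = decedent_total,
         grand_total = grand_total, fraction = fraction),
    class = "mrruf_result"
  )
}

#' @export
print.mrruf_result <- function(x, ...) {
  cat(sprintf("MRRUF (%s): %s  [decedent %s / total %s]\n",
              x$domain,
              if (is.na(x$fraction)) "NA (zero denominator)"
              else sprintf("%.3f", x$fraction),
              format(x$decedent_total, big.mark = ","),
              format(x$grand_total, big.mark = ",")))
  invisible(x)
}

#' Crude inpatient mortality rate
#'
#' @param cohort cohort tibble.
#' @return deaths / admissions, in `[0, 1]`; `NA` for an empty cohort.
#' @export
mortality_rate <- function(cohort) {
  n <- nrow(cohort)
  if (n == 0) return(NA_real_)
  sum(cohort$died) / n
}

#' Pool per-stratum MRRUFs into a whole-cohort MRRUF
#'
#' Given per-stratum fractions and the corresponding per-stratum resource
#' totals (the denominators), returns the resource-weighted mean
#' \eqn{\sum_g f_g T_g / \sum_g T_g}. For any partition of a cohort this is
#' algebraically identical to [mrruf()] computed on the whole cohort, so
#' whole-population fractions can be recovered exactly from published
#' stratified tables. Strata with `NA` fractions and zero totals are ignored.
#'
#' @param fractions numeric vector of per-stratum MRRUF fractions.
#' @param totals numeric vector of per-stratum resource totals (same length,
#'   non-negative, at least one positive).
#'
#' @return Pooled fraction in `[0, 1]`.
#' @export
#'
#' @examples
#' pooled_mrruf_from_strata(c(0.5, 0.0), c(10, 10))  # 0.25
pooled_mrruf_from_strata <- function(fractions, totals) {
  stopifnot(length(fractions) == length(totals))
  if (any(totals < 0, na.rm = TRUE)) stop("totals must be non-negative", call. = FALSE)
  keep <- totals > 0
  if (!any(keep)) stop("all resource totals are zero", call. = FALSE)
  if (any(is.na(fractions[keep]))) stop("NA fraction with positive total", call. = FALSE)
  sum(fractions[keep] * totals[keep]) / sum(totals[keep])
}

#' Stratified cohort summary (mortality and MRRUF per stratum)
#'
#' Produces one row per non-empty stratum with the admission count, deaths,
#' death percentage, resource totals and both MRRUFs -- the row structure of a
#' stratified mortality/resource table. Rows appear in stratum definition
#' order (band order, ascending year, or institution id).
#'
#' @param cohort non-empty cohort tibble.
#' @param grouping one of `"age_band"`, `"volume_stratum"`, `"year"`,
#'   `"institution"`.
#' @param window_years study window length, used to derive volume strata.
#'
#' @return Tibble with columns `stratum`, `n_admissions`, `n_deaths`,
#'   `death_pct`, `los_total`, `charges_total`, `mrruf_los`, `mrruf_charges`.
#' @export
stratified_summary <- function(cohort,
                               grouping = c("age_band", "volume_stratum",
                                            "year", "institution"),
                               window_years = 10) {
  grouping <- match.arg(grouping)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  stratum <- switch(
    grouping,
    age_band = age_band(cohort$age_years),
    volume_stratum = {
      prof <- institution_profiles(cohort, window_years)
      totals <- stats::setNames(prof$total_admissions, prof$institution_id)
      volume_stratum(unname(totals[cohort$institution_id]))
    },
    year = factor(cohort$year, levels = sort(unique(cohort$year))),
    institution = factor(cohort$institution_id,
                         levels = sort(unique(cohort$institution_id)))
  )
  cohort |>
    dplyr::mutate(.stratum = stratum) |>
    dplyr::group_by(.data$.stratum) |>
    dplyr::summarise(
      n_admissions = dplyr::n(),
      n_deaths = sum(.data$died),
      death_pct = 100 * sum(.data$died) / dplyr::n(),
      los_total = sum(as.numeric(.data$los_days)),
      charges_total = sum(.data$billed_charges),
      mrruf_los = mrruf_fraction(.data$los_days, .data$died),
      mrruf_charges = mrruf_fraction(.data$billed_charges, .data$died),
      .groups = "drop"
    ) |>
    dplyr::rename(stratum = ".stratum") |>
    dplyr::mutate(stratum = as.character(.data$stratum))
}

mrruf_fraction <- function(resource, died) {
  total <- sum(as.numeric(resource))
  if (total > 0) sum(as.numeric(resource[died])) / total else NA_real_
}

#' Reference summary tables: HLHS admissions in PHIS, 2004-2013
#'
#' Published stratified summaries of the 11,122 hypoplastic left heart
#' syndrome admissions recorded across 43 children's hospitals in the
#' Pediatric Health Information System between 2004 and 2013. These are the
#' calibration targets of [default_cohort_config()] and the inputs for
#' reconstructing the whole-population MRRUF by pooling. Charges in the
#' stratified blocks are in millions of dollars (`charges_musd`).
#'
#' The `5-12` age row's printed death percentage (3.3) disagrees with its own
#' counts (18/531 = 3.39, which rounds to 3.4); both are carried as printed.
#'
#' @return A list with elements `overall` (admissions, inpatient-days, total
#'   charges in dollars, deaths, decedent/survivor medians), `by_volume` and
#'   `by_age` (tibbles: `stratum`, `n_admissions`, `los_total`, `charges_musd`,
#'   `n_deaths`), and `mrruf_by_age` (tibble: `stratum`, `death_pct_printed`,
#'   `mrruf_los`, `mrruf_charges`).
#' @export
hlhs_reference_tables <- function() {
  list(
    overall = list(
      n_admissions = 11122L, los_total = 277027L, charges_total = 3928794660,
      n_deaths = 1145L, mortality_pct = 10.3,
      median_los_died = 17, median_los_alive = 12,
      median_charges_died = 4.09e5, median_charges_alive = 1.63e5,
      n_institutions = 43L, mean_admissions_per_institution = 259,
      sd_admissions_per_institution = 181
    ),
    by_volume = tibble::tibble(
      stratum = c("<100", "100-199", "200-299", "300-499", ">=500"),
      n_admissions = c(398L, 1441L, 2528L, 3652L, 3103L),
      los_total = c(8260L, 44777L, 64295L, 95722L, 63973L),
      charges_musd = c(138.9, 628.9, 895.1, 1429.1, 836.3),
      n_deaths = c(59L, 199L, 286L, 351L, 250L)
    ),
    by_age = tibble::tibble(
      stratum = c("<1", "1", "2-4", "5-12", ">12"),
      n_admissions = c(7585L, 484L, 2422L, 531L, 100L),
      los_total = c(226939L, 7696L, 34130L, 6753L, 1509L),
      charges_musd = c(3142, 126.0, 510.1, 121.4, 29.3),
      n_deaths = c(1055L, 22L, 42L, 18L, 8L)
    ),
    mrruf_by_age = tibble::tibble(
      stratum = c("<1", "1", "2-4", "5-12", ">12"),
      death_pct_printed = c(13.9, 4.5, 1.7, 3.3, 8.0),
      mrruf_los = c(0.178, 0.121, 0.057, 0.076, 0.185),
      mrruf_charges = c(0.238, 0.135, 0.083, 0.111, 0.220)
    )
  )
}
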