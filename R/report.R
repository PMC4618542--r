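#' Build a full MRRUF analysis report
#'
#' Composes the stratification, MRRUF and inferential layers into one
#' structured report mirroring the published analysis:
#'
#' * `overall` -- admissions, deaths, mortality percentage, total
#'   inpatient-days and charges, and both MRRUFs.
#' * `table1_block` -- stratified resource totals by hospital-volume stratum
#'   and by age band, with charges also expressed in $ millions
#'   (`charges_musd`) as in the published table.
#' * `table2_block` -- per age band: N, deaths %, both MRRUFs, and
#'   significance flags against the `<1` reference band (chi-square for
#'   mortality; Mann-Whitney on per-institution MRRUFs for the fractions),
#'   with the selected multiple-comparison correction.
#' * `trends_block` -- per-year mortality and MRRUF; least-squares trend of
#'   institution-year mortality on calendar year; Spearman correlations of
#'   per-institution mortality and MRRUF with institutional volume.
#'
#' The low-volume exclusion (when enabled) is applied to the trend and
#' correlation analyses only; the descriptive blocks summarize every
#' admission, so block totals always conserve to the overall block.
#'
#' @param cohort cohort tibble.
#' @param window_years study window length in years (default 10).
#' @param exclude_low_volume apply [exclude_nonrepresentative()] before the
#'   trend/correlation analyses.
#' @param max_volume_threshold volume threshold for the exclusion.
#' @param correction multiple-comparison correction for the pairwise age-band
#'   tests: `"bonferroni"` (default) or `"none"`.
#' @param reference_band reference age band for pairwise comparisons.
#'
#' @return A list of class `mrruf_report`.
#' @export
build_report <- function(cohort, window_years = 10,
                         exclude_low_volume = FALSE,
                         max_volume_threshold = 1,
                         correction = c("bonferroni", "none"),
                         reference_band = "<1") {
  correction <- match.arg(correction)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)

  overall <- list(
    n_admissions = nrow(cohort),
    n_deaths = sum(cohort$died),
    mortality_pct = 100 * mortality_rate(cohort),
    los_total = sum(as.numeric(cohort$los_days)),
    charges_total = sum(cohort$billed_charges),
    mrruf_los = mrruf(cohort, "los")$fraction,
    mrruf_charges = mrruf(cohort, "charges")$fraction
  )

  by_volume <- stratified_summary(cohort, "volume_stratum", window_years)
  by_age <- stratified_summary(cohort, "age_band", window_years)
  by_volume$charges_musd <- by_volume$charges_total / 1e6
  by_age$charges_musd <- by_age$charges_total / 1e6

  table2 <- age_comparisons(cohort, by_age, correction, reference_band,
                            window_years)
  trends <- trend_analyses(cohort, window_years, exclude_low_volume,
                           max_volume_threshold)

  structure(
    list(overall = overall,
         table1_block = list(by_volume = by_volume, by_age = by_age),
         table2_block = table2,
         trends_block = trends,
         options = list(window_years = window_years,
                        exclude_low_volume = exclude_low_volume,
                        max_volume_threshold = max_volume_threshold,
                        correction = correction,
                        reference_band = reference_band)),
    class = "mrruf_report"
  )
}

age_comparisons <- function(cohort, by_age, correction, reference_band,
                            window_years) {
  tab <- cbind(died = by_age$n_deaths,
               survived = by_age$n_admissions - by_age$n_deaths)
  rownames(tab) <- by_age$stratum

  homogeneity <- chi_square_homogeneity(tab)
  mortality_pairs <- if (reference_band %in% by_age$stratum && nrow(by_age) >= 2) {
    pairwise_vs_reference(tab, reference_band, correction)
  } else NULL

  mrruf_pairs <- mrruf_age_comparisons(cohort, by_age$stratum, reference_band,
                                       correction)

  summary <- by_age[, c("stratum", "n_admissions", "death_pct",
                        "mrruf_los", "mrruf_charges")]
  if (!is.null(mortality_pairs)) {
    flags <- stats::setNames(mortality_pairs$significant, mortality_pairs$group)
    summary$mortality_sig_vs_ref <- unname(flags[summary$stratum])
  }
  list(summary = summary, homogeneity = homogeneity,
       mortality_pairwise = mortality_pairs, mrruf_pairwise = mrruf_pairs)
}

# Mann-Whitney comparisons of MRRUF between age bands, using per-institution
# band MRRUFs as the observations (institutions with no band admissions or a
# zero resource total contribute nothing).
mrruf_age_comparisons <- function(cohort, band_labels, reference_band,
                                  correction) {
  if (!(reference_band %in% band_labels) || length(band_labels) < 2) return(NULL)
  cohort$.band <- as.character(age_band(cohort$age_years))
  per_inst <- function(band, domain) {
    sub <- cohort[cohort$.band == band, ]
    vals <- vapply(split(sub, sub$institution_id), function(g) {
      mrruf_fraction(if (domain == "los") g$los_days else g$billed_charges,
                     g$died)
    }, numeric(1))
    vals[!is.na(vals)]
  }
  rows <- list()
  others <- setdiff(band_labels, reference_band)
  k <- length(others)
  for (domain in c("los", "charges")) {
    ref_vals <- per_inst(reference_band, domain)
    for (band in others) {
      vals <- per_inst(band, domain)
      if (length(ref_vals) == 0 || length(vals) == 0) next
      res <- mann_whitney_u(vals, ref_vals)
      p_adj <- if (correction == "bonferroni") min(1, res$p_value * k) else res$p_value
      rows[[length(rows) + 1]] <- tibble::tibble(
        domain = domain, group = band, reference = reference_band,
        statistic = res$statistic, p_value = res$p_value, p_adjusted = p_adj,
        significant = p_adj < 0.05, n_group = length(vals),
        n_reference = length(ref_vals)
      )
    }
  }
  if (length(rows) == 0) NULL else dplyr::bind_rows(rows)
}

trend_analyses <- function(cohort, window_years, exclude_low_volume,
                           max_volume_threshold) {
  excluded <- tibble::tibble()
  analysis_cohort <- cohort
  if (exclude_low_volume) {
    filt <- exclude_nonrepresentative(cohort,
                                      max_volume_threshold = max_volume_threshold,
                                      window_years = window_years)
    analysis_cohort <- filt$cohort
    excluded <- filt$excluded
  }

  by_year <- stratified_summary(analysis_cohort, "year", window_years)

  inst_year <- analysis_cohort |>
    dplyr::group_by(.data$institution_id, .data$year) |>
    dplyr::summarise(n = dplyr::n(), deaths = sum(.data$died), .groups = "drop") |>
    dplyr::mutate(mortality_rate = .data$deaths / .data$n)

  year_trend <- if (length(unique(inst_year$year)) >= 3) {
    ols_trend(inst_year$year, inst_year$mortality_rate)
  } else NULL

  prof <- institution_profiles(analysis_cohort, window_years)
  inst_summ <- stratified_summary(analysis_cohort, "institution", window_years)
  inst <- dplyr::left_join(prof, inst_summ,
                           by = c(institution_id = "stratum"))

  volume_assoc <- if (nrow(inst) >= 3) {
    dplyr::bind_rows(
      cbind(variable = "mortality_rate",
            spearman_rho(inst$volume, inst$mortality_rate)),
      cbind(variable = "mrruf_los",
            spearman_rho(inst$volume, inst$mrruf_los)),
      cbind(variable = "mrruf_charges",
            spearman_rho(inst$volume, inst$mrruf_charges))
    )
  } else NULL

  mrruf_year_trend <- if (nrow(by_year) >= 3) {
    yrs <- as.numeric(by_year$stratum)
    dplyr::bind_rows(
      cbind(variable = "mrruf_los", ols_trend(yrs, by_year$mrruf_los)),
      cbind(variable = "mrruf_charges", ols_trend(yrs, by_year$mrruf_charges))
    )
  } else NULL

  list(by_year = by_year, mortality_year_trend = year_trend,
       mrruf_year_trend = mrruf_year_trend, volume_association = volume_assoc,
       excluded_institutions = excluded)
}

#' @export
print.mrruf_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("MRRUF analysis: %d admissions, %d deaths (%.1f%%)\n",
              o$n_admissions, o$n_deaths, o$mortality_pct))
  cat(sprintf("  total LOS %s days; total charges $%s\n",
              format(o$los_total, big.mark = ","),
              format(round(o$charges_total), big.mark = ",")))
  cat(sprintf("  MRRUF: %.3f (LOS), %.3f (charges)\n",
              o$mrruf_los, o$mrruf_charges))
  cat("Blocks: table1_block, table2_block, trends_block\n")
  invisible(x)
}

#' Write a report to disk
#'
#' Writes the full report as JSON (numbers at machine precision) and, when
#' `tables_dir` is given, the tabular blocks as CSV files with identical
#' numbers.
#'
#' @param report an `mrruf_report`.
#' @param json_path output path for the JSON rendering.
#' @param tables_dir optional directory for CSV renderings of the tables.
#'
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, tables_dir = NULL) {
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  if (!is.null(tables_dir)) {
    if (!dir.exists(tables_dir)) dir.create(tables_dir, recursive = TRUE)
    readr::write_csv(report$table1_block$by_volume,
                     file.path(tables_dir, "table1_by_volume.csv"))
    readr::write_csv(report$table1_block$by_age,
                     file.path(tables_dir, "table1_by_age.csv"))
    readr::write_csv(report$table2_block$summary,
                     file.path(tables_dir, "table2_by_age.csv"))
    readr::write_csv(report$trends_block$by_year,
                     file.path(tables_dir, "trends_by_year.csv"))
  }
  invisible(json_path)
}
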