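# Small cohort builders for tests. random_cohort() is deliberately independent
# of generate_cohort(): a flat sampler with no calibration, used for
# property-style checks of the statistics themselves.

make_cohort <- function(institution_id = "A", year = 2005L, age_years = 0L,
                        los_days = 10L, billed_charges = 1e5, died = FALSE) {
  tibble::tibble(
    institution_id = institution_id,
    year = as.integer(year),
    age_years = as.integer(age_years),
    los_days = as.integer(los_days),
    billed_charges = billed_charges,
    died = died
  )
}

random_cohort <- function(n, n_inst = 4) {
  make_cohort(
    institution_id = sample(LETTERS[seq_len(n_inst)], n, replace = TRUE),
    year = sample(2004:2013, n, replace = TRUE),
    age_years = sample(0:21, n, replace = TRUE),
    los_days = 1L + stats::rpois(n, 10),
    billed_charges = round(stats::rlnorm(n, log(1.5e5), 1), 2),
    died = stats::runif(n) < 0.15
  )
}

write_cohort_csv <- function(cohort, path = tempfile(fileext = ".csv")) {
  mrruf::write_admissions(cohort, path)
  path
}
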