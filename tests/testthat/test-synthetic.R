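test_that("identical config and seed reproduce the identical cohort", {
  a <- generate_cohort(default_cohort_config(seed = 7))
  b <- generate_cohort(default_cohort_config(seed = 7))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$spec$realized_band_counts, b$spec$realized_band_counts)
  c <- generate_cohort(default_cohort_config(seed = 8))
  expect_false(identical(a$cohort, c$cohort))
  # the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_cohort(default_cohort_config(seed = 7)))
  expect_identical(rnorm(1), before)
})

test_that("every generated record satisfies the admission invariants", {
  co <- generate_cohort(default_cohort_config(seed = 3))$cohort
  expect_equal(attr(co, "dropped"), 0)
  expect_true(all(co$los_days >= 1))
  expect_true(all(co$billed_charges >= 0))
  expect_true(all(co$age_years >= 0 & co$age_years <= 21))
  expect_true(all(co$year >= 2004 & co$year <= 2013))
  # spot-check single records through the validator
  idx <- c(1, nrow(co) %/% 2, nrow(co))
  for (i in idx) expect_identical(validate_record(as.list(co[i, ])), character(0))
})

test_that("zero death probabilities yield zero mortality and zero MRRUF", {
  cfg <- cohort_config(death_prob_by_band = rep(0, 5), n_institutions = 5, seed = 2)
  co <- generate_cohort(cfg)$cohort
  expect_equal(mortality_rate(co), 0)
  expect_equal(mrruf(co, "los")$fraction, 0)
  expect_equal(mrruf(co, "charges")$fraction, 0)
  expect_equal(expected_statistics(cfg)$mortality_rate, 0)
})

test_that("closed-form mixture MRRUF matches hand arithmetic and symmetry", {
  # single band, p = 0.1, E[LOS | death] = 20, E[LOS | alive] = 10 -> 2/11
  expect_equal(mrruf:::mixture_mrruf(1, 0.1, 20, 10), 2 / 11)
  # equal resource distributions for both statuses at p = 0.5 -> exactly 0.5
  expect_equal(mrruf:::mixture_mrruf(rep(0.2, 5), rep(0.5, 5),
                                     rep(8, 5), rep(8, 5)), 0.5)
})

test_that("expected_statistics reflects the configured calibration", {
  es <- expected_statistics(default_cohort_config())
  expect_equal(es$mortality_rate,
               sum(default_cohort_config()$age_band_probs *
                     default_cohort_config()$death_prob_by_band))
  expect_equal(es$mortality_rate, 0.103, tolerance = 0.005)
  expect_equal(es$median_los_died, 17)
  expect_equal(es$median_los_alive, 12)
  expect_equal(es$mean_los, 24.9, tolerance = 0.01)
  expect_gt(es$mrruf_charges, es$mrruf_los)  # higher decedent per-diem
})

test_that("increasing a band death probability weakly increases expected statistics", {
  base <- default_cohort_config()
  es0 <- expected_statistics(base)
  for (g in 1:5) {
    bumped <- base
    bumped$death_prob_by_band[g] <- min(1, bumped$death_prob_by_band[g] + 0.2)
    es1 <- expected_statistics(bumped)
    expect_gte(es1$mortality_rate, es0$mortality_rate)
    expect_gte(es1$mrruf_los, es0$mrruf_los)
    expect_gte(es1$mrruf_charges, es0$mrruf_charges)
  }
})

test_that("large cohorts recover the configured statistics within 3 standard errors", {
  cfg <- default_cohort_config(seed = 101)
  cfg$n_institutions <- 200L  # ~52k admissions; distribution parameters untouched
  co <- generate_cohort(cfg)$cohort
  n <- nrow(co)
  expect_gte(n, 50000)
  es <- expected_statistics(cfg)

  p_hat <- mortality_rate(co)
  se_p <- sqrt(es$mortality_rate * (1 - es$mortality_rate) / n)
  expect_lt(abs(p_hat - es$mortality_rate), 3 * se_p)

  # ratio-estimator standard error for f = sum(d) / sum(t):
  # se ~= sd(d_i - f * t_i) / (mean(t) * sqrt(n))
  mrruf_se <- function(resource, died, f) {
    d <- ifelse(died, resource, 0)
    stats::sd(d - f * resource) / (mean(resource) * sqrt(length(resource)))
  }
  f_los <- mrruf(co, "los")$fraction
  expect_lt(abs(f_los - es$mrruf_los),
            3 * mrruf_se(as.numeric(co$los_days), co$died, es$mrruf_los))
  f_ch <- mrruf(co, "charges")$fraction
  expect_lt(abs(f_ch - es$mrruf_charges),
            3 * mrruf_se(co$billed_charges, co$died, es$mrruf_charges))
})

test_that("per-band death rates and per-year trend are realized as configured", {
  cfg <- default_cohort_config(seed = 55)
  cfg$n_institutions <- 200L
  co <- generate_cohort(cfg)$cohort
  s <- stratified_summary(co, "age_band")
  for (g in seq_len(5)) {
    p <- cfg$death_prob_by_band[s$stratum[g]]
    se <- sqrt(p * (1 - p) / s$n_admissions[g])
    expect_lt(abs(s$death_pct[g] / 100 - p), 3.5 * se)
  }
  # declining mortality across the window at the configured negative trend
  yearly <- stratified_summary(co, "year")
  fit <- ols_trend(as.numeric(yearly$stratum), yearly$death_pct)
  expect_lt(fit$slope, 0)
})

test_that("config round-trips through YAML and JSON", {
  cfg <- cohort_config(seed = 12, year_trend_log_odds = -0.08)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_config(cfg, path)
    back <- read_config(path)
    expect_equal(back[names(back) != "years"], cfg[names(cfg) != "years"],
                 tolerance = 1e-12)
    expect_equal(back$years, cfg$years)
  }
  expect_error(cohort_config(age_band_probs = c(0.5, 0.5, 0.5, 0, 0)))
})
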