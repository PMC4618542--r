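#' Configuration for the synthetic HLHS admission-cohort generator
#'
#' Builds a generator configuration. Defaults are calibrated to the published
#' marginals of the 2004-2013 PHIS HLHS cohort (see
#' [hlhs_reference_tables()]): 43 institutions averaging 259 +/- 181
#' admissions over the ten-year window; the age-band mixture of the published
#' per-age admission counts; per-band death probabilities equal to the
#' published death percentages; log-normal length of stay with
#' status-specific medians 17 days (deaths) and 12 days (survivors); and
#' charges proportional to the stay with a status-specific per-diem whose
#' medians place the charge medians at $409,000 (deaths) and $163,000
#' (survivors). The log-scale sigma of LOS (1.1556) is set so the overall mean
#' stay is about 24.9 days given the medians; the per-diem sigma (0.25)
#' supplies modest extra charge dispersion beyond what stay length induces.
#'
#' A negative per-year trend on the log-odds of death reproduces declining
#' mortality over the window; per-band intercepts are renormalized so each
#' band's window-average death probability still equals its configured rate.
#'
#' @param n_institutions number of hospitals (default 43).
#' @param years admission-year window (default `2004:2013`).
#' @param volume_mean,volume_sd,volume_min truncated-normal parameters for the
#'   per-institution total admissions over the window (defaults 259, 181, 1).
#' @param age_band_probs named 5-vector of age-band probabilities (sums to 1).
#' @param death_prob_by_band named 5-vector of per-band inpatient death
#'   probabilities.
#' @param year_trend_log_odds additive per-year effect on the log-odds of
#'   death (default -0.05, a gentle decade-long decline).
#' @param los_median_died,los_median_alive median length of stay in days by
#'   discharge status; scalars recycle across the five bands.
#' @param los_sigma log-scale standard deviation of the stay distribution.
#' @param per_diem_median_died,per_diem_median_alive median charge per
#'   inpatient-day by discharge status (defaults 409000/17 and 163000/12).
#' @param per_diem_sigma log-scale standard deviation of the per-diem.
#' @param seed integer seed; every draw in [generate_cohort()] flows from it.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_institutions = 43L,
                          years = 2004:2013,
                          volume_mean = 259,
                          volume_sd = 181,
                          volume_min = 1,
                          age_band_probs = c(`<1` = 7585, `1` = 484, `2-4` = 2422,
                                             `5-12` = 531, `>12` = 100) / 11122,
                          death_prob_by_band = c(`<1` = 0.139, `1` = 0.045,
                                                 `2-4` = 0.017, `5-12` = 0.033,
                                                 `>12` = 0.080),
                          year_trend_log_odds = -0.05,
                          los_median_died = 17,
                          los_median_alive = 12,
                          los_sigma = 1.1556,
                          per_diem_median_died = 409000 / 17,
                          per_diem_median_alive = 163000 / 12,
                          per_diem_sigma = 0.25,
                          seed = 1L) {
  bands <- age_band_defs()$label
  cfg <- list(
    n_institutions = as.integer(n_institutions),
    years = as.integer(years),
    volume_mean = volume_mean, volume_sd = volume_sd, volume_min = volume_min,
    age_band_probs = stats::setNames(rep_len(age_band_probs, 5), bands),
    death_prob_by_band = stats::setNames(rep_len(death_prob_by_band, 5), bands),
    year_trend_log_odds = year_trend_log_odds,
    los_median_died = stats::setNames(rep_len(los_median_died, 5), bands),
    los_median_alive = stats::setNames(rep_len(los_median_alive, 5), bands),
    los_sigma = los_sigma,
    per_diem_median_died = per_diem_median_died,
    per_diem_median_alive = per_diem_median_alive,
    per_diem_sigma = per_diem_sigma,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_cohort_config <- function(seed = 1L) cohort_config(seed = seed)

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_institutions >= 1,
    length(cfg$years) >= 1,
    cfg$volume_mean > 0, cfg$volume_sd >= 0, cfg$volume_min >= 1,
    abs(sum(cfg$age_band_probs) - 1) < 1e-9,
    all(cfg$age_band_probs >= 0),
    all(cfg$death_prob_by_band >= 0 & cfg$death_prob_by_band <= 1),
    all(cfg$los_median_died > 0), all(cfg$los_median_alive > 0),
    cfg$los_sigma > 0,
    cfg$per_diem_median_died > 0, cfg$per_diem_median_alive > 0,
    cfg$per_diem_sigma >= 0
  )
  invisible(cfg)
}

#' Read or write a generator configuration as YAML or JSON
#'
#' Format is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param cfg a `cohort_config`.
#' @param path file path.
#' @return `read_config()` returns a validated `cohort_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  plain <- unclass(cfg)
  plain$age_band_probs <- as.list(plain$age_band_probs)
  plain$death_prob_by_band <- as.list(plain$death_prob_by_band)
  plain$los_median_died <- as.list(plain$los_median_died)
  plain$los_median_alive <- as.list(plain$los_median_alive)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(plain, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(cohort_config, lapply(raw, function(x) {
    if (is.list(x)) unlist(x) else x
  }))
}

# Per-band logit intercepts such that the death probability averaged over the
# window equals the configured band rate despite the per-year trend.
band_intercepts <- function(cfg) {
  centered <- cfg$years - mean(cfg$years)
  vapply(cfg$death_prob_by_band, function(p) {
    if (p <= 0) return(-Inf)
    if (p >= 1) return(Inf)
    stats::uniroot(
      function(a) mean(stats::plogis(a + cfg$year_trend_log_odds * centered)) - p,
      interval = stats::qlogis(p) + c(-5, 5), tol = 1e-12
    )$root
  }, numeric(1))
}

#' Generate a synthetic admission cohort
#'
#' Hierarchical sampling: institution total volumes are drawn from a truncated
#' normal (rounded to integers, floored at `volume_min`); each admission then
#' receives a year (uniform over the window), an age band (configured mixture)
#' and a uniform integer age within the band, a death indicator (Bernoulli on
#' the band's rate with the per-year log-odds trend, renormalized so the
#' window average matches the band rate), a stay drawn log-normal and rounded
#' up to a whole number of days, and charges equal to the un-rounded stay
#' duration times a log-normal per-diem -- so the charge distribution is
#' exactly log-normal with median = LOS median x per-diem median, while
#' remaining coupled to stay length. Charges are rounded to cents. The same
#' configuration and seed always reproduce the identical cohort; the caller's
#' RNG state is left untouched.
#'
#' @param config a `cohort_config`.
#' @param seed optional override of `config$seed`.
#'
#' @return A list with elements `cohort` (a cohort tibble) and `spec`
#'   (generation metadata: the configuration, the seed, and realized
#'   admission counts per age band).
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  # seed the stream for this generation only; restore the caller's RNG state
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n_inst <- config$n_institutions
  vols <- integer(n_inst)
  for (i in seq_len(n_inst)) {
    repeat {
      v <- round(stats::rnorm(1, config$volume_mean, config$volume_sd))
      if (v >= config$volume_min) break
    }
    vols[i] <- v
  }
  inst_ids <- sprintf("H%03d", seq_len(n_inst))
  n <- sum(vols)

  bands <- age_band_defs()
  band_idx <- sample.int(5, n, replace = TRUE, prob = config$age_band_probs)
  age <- bands$lower[band_idx] +
    floor(stats::runif(n) * (bands$upper[band_idx] - bands$lower[band_idx] + 1))
  year <- sample(config$years, n, replace = TRUE)

  alpha <- band_intercepts(config)
  p_death <- stats::plogis(alpha[band_idx] +
                             config$year_trend_log_odds * (year - mean(config$years)))
  p_death[config$death_prob_by_band[band_idx] == 0] <- 0
  died <- stats::runif(n) < p_death

  med_los <- ifelse(died, config$los_median_died[band_idx],
                    config$los_median_alive[band_idx])
  los_cont <- stats::rlnorm(n, meanlog = log(med_los), sdlog = config$los_sigma)
  los_days <- as.integer(ceiling(los_cont))

  med_pd <- ifelse(died, config$per_diem_median_died, config$per_diem_median_alive)
  per_diem <- stats::rlnorm(n, meanlog = log(med_pd), sdlog = config$per_diem_sigma)
  charges <- round(los_cont * per_diem, 2)

  cohort <- tibble::tibble(
    institution_id = rep(inst_ids, times = vols),
    year = as.integer(year),
    age_years = as.integer(age),
    los_days = los_days,
    billed_charges = charges,
    died = died
  )
  cohort <- as_cohort(cohort, provenance = sprintf("synthetic (seed %d)", config$seed),
                      year_range = range(config$years))
  realized <- table(factor(bands$label[band_idx], levels = bands$label))
  list(
    cohort = cohort,
    spec = list(config = config, seed = config$seed,
                n_admissions = n,
                realized_band_counts = stats::setNames(as.integer(realized),
                                                       names(realized)))
  )
}

# Expected value of ceiling(X) for X ~ lognormal(log(median), sigma):
# sum over k >= 0 of P(X > k), truncated where the tail is negligible.
expected_ceiling_lognormal <- function(median, sigma) {
  kmax <- ceiling(stats::qlnorm(1 - 1e-12, log(median), sigma))
  k <- 0:kmax
  sum(1 - stats::plnorm(k, log(median), sigma))
}

# Mixture MRRUF from band weights, band death probabilities and band-by-status
# mean resources: sum_g pi_g p_g m_dead_g / sum_g pi_g (p_g m_dead_g +
# (1 - p_g) m_alive_g).
mixture_mrruf <- function(band_probs, death_probs, mean_dead, mean_alive) {
  num <- sum(band_probs * death_probs * mean_dead)
  den <- sum(band_probs * (death_probs * mean_dead +
                             (1 - death_probs) * mean_alive))
  if (den > 0) num / den else NA_real_
}

#' Closed-form statistics implied by a generator configuration
#'
#' The analytic counterparts of what [generate_cohort()] realizes by
#' simulation, for use as an oracle in parameter-recovery checks:
#' the mixture mortality rate \eqn{\sum_g \pi_g p_g}; LOS- and charge-domain
#' MRRUF as decedent expected resource over total expected resource, using the
#' log-normal mean (median x exp(sigma^2/2)) -- with the day count's mean
#' computed exactly for the rounded-up integer stay -- and the population
#' median stay by discharge status (solved from the band-mixture CDF of the
#' integer stay).
#'
#' @param config a `cohort_config`.
#'
#' @return A list: `mortality_rate`, `mrruf_los`, `mrruf_charges`,
#'   `median_los_died`, `median_los_alive`, `mean_los`.
#' @export
expected_statistics <- function(config = default_cohort_config()) {
  validate_config(config)
  pi_g <- config$age_band_probs
  p_g <- config$death_prob_by_band
  mortality <- sum(pi_g * p_g)

  e_los_d <- vapply(config$los_median_died, expected_ceiling_lognormal,
                    numeric(1), sigma = config$los_sigma)
  e_los_a <- vapply(config$los_median_alive, expected_ceiling_lognormal,
                    numeric(1), sigma = config$los_sigma)
  mrruf_los <- mixture_mrruf(pi_g, p_g, e_los_d, e_los_a)

  charge_factor <- exp((config$los_sigma^2 + config$per_diem_sigma^2) / 2)
  e_ch_d <- config$los_median_died * config$per_diem_median_died * charge_factor
  e_ch_a <- config$los_median_alive * config$per_diem_median_alive * charge_factor
  mrruf_charges <- mixture_mrruf(pi_g, p_g, e_ch_d, e_ch_a)

  list(
    mortality_rate = mortality,
    mrruf_los = mrruf_los,
    mrruf_charges = mrruf_charges,
    median_los_died = mixture_int_los_median(config$los_median_died,
                                             config$los_sigma, pi_g * p_g),
    median_los_alive = mixture_int_los_median(config$los_median_alive,
                                              config$los_sigma, pi_g * (1 - p_g)),
    mean_los = sum(pi_g * (p_g * e_los_d + (1 - p_g) * e_los_a))
  )
}

# Median of the integer (rounded-up) stay under a band mixture with weights w:
# smallest integer m with P(ceil(X) <= m) >= 0.5, i.e. mixture CDF at m >= 0.5.
mixture_int_los_median <- function(medians, sigma, w) {
  if (sum(w) <= 0) return(NA_real_)
  w <- w / sum(w)
  cdf <- function(m) sum(w * stats::plnorm(m, log(medians), sigma))
  m <- 1
  while (cdf(m) < 0.5 - 1e-9) m <- m + 1
  m
}
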