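---
title: "Methods: the mortality-related resource utilization fraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mortality-related resource utilization fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrruf)
```

## The statistic

For a cohort of hospital admissions, let $r_i$ be the resource expended
during admission $i$ — inpatient-days or billed dollars — and $d_i \in
\{0,1\}$ indicate inpatient death. The mortality-related resource utilization
fraction is

$$\mathrm{MRRUF} \;=\; \frac{\sum_i d_i\, r_i}{\sum_i r_i}.$$

It is a ratio of totals, not a mean of per-admission ratios, which gives it
two properties this package leans on throughout:

* **Scale equivariance.** Multiplying all charges by a constant (inflation,
  charge-to-cost factors) leaves the charge-domain MRRUF unchanged.
* **Exact pooling.** For any partition of the cohort into strata $g$ with
  fractions $f_g$ and resource totals $T_g$,
  $\mathrm{MRRUF} = \sum_g f_g T_g \,/\, \sum_g T_g$. The identity is
  algebraic, so `pooled_mrruf_from_strata()` recovers a whole-population
  fraction *exactly* from a stratified table — this is how the package
  reconstructs whole-cohort values from published per-age-band rows, and it
  is property-tested to $10^{-12}$ on random cohorts and random partitions.

A zero denominator (empty cohort, or a stratum whose members accrued none of
the resource) makes the fraction *undefined*, represented as `NA` and
propagated as such through reports. Representing it as 0 would falsely assert
"decedents accrued nothing".

MRRUF is not a cost measure: it cannot enter a cost-benefit calculus, and a
low institutional value is not by itself evidence of good care (it may
reflect low mortality, efficient care of hopeless cases, or reluctance to
attempt rescue). The package computes; interpretation stays with the analyst.

## Data model and conventions

One row per hospitalization: institution, admission year, age in completed
years (0–21), length of stay in whole days ($\ge 1$), billed charges in
dollars ($\ge 0$, stored to cent precision), and a death flag parsed from a
discharge-status vocabulary (`died`/`dead`/`inpatient_death`/`1`/`true` vs
`alive`/`discharged`/`0`/`false`, case-insensitive; anything else is
invalid). Analysis is strictly admission-level: readmissions of the same
child are independent rows, and transfers are not linked.

Two conventions are deliberately explicit because the field's sources are
ambiguous about them:

* **Length-of-stay counting.** No admission-day/discharge-day convention is
  assumed beyond "a whole number of days, at least 1". The synthetic
  generator realizes this as the ceiling of a continuous stay duration, so a
  same-day discharge counts as one inpatient-day.
* **Age bands.** The five-band partition is $\{0\}, \{1\}, \{2\!-\!4\},
  \{5\!-\!12\}, \{13\!-\!21\}$, the convention of the published stratified
  tables for this cohort (an alternative `5-13`/`14-21` split circulates in
  methods prose). Band definitions are a plain data-frame argument to
  `age_band()`, so the alternative is a drop-in replacement, and definitions
  round-trip through YAML/JSON.

**Hospital volume** has two faces, both implemented: volume *strata*
(`<100` … `>=500`) partition institutions by their *total* admission count
over the study window, while the *continuous* volume variable used in
correlations is total/window-length (admissions per year). The low-volume
exclusion filter (`exclude_nonrepresentative()`) removes institutions below a
volume threshold with zero deaths — default 1 admission/year, explicit and
auditable because published analyses describe such exclusions without
printing the cutoff. By default the exclusion applies only to the trend and
correlation analyses, not the descriptive totals, so every report block
conserves to the overall cohort.

## Inferential toolkit

* **Chi-square homogeneity** (`chi_square_homogeneity()`): Pearson statistic
  on a groups × (died, survived) table, no continuity correction anywhere in
  the package, df = rows − 1. On a 2×2 table it equals the squared
  two-proportion z statistic (tested numerically).
* **Pairwise reference comparisons** (`pairwise_vs_reference()`): one 2×2
  test per band against a reference (default `<1`), Bonferroni-corrected
  ($p_{adj} = \min(1, kp)$) by default — conservative and auditable where the
  correction used by a source is unnamed — selectable to `"none"`;
  significance flagged at 0.05 on the corrected value.
* **Mann-Whitney U** (`mann_whitney_u()`): midranks for ties; $U = W_x -
  n_x(n_x+1)/2$. For $n_x n_y \le 400$ (the default switch point) the
  two-sided p is computed from the *exact permutation distribution of the
  rank sum*, valid under ties where tabulated null distributions are not,
  via a subset-sum dynamic program on doubled midranks (doubling makes
  midranks integers; subset counts stay below $2^{53}$ in this regime, so
  double-precision counting is exact). Two-sided p is
  $P(|W - EW| \ge |w_{obs} - EW|)$. Above the switch point, a normal
  approximation with tie-corrected variance is used; the two agree within
  0.02 near the boundary (property-tested), and on tie-free samples the
  exact path reproduces `wilcox.test(exact = TRUE)` to machine precision.
* **Spearman correlation** (`spearman_rho()`): Pearson correlation of
  midranks; exact permutation p by full enumeration for $n \le 8$ ($8! =
  40{,}320$ permutations), t approximation otherwise; constant input yields
  an undefined (`NA`) rho.
* **Trend** (`ols_trend()`): simple least squares with
  $r^2_{adj} = 1 - (1-r^2)(n-1)/(n-2)$ and a t-based slope test.

Units of analysis for the observational claims are configurable surfaces of
`build_report()`: calendar trends use institution-year mortality rates;
volume correlations use per-institution volume, mortality and MRRUF; age-band
MRRUF comparisons use per-institution band MRRUFs as the Mann-Whitney
observations (institutions contributing no admissions, or a zero resource
total, in a band are dropped from that comparison). These are the only units
that make the published analyses computable from admission-level data, and
each is stated in the report metadata.

## The synthetic cohort generator

The PHIS source data are proprietary, so the package ships a seeded
generator (`generate_cohort()`) whose defaults are calibrated once to the
published marginals of the 2004–2013 HLHS cohort, and are not tuned further:

| parameter | default | calibration target |
|---|---|---|
| institutions | 43 | published hospital count |
| total admissions per institution | truncated normal, mean 259, sd 181, min 1, rounded | published mean ± sd |
| age-band mixture | (7585, 484, 2422, 531, 100)/11122 | published per-age admission counts |
| death probability per band | 0.139, 0.045, 0.017, 0.033, 0.080 | published per-age death percentages |
| year trend on death log-odds | −0.05 per year | direction and rough magnitude of the published decade-long mortality decline; per-band intercepts renormalized (by root-finding on the window mean) so each band's window-average rate still equals its configured value |
| stay distribution | log-normal, median 17 d (deaths) / 12 d (survivors), $\sigma = 1.1556$, rounded up to whole days | published status-specific medians; $\sigma$ solved so the overall mean stay is ≈ 24.9 d given the medians, the 10.3% mixture mortality and the +0.5-day ceiling effect |
| per-diem charges | log-normal, median 409000/17 $/d (deaths), 163000/12 (survivors), $\sigma = 0.25$ | status-specific charge medians of $409{,}000 and $163{,}000 |

Charges are generated as the *un-rounded* continuous stay duration × a
per-diem draw, then rounded to cents. Multiplying before rounding keeps the
charge distribution exactly log-normal with median = stay median × per-diem
median, so the configured charge medians are hit exactly while charges remain
coupled to stay length; the higher decedent per-diem makes the charge-domain
MRRUF exceed the LOS-domain MRRUF, reproducing the published ordering
structurally rather than by accident. The log-normal family is the minimal
right-skewed choice consistent with the published median-far-below-mean
pattern; with only two parameters per status it cannot also match the
published interquartile ranges exactly (it lands near them), and medians are
prioritized. The published overall mean charge is likewise slightly
over-determined; the generator's value runs a few percent high, a known and
accepted consequence of matching medians.

`expected_statistics()` is the generator's analytic oracle: mixture mortality
$\sum_g \pi_g p_g$; each MRRUF as decedent expected resource over total
expected resource with the log-normal mean $m\,e^{\sigma^2/2}$ — for the day
count using the *exact* mean of the rounded-up stay, $E[\lceil X\rceil] =
\sum_{k\ge0} P(X > k)$, rather than the continuous mean, so parameter
recovery is unbiased; and the status-specific median of the integer stay from
the band-mixture CDF. The headline property test generates ≥ 50,000
admissions (the default configuration with the institution count scaled to
200 — a run-size choice; all distributional parameters untouched) and
requires empirical mortality and both MRRUFs to land within 3 standard errors
of the oracle, with the MRRUF standard error from the ratio-estimator
(influence-function) formula
$\widehat{se} = sd(d_i r_i - f r_i) / (\bar r \sqrt n)$.

What the generator does *not* emulate: readmission correlation within
patients, transfers, surgical-stage structure, case-mix differences between
institutions (all institutions share the same band mixture and rates, so
volume-MRRUF correlations are null by construction — which is what the
structural tests assert), seasonal effects, and any within-year charge
inflation. Passing tests therefore demonstrate that the *pipeline* computes
the intended quantities under realistic marginals, not that real PHIS data
would yield these values; published regression/correlation point estimates
(e.g. an adjusted $r^2$ or a specific Spearman rho against volume) are not
reproducible without the raw data and are checked only for structural
direction.

## Numerical choices and degenerate inputs

* Pooling identity asserted to $10^{-12}$ (floating-point tolerance only;
  the identity is exact).
* Undefined statistics (`NA`): MRRUF with zero denominator, mortality of an
  empty cohort, Spearman rho of constant input. Errors instead of `NA`:
  chi-square with a zero row/column margin, OLS on constant $x$, empty
  Mann-Whitney samples — these indicate malformed analyses, not data.
* Exact Mann-Whitney two-sided mass comparisons use a $10^{-9}$ slack on the
  doubled-rank scale when deciding "at least as extreme", so midrank
  arithmetic never drops a tied configuration.
* Percentages are displayed to one decimal and fractions to three in printed
  summaries; machine-precision values are always retained in the report
  objects and JSON (CSV and JSON renderings carry identical numbers).
* The generator rounds charges to cents so the CSV round trip
  (`write_admissions()` then `read_admissions()`) is the identity,
  property-tested on random cohorts.

## Known limitations

Inpatient death is the sole adverse outcome: deaths after discharge and
severe non-fatal morbidity are invisible, so the MRRUF understates resource
investment in poor outcomes generally. Billed charges are not costs. The
admission-level design counts a patient once per hospitalization, inflating
denominators for frequently readmitted children. The reference summaries
embedded in `hlhs_reference_tables()` carry one internal inconsistency of
their published source — the `5-12` band's printed death percentage (3.3)
disagrees with its own counts (18/531 → 3.4) — recorded as printed and
excluded from consistency checks.
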