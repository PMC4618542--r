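#' Chi-square test of homogeneity of mortality across groups
#'
#' Pearson chi-square on a groups x {died, survived} count table, without
#' continuity correction, df = rows - 1.
#'
#' @param table numeric matrix with one row per group and two columns (deaths,
#'   survivors). Row names label the groups.
#'
#' @return A tibble (one row) with `test_name`, `statistic`, `df`, `p_value`,
#'   `n`, `method_notes`.
#' @export
#'
#' @examples
#' chi_square_homogeneity(rbind(a = c(10, 90), b = c(30, 70)))  # X2 = 12.5
chi_square_homogeneity <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) != 2) stop("table must have two columns (died, survived)", call. = FALSE)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("every row and column total must be positive", call. = FALSE)
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  tibble::tibble(
    test_name = "chi_square_homogeneity",
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value),
    n = sum(table),
    method_notes = "Pearson, no continuity correction"
  )
}

#' Pairwise mortality comparisons against a reference group
#'
#' One 2x2 chi-square (no continuity correction) per non-reference group
#' against the reference, with optional Bonferroni correction across the
#' comparisons (`p_adj = min(1, p * k)`); significance flagged at 0.05 on the
#' corrected p-value.
#'
#' @param table counts matrix as in [chi_square_homogeneity()], with row names.
#' @param reference row name of the reference group.
#' @param correction `"bonferroni"` (default) or `"none"`.
#'
#' @return Tibble with one row per comparison: `group`, `reference`,
#'   `statistic`, `p_value` (raw), `p_adjusted`, `significant`, `n`,
#'   `method_notes`.
#' @export
pairwise_vs_reference <- function(table, reference,
                                  correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  table <- as.matrix(table)
  groups <- rownames(table)
  if (is.null(groups) || !(reference %in% groups)) {
    stop("reference group not found in table row names", call. = FALSE)
  }
  if (nrow(table) < 2) stop("need at least two groups", call. = FALSE)
  others <- setdiff(groups, reference)
  k <- length(others)
  rows <- lapply(others, function(g) {
    sub <- table[c(reference, g), , drop = FALSE]
    res <- chi_square_homogeneity(sub)
    p_adj <- if (correction == "bonferroni") min(1, res$p_value * k) else res$p_value
    tibble::tibble(
      group = g, reference = reference, statistic = res$statistic,
      p_value = res$p_value, p_adjusted = p_adj,
      significant = p_adj < 0.05, n = res$n,
      method_notes = paste0("2x2 chi-square vs reference; correction=", correction)
    )
  })
  dplyr::bind_rows(rows)
}

#' Mann-Whitney U test with tie-aware exact p-values
#'
#' Two-sided Mann-Whitney U test using midranks for ties. The U statistic is
#' the rank-sum form \eqn{U = W_x - n_x(n_x+1)/2}. For small samples
#' (`n_x * n_y <= exact_limit`, mode `"auto"` or `"exact"`) the p-value is
#' computed from the exact permutation distribution of the rank sum over all
#' \eqn{\binom{n_x+n_y}{n_x}} group labelings -- valid in the presence of ties,
#' where tabulated null distributions are not -- via a subset-sum dynamic
#' program on doubled midranks. Otherwise a normal approximation with
#' tie-corrected variance is used, with no continuity correction. Two-sided p
#' is \eqn{P(|W - E W| \ge |w_{obs} - E W|)} under permutation.
#'
#' @param x,y numeric samples (both non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @param exact_limit largest `n_x * n_y` for which `"auto"` picks the exact
#'   distribution (default 400).
#'
#' @return Tibble with `test_name`, `statistic` (U for `x`), `p_value`,
#'   `n_x`, `n_y`, `method_notes`.
#' @export
#'
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal"),
                           exact_limit = 400) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))  # midranks
  wx <- sum(r[seq_len(nx)])
  u <- wx - nx * (nx + 1) / 2
  use_exact <- mode == "exact" || (mode == "auto" && nx * ny <= exact_limit)
  if (use_exact) {
    p <- mw_exact_p(r, nx)
    notes <- "exact permutation distribution of rank sum (midranks)"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    notes <- "normal approximation, tie-corrected variance, no continuity correction"
  }
  tibble::tibble(
    test_name = "mann_whitney_u", statistic = u, p_value = min(1, p),
    n_x = nx, n_y = ny, method_notes = notes
  )
}

# Exact two-sided permutation p for the rank sum of the first nx midranks.
# Works on doubled midranks (integers); dp[k, s] counts size-k subsets of the
# pooled ranks with doubled-rank sum s. Subset counts stay below 2^53 for the
# sample sizes where this is invoked, so double arithmetic is exact.
mw_exact_p <- function(r, nx) {
  r2 <- as.integer(round(2 * r))
  n <- length(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
  # dp[k + 1, s + 1]: number of k-subsets with doubled-rank sum s
  dp <- matrix(0, nrow = nx + 1, ncol = smax + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    kmax <- nx
    for (k in kmax:1) {
      cols <- (v + 1):(smax + 1)
      dp[k + 1, cols] <- dp[k + 1, cols] + dp[k, cols - v]
    }
  }
  counts <- dp[nx + 1, ]
  total <- sum(counts)
  sums <- 0:smax
  ew <- nx * mean(r2)
  obs <- sum(r2[seq_len(nx)])
  dev <- abs(obs - ew)
  extreme <- abs(sums - ew) >= dev - 1e-9
  sum(counts[extreme]) / total
}

#' Spearman rank correlation with midranks
#'
#' Pearson correlation of midranks. For `n <= 8` the two-sided p-value is
#' exact, by enumerating all permutations of one variable's ranks; otherwise
#' it uses the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on
#' `n - 2` degrees of freedom. Constant input yields an `NA` rho (undefined).
#'
#' @param x,y paired numeric samples, `n >= 3`.
#'
#' @return Tibble with `test_name`, `statistic` (rho), `p_value`, `n`,
#'   `method_notes`.
#' @export
#'
#' @examples
#' spearman_rho(c(1, 2, 3), c(3, 1, 2))  # rho = -0.5
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(tibble::tibble(test_name = "spearman_rho", statistic = NA_real_,
                          p_value = NA_real_, n = n,
                          method_notes = "undefined: constant input"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    notes <- "midranks; exact permutation p"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    notes <- "midranks; t approximation"
  }
  tibble::tibble(test_name = "spearman_rho", statistic = rho, p_value = p,
                 n = n, method_notes = notes)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Simple least-squares trend with adjusted r-squared
#'
#' Ordinary least squares of `y` on `x`, reporting the slope test
#' (t-distribution) and \eqn{r^2_{adj} = 1 - (1 - r^2)(n-1)/(n-2)}.
#'
#' @param x numeric predictor (not constant), `n >= 3`.
#' @param y numeric response, paired with `x`.
#'
#' @return Tibble with `slope`, `intercept`, `r_squared`,
#'   `adjusted_r_squared`, `p_value`, `n`.
#' @export
ols_trend <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    adjusted_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
    p_value = unname(sm$coefficients[2, 4]),
    n = n
  )
}
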