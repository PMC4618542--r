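test_that("chi-square homogeneity matches hand computation and degenerate cases", {
  res <- chi_square_homogeneity(rbind(a = c(10, 90), b = c(30, 70)))
  expect_equal(res$statistic, 12.5)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, stats::pchisq(12.5, 1, lower.tail = FALSE))

  same <- chi_square_homogeneity(rbind(a = c(10, 90), b = c(10, 90)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(chi_square_homogeneity(rbind(c(0, 0), c(1, 1))), "positive")
})

test_that("2x2 chi-square equals the squared two-proportion z statistic", {
  set.seed(5)
  for (i in 1:15) {
    d <- rbinom(2, 200, runif(2, 0.05, 0.5)); s <- 200 - d
    tab <- cbind(died = d, survived = s)
    rownames(tab) <- c("g1", "g2")
    p1 <- d[1] / 200; p2 <- d[2] / 200; pp <- sum(d) / 400
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 200 + 1 / 200))
    expect_equal(chi_square_homogeneity(tab)$statistic, z^2, tolerance = 1e-10)
  }
})

test_that("pairwise reference comparisons apply Bonferroni and flag at 0.05", {
  tab <- rbind(`<1` = c(100, 900), a = c(100, 900), b = c(100, 900))
  res <- pairwise_vs_reference(tab, "<1")
  expect_equal(res$p_adjusted, c(1, 1))
  expect_false(any(res$significant))

  # corrected p = min(1, raw p * number of comparisons)
  tab2 <- rbind(`<1` = c(139, 861), g1 = c(100, 900), g2 = c(80, 920))
  res2 <- pairwise_vs_reference(tab2, "<1", correction = "bonferroni")
  raw <- pairwise_vs_reference(tab2, "<1", correction = "none")
  expect_equal(res2$p_adjusted, pmin(1, raw$p_value * 2))
  expect_error(pairwise_vs_reference(tab2, "zz"), "reference")
})

test_that("Mann-Whitney U statistic and exact p match enumeration", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 6)

  same <- mann_whitney_u(c(5, 1, 3), c(3, 1, 5))
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  set.seed(13)
  for (i in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    # integer draws force ties; oracle and DP must agree exactly
    x <- sample(1:6, nx, replace = TRUE)
    y <- sample(1:6, ny, replace = TRUE)
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                 mw_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney agrees with wilcox.test on tie-free samples", {
  set.seed(21)
  x <- rnorm(8); y <- rnorm(9) + 0.5
  ours <- mann_whitney_u(x, y, mode = "exact")
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  big_x <- rnorm(40); big_y <- rnorm(45) + 0.3
  ours_n <- mann_whitney_u(big_x, big_y, mode = "normal")
  ref_n <- stats::wilcox.test(big_x, big_y, exact = FALSE, correct = FALSE)
  expect_equal(ours_n$p_value, ref_n$p.value, tolerance = 1e-10)
})

test_that("exact and normal p-values agree near the mode-switch boundary", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20) + runif(1, -1, 1)  # n_x * n_y = 400
    pe <- mann_whitney_u(x, y, mode = "exact")$p_value
    pn <- mann_whitney_u(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("Mann-Whitney is invariant to monotone transformation and order", {
  set.seed(8)
  x <- rlnorm(10); y <- rlnorm(12, 0.4)
  base <- mann_whitney_u(x, y)
  expect_equal(mann_whitney_u(log(x), log(y)), base)
  expect_equal(mann_whitney_u(sample(x), sample(y))$p_value, base$p_value)
  expect_error(mann_whitney_u(numeric(0), y), "non-empty")
})

test_that("Spearman rho matches the classical formula and handles ties by midranks", {
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2))$statistic, -0.5)
  inc <- spearman_rho(1:6, exp(1:6))
  expect_equal(inc$statistic, 1)

  # tie case: must equal Pearson on midranks (oracle by direct computation)
  x <- c(1, 2, 2, 4); y <- c(10, 30, 20, 40)
  expect_equal(spearman_rho(x, y)$statistic,
               stats::cor(rank(x), rank(y)))

  const <- spearman_rho(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(const$statistic))
})

test_that("Spearman p: exact permutation at small n, t approximation otherwise", {
  # n = 3, rho = -0.5: the 6 permutations give rho in {1, .5, .5, -.5, -.5, -1},
  # so all are at least as extreme as the observed |rho| and p = 1
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2))$p_value, 1)
  # n = 4, y reversed: only the two perfect orderings reach |rho| = 1
  expect_equal(spearman_rho(1:4, 4:1)$p_value, 2 / 24)
  set.seed(4)
  x <- rnorm(7); y <- rnorm(7)
  ours <- spearman_rho(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(ours$statistic, unname(ref$estimate), tolerance = 1e-12)

  x2 <- rnorm(30); y2 <- x2 + rnorm(30)
  ours2 <- spearman_rho(x2, y2)
  rho <- cor(rank(x2), rank(y2))
  tstat <- rho * sqrt(28 / (1 - rho^2))
  expect_equal(ours2$p_value, 2 * pt(-abs(tstat), 28))
  # monotone-transformation invariance
  expect_equal(spearman_rho(exp(x2), y2^3 - 100)$statistic, ours2$statistic)
})

test_that("ols_trend reproduces lm and the adjusted r-squared formula", {
  fit <- ols_trend(c(0, 1, 2), c(0, 1, 0))
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)

  perfect <- suppressWarnings(ols_trend(1:5, 2 * (1:5) + 3))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$adjusted_r_squared, 1)

  set.seed(9)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  ours <- ols_trend(x, y)
  sm <- summary(lm(y ~ x))
  expect_equal(ours$adjusted_r_squared, sm$adj.r.squared)
  expect_equal(ours$p_value, sm$coefficients[2, 4])
  expect_error(ols_trend(rep(1, 5), rnorm(5)), "constant")
})
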