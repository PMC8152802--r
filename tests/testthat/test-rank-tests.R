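test_that("small-sample Wilcoxon p equals exhaustive enumeration", {
  # 2+2 extreme case: only 1 of the 6 labelings is as extreme
  r <- wilcoxon_one_tailed(c(3, 4), c(1, 2))
  expect_equal(r$p_value, 1 / 6)
  expect_true(r$exact)
  expect_equal(r$statistic, 4)

  # independent oracle: stats::wilcox.test exact branch (no ties, n < 50)
  set.seed(21)
  for (i in 1:10) {
    x <- sample(1:100, 5)
    y <- sample(101:200, 6) / 2
    mine <- wilcoxon_one_tailed(x, y, "greater")
    ref <- stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups give a symmetric, null Wilcoxon result", {
  x <- c(1, 2, 3, 4, 5)
  r <- wilcoxon_one_tailed(x, x)
  expect_equal(r$effect_pct, 0)
  expect_gt(r$p_value, 0.4)
  expect_lt(r$p_value, 0.75)
  # fully tied data are degenerate, p = 1
  d <- wilcoxon_one_tailed(rep(2, 3), rep(2, 4))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
})

test_that("exact and approximate Wilcoxon branches agree near the cut-over", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(6, 1)
    y <- rnorm(6)
    pooled <- c(x, y)
    exact <- wilcoxon_one_tailed(x, y)$p_value
    # same data pushed through the large-sample branch by inflating both
    # groups is not possible without changing the data, so compare against
    # the normal approximation computed directly
    r <- rank(pooled)
    w <- sum(r[1:6]) - 6 * 7 / 2
    mu <- 18
    sigma <- sqrt(6 * 6 / 12 * 13)
    approx <- pnorm((w - mu) / sigma, lower.tail = FALSE)
    expect_lt(abs(exact - approx), 0.06)
  }
})

test_that("group-contrast Wilcoxon detects the late-season width shift", {
  set.seed(8)
  d <- rnorm(500, 183, 6)   # diapausing-group widths
  nd <- rnorm(500, 176, 7)  # non-diapausing-group widths
  r <- wilcoxon_one_tailed(d, nd, "greater")
  expect_lt(r$p_value, 1e-10)
  expect_gt(r$effect_pct, 3)
  expect_lt(r$effect_pct, 5)
  expect_false(r$exact)
  # large-sample branch tracks the tie-corrected normal approximation of
  # the reference implementation
  ref <- stats::wilcox.test(d, nd, alternative = "greater",
                            exact = FALSE, correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(log(r$p_value), log(ref$p.value), tolerance = 1e-6)
})

test_that("Kruskal-Wallis matches its defining formula and the reference", {
  # identical groups carry no rank signal
  expect_equal(kruskal_wallis(list(1:5, 1:5))$statistic, 0, tolerance = 1e-12)

  set.seed(13)
  for (i in 1:10) {
    groups <- list(rnorm(7), rnorm(5, 0.5), round(rnorm(6), 1))
    mine <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(groups)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
  expect_error(kruskal_wallis(list(1:3)), "at least two")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis holds its nominal type-I error", {
  set.seed(17)
  reps <- 1000
  rejections <- 0
  for (i in seq_len(reps)) {
    groups <- list(rnorm(10), rnorm(10), rnorm(10))
    if (kruskal_wallis(groups)$p_value < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / reps
  # binomial 99.7% band around 0.05 at 1000 reps
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("Spearman correlation matches the exact rank formula and reference", {
  x <- c(3, 1, 4, 1.5, 9)
  y <- c(2, 0.5, 7, 1, 8)
  r <- spearman(x, y)
  d <- rank(x) - rank(y)
  expect_equal(r$rho, 1 - 6 * sum(d^2) / (5 * 24), tolerance = 1e-12)

  expect_equal(spearman(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman(1:8, -(1:8)^3)$rho, -1)

  # monotone-transform invariance
  set.seed(2)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(spearman(a, b)$rho, spearman(exp(a), b)$rho)
  expect_equal(spearman(a, b)$rho, spearman(a, b^3 + b)$rho)

  # t-approximation branch: rho agrees with the reference implementation
  bb <- a + rnorm(15, 0, 0.8)
  big <- spearman(a, bb)
  ref <- suppressWarnings(stats::cor.test(a, bb, method = "spearman"))
  expect_equal(big$rho, unname(ref$estimate), tolerance = 1e-12)
  tref <- big$rho * sqrt((big$n - 2) / (1 - big$rho^2))
  expect_equal(big$p_value, 2 * pt(-abs(tref), big$n - 2))

  # exact permutation p for short series against full enumeration built here
  xs <- c(1, 2, 3, 4, 5)
  ys <- c(2, 1, 5, 3, 4)
  rp <- spearman(xs, ys)
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  rho_all <- apply(perms, 1, function(p) stats::cor(rank(xs), rank(ys[unlist(p)])))
  expect_equal(rp$p_value, mean(abs(rho_all) >= abs(rp$rho) - 1e-12))

  expect_error(spearman(1:5, rep(3, 5)), "zero variance")
  expect_error(spearman(1:2, 1:2), "at least 3")
})
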