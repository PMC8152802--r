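# simulate a per-egg design directly from known logistic coefficients
simulate_design <- function(n, b0, b1, b2, b3, years = c(2019, 2020)) {
  week <- sample(26:43, n, replace = TRUE)
  width <- rnorm(n, 177, 7)
  eta <- b0 + b1 * week + b2 * width + b3 * week * width
  tibble::tibble(
    y = rbinom(n, 1, plogis(eta)),
    x1 = week,
    x2 = width,
    year = factor(sample(years, n, replace = TRUE)),
    x1x2 = week * width
  )
}

test_that("the design keeps only viable eggs with morphometry", {
  eggs <- dplyr::bind_rows(
    with_morph(eggs_from_counts(2019, 30, H = 4, E = 2), 616, 177),
    eggs_from_counts(2019, 30, H = 1, P = 2, U = 1) # no morphometry
  )
  d <- build_design(eggs)
  expect_equal(nrow(d), 6L)
  expect_equal(sum(d$y), 2L)
  expect_equal(attr(d, "n_with_morph"), 6L)
  expect_error(
    build_design(eggs_from_counts(2019, 30, P = 3, U = 2)),
    "no viable eggs"
  )
  # generator bookkeeping: row count equals viable-with-morphometry count
  sim <- simulate_season(small_sim_config(seed = 2))
  d2 <- build_design(sim$eggs)
  viable_morph <- sum(sim$eggs$status %in% c("HATCHED", "EMBRYONATED_UNHATCHED") &
                        !is.na(sim$eggs$width_rep1_um))
  expect_equal(nrow(d2), viable_morph)
})

test_that("intercept-only fits match the closed-form logit", {
  d <- tibble::tibble(y = rep(c(0L, 1L), each = 25), x1 = 1, x2 = 1,
                      year = factor(2019), x1x2 = 1)
  f <- fit_logistic(d, terms = character(0))
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
  d2 <- tibble::tibble(y = rep(c(1L, 0L), times = c(10, 30)), x1 = 1, x2 = 1,
                       year = factor(2019), x1x2 = 1)
  f2 <- fit_logistic(d2, terms = character(0))
  expect_equal(unname(f2$coefficients), log(1 / 3), tolerance = 1e-8)
})

test_that("IRLS solves the score equations and matches a reference fit", {
  set.seed(4)
  d <- simulate_design(800, b0 = -30, b1 = 0.5, b2 = 0.07, b3 = 0)
  f <- fit_logistic(d, terms = c("x1", "x2"))
  expect_true(f$converged)
  # score equations: sum (y - p) x = 0 for every design column
  X <- cbind(1, d$x1, d$x2)
  resid <- d$y - f$fitted
  expect_true(all(abs(crossprod(X, resid)) < 1e-6))
  # AIC identity, exact
  expect_identical(f$aic, 2 * f$k - 2 * f$log_lik)
  # reference oracle: stats::glm on the same data
  ref <- stats::glm(y ~ x1 + x2, binomial(), data = d)
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(f$log_lik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_equal(f$aic, ref$aic, tolerance = 1e-6)
  expect_equal(unname(f$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
  # direct likelihood maximisation agrees with IRLS on a small,
  # well-conditioned instance
  set.seed(44)
  ds <- tibble::tibble(
    x1 = runif(60, -2, 2), x2 = 0, year = factor(2019), x1x2 = 0
  )
  ds$y <- rbinom(60, 1, plogis(0.3 + 0.8 * ds$x1))
  fs <- fit_logistic(ds, "x1")
  Xs <- cbind(1, ds$x1)
  nll <- function(beta) {
    eta <- drop(Xs %*% beta)
    -sum(ds$y * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  expect_equal(unname(fs$coefficients), opt$par, tolerance = 1e-6)
})

test_that("known generative coefficients are recovered within 2 SE at n = 5000", {
  set.seed(12)
  truth <- c(b0 = -55, b1 = 1.2, b2 = 0.25, b3 = -0.004)
  d <- simulate_design(5000, truth["b0"], truth["b1"], truth["b2"], truth["b3"])
  f <- fit_logistic(d, terms = c("x1", "x2", "x1:x2"))
  expect_true(f$converged)
  expect_false(f$separation)
  for (i in 1:4) {
    expect_lt(abs(f$coefficients[[i]] - truth[[i]]), 2 * f$se[[i]])
  }
})

test_that("per-egg Bernoulli and grouped binomial fits coincide", {
  set.seed(6)
  d <- simulate_design(600, b0 = -18, b1 = 0.5, b2 = 0, b3 = 0)
  f <- fit_logistic(d, terms = c("x1"))
  grouped <- d |>
    dplyr::count(.data$x1, wt = .data$y, name = "successes") |>
    dplyr::left_join(dplyr::count(d, .data$x1), by = "x1")
  ref <- stats::glm(cbind(successes, n - successes) ~ x1, binomial(),
                    data = grouped)
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-6)
})

test_that("degenerate designs are reported, separation is flagged", {
  set.seed(9)
  d <- simulate_design(200, -5, 0.1, 0, 0)
  d$x1x2 <- d$x1 * 2 # collinear with x1 once x2 is constant
  d$x2 <- 2
  expect_error(fit_logistic(d, c("x1", "x2", "x1:x2")), "collinear")
  # perfectly separated outcome
  d2 <- tibble::tibble(
    y = as.integer((1:40) > 20), x1 = 1:40, x2 = 1,
    year = factor(2019), x1x2 = 1:40
  )
  f2 <- fit_logistic(d2, "x1")
  expect_true(f2$separation)
})

test_that("AIC selection finds the active predictor set", {
  set.seed(15)
  has_x1 <- 0
  drops_x2 <- 0
  for (i in 1:100) {
    d <- simulate_design(300, b0 = -15, b1 = 0.42, b2 = 0, b3 = 0)
    sel <- suppressWarnings(select_by_aic(d, candidates = c("x1", "x2")))
    got <- sel$table$formula[1]
    if (grepl("x1", got)) has_x1 <- has_x1 + 1
    if (grepl("x1", got) && !grepl("x2", got)) drops_x2 <- drops_x2 + 1
  }
  # the active predictor is essentially always retained ...
  expect_gte(has_x1, 99)
  # ... while the inert one is excluded at the rate AIC theory predicts:
  # P(spurious inclusion) = P(chi2_1 > 2) ~= 0.157, so exclusion ~84%,
  # within a 3-sigma binomial band at 100 replicates
  expect_gt(drops_x2 / 100, 0.843 - 3 * sqrt(0.843 * 0.157 / 100))
  expect_lt(drops_x2 / 100, 0.843 + 3 * sqrt(0.843 * 0.157 / 100))
  # ranking table is AIC-sorted with an exact delta column
  d <- simulate_design(500, -15, 0.42, 0, 0)
  sel <- select_by_aic(d)
  expect_true(!is.unsorted(sel$table$aic))
  expect_equal(sel$table$delta_aic, sel$table$aic - sel$table$aic[1])
  expect_equal(sel$best$aic, sel$table$aic[1])
  # single candidate set reduces to that fit plus the intercept-only model
  one <- select_by_aic(d, candidates = "x1")
  expect_equal(nrow(one$table), 2L)
})

test_that("predictions stay strictly inside (0, 1) and follow the link", {
  set.seed(18)
  d <- simulate_design(2000, b0 = -60, b1 = 1.4, b2 = 0.18, b3 = -0.002)
  f <- fit_logistic(d, c("x1", "x2", "x1:x2"))
  # linear predictor 0 -> 0.5, by construction of the inverse link
  b <- f$coefficients
  w0 <- 177
  week0 <- -(b[["(Intercept)"]] + b[["x2"]] * w0) /
    (b[["x1"]] + b[["x1:x2"]] * w0)
  expect_equal(predict_diapause(f, week0, w0), 0.5, tolerance = 1e-10)
  # monotone in week when b1 + b3 * width > 0
  ww <- seq(162, 197, by = 5)
  for (w in ww) {
    ps <- predict_diapause(f, 26:43, w)
    if (b[["x1"]] + b[["x1:x2"]] * w > 0) expect_true(all(diff(ps) > 0))
    expect_true(all(ps > 0 & ps < 1))
  }
  # the field-range span is a strict sub-interval of (0, 1)
  span <- range(predict_diapause(f, rep(26:43, length(ww)),
                                 rep(ww, each = 18)))
  expect_gt(span[1], 0)
  expect_lt(span[2], 1)

  # year effects demand a seen level
  fy <- fit_logistic(d, c("x1", "year"))
  expect_error(predict_diapause(fy, 30, 177, year = 2031), "unseen")
  expect_silent(predict_diapause(fy, 30, 177, year = 2019))
})
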