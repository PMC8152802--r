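test_that("the four rates follow their formulas on hand-checkable cohorts", {
  counts <- tibble::tibble(iso_year = 2019L, iso_week = 30L,
                           H = 18L, E = 2L, P = 3L, U = 2L)
  r <- rates_from_counts(counts)
  expect_equal(r$hatching_success_pct, 90)
  expect_equal(r$diapause_incidence_pct, 10)
  expect_equal(r$viability_pct, 80)
  expect_equal(r$mortality_pct, 20)

  all_dia <- rates_from_counts(tibble::tibble(
    iso_year = 2019L, iso_week = 40L, H = 0L, E = 10L, P = 0L, U = 0L
  ))
  expect_equal(all_dia$diapause_incidence_pct, 100)
  expect_equal(all_dia$viability_pct, 100)
})

test_that("rates agree with per-egg enumeration and conserve to 100 exactly", {
  set.seed(42)
  n_cases <- 500
  counts <- tibble::tibble(
    iso_year = 2019L, iso_week = rep(20:44, length.out = n_cases),
    H = rpois(n_cases, 10), E = rpois(n_cases, 5),
    P = rpois(n_cases, 2), U = rpois(n_cases, 2)
  )
  counts$H <- counts$H + 1L # keep viable denominator positive
  r <- rates_from_counts(counts)

  # brute-force oracle: classify each egg, count memberships, form ratios
  oracle <- function(H, E, P, U) {
    eggs <- rep(c("H", "E", "P", "U"), times = c(H, E, P, U))
    viable <- eggs %in% c("H", "E")
    c(
      hatch = 100 * sum(eggs == "H") / sum(viable),
      dia = 100 * sum(eggs == "E") / sum(viable),
      via = 100 * sum(viable) / length(eggs),
      mort = 100 * sum(!viable) / length(eggs)
    )
  }
  idx <- sample(n_cases, 50)
  for (i in idx) {
    o <- oracle(counts$H[i], counts$E[i], counts$P[i], counts$U[i])
    expect_equal(r$hatching_success_pct[i], unname(o["hatch"]), tolerance = 1e-12)
    expect_equal(r$diapause_incidence_pct[i], unname(o["dia"]), tolerance = 1e-12)
    expect_equal(r$viability_pct[i], unname(o["via"]), tolerance = 1e-12)
    expect_equal(r$mortality_pct[i], unname(o["mort"]), tolerance = 1e-12)
  }
  # conservation identities, exact
  expect_equal(r$hatching_success_pct + r$diapause_incidence_pct,
               rep(100, n_cases))
  expect_equal(r$viability_pct + r$mortality_pct, rep(100, n_cases))

  # degenerate cohorts error explicitly instead of returning zero
  expect_error(
    rates_from_counts(tibble::tibble(iso_year = 2019L, iso_week = 20L,
                                     H = 0L, E = 0L, P = 3L, U = 1L)),
    "no viable eggs"
  )
})

test_that("weekly incidence omits small cohorts and matches the generative rate", {
  eggs <- dplyr::bind_rows(
    eggs_from_counts(2019, 30, H = 20, E = 5),
    eggs_from_counts(2019, 31, H = 3, E = 2),  # n = 5 -> dropped
    eggs_from_counts(2019, 32, H = 10, E = 10)
  )
  expect_message(series <- weekly_incidence(eggs, min_n = 6), "omitted")
  expect_equal(series$iso_week, c(30L, 32L))
  expect_equal(attr(series, "omitted")$iso_week, 31L)

  # all weeks retained when large enough
  series2 <- weekly_incidence(eggs_from_counts(2019, 33, H = 5, E = 5), min_n = 6)
  expect_equal(nrow(series2), 1L)

  # binomial sampling oracle on a seeded synthetic season
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_season(cfg)
  series3 <- suppressMessages(weekly_incidence(sim$eggs, min_n = 6))
  joined <- dplyr::inner_join(series3, sim$truth$weekly,
                              by = c("iso_year", "iso_week"))
  n_viable <- joined$n_tested * (1 - cfg$mortality)
  se <- sqrt(joined$p_diapause * (1 - joined$p_diapause) / n_viable)
  dev <- abs(joined$diapause_incidence_pct / 100 - joined$p_diapause)
  expect_true(all(dev <= pmax(3 * se, 0.02)))
})

test_that("cutoff detection applies the sustained-crossing rule", {
  series_of <- function(weeks, inc) {
    tibble::tibble(iso_year = 2019L, iso_week = weeks,
                   diapause_incidence_pct = inc)
  }
  s1 <- series_of(34:38, c(30, 42, 55, 60, 90))
  expect_equal(detect_cutoff(s1)$cutoff_week, 36L)
  # an early unsustained spike is skipped
  s2 <- series_of(34:38, c(55, 40, 52, 70, 80))
  expect_equal(detect_cutoff(s2)$cutoff_week, 36L)
  # exact equality counts as crossing
  s3 <- series_of(34:37, c(20, 50, 50, 80))
  expect_equal(detect_cutoff(s3)$cutoff_week, 35L)
  # fewer than `sustain` remaining weeks: all remaining must hold
  s4 <- series_of(34:36, c(20, 30, 60))
  expect_equal(detect_cutoff(s4)$cutoff_week, 36L)
  # no sustained crossing is a result, not an error
  s5 <- series_of(34:38, c(20, 55, 30, 52, 40))
  res <- detect_cutoff(s5)
  expect_true(is.na(res$cutoff_week))
  expect_match(res$reason, "no sustained crossing")
  # invariant to prepending sub-threshold weeks
  s6 <- dplyr::bind_rows(series_of(30:33, c(5, 10, 8, 12)), s1)
  expect_equal(detect_cutoff(s6)$cutoff_week, 36L)
  expect_error(detect_cutoff(s1[0, ]), "empty")
})

test_that("CPP increases with maternal delay and averages across years", {
  strasbourg <- site_strasbourg()
  cut19 <- detect_cutoff(tibble::tibble(
    iso_year = 2019L, iso_week = 30:40,
    diapause_incidence_pct = c(10, 12, 15, 25, 40, 45, 55, 70, 85, 95, 100)
  ))
  expect_equal(cut19$cutoff_week, 36L)
  cpps <- dplyr::bind_rows(lapply(0:2, function(d) {
    compute_cpp(cut19, strasbourg, delay_weeks = d)
  }))
  expect_true(all(diff(cpps$cpp_min) > 0)) # monotone in delay
  # the printed references: 13h07 (delay 0), 13h31 (1), 13h57 (2)
  expect_lt(abs(cpps$cpp_min[1] - (13 * 60 + 7)), 3)
  expect_lt(abs(cpps$cpp_min[2] - (13 * 60 + 31)), 3)
  expect_lt(abs(cpps$cpp_min[3] - (13 * 60 + 57)), 3)
  # delay beyond the observed season start errors
  expect_error(compute_cpp(cut19, strasbourg, delay_weeks = 7), "season start")

  avg <- average_cpp(dplyr::bind_rows(
    tibble::tibble(iso_year = 2019L, cutoff_week = 36L, delay_weeks = 1L,
                   cpp_min = 13 * 60 + 31, cpp_hhmm = "13 h 31 min"),
    tibble::tibble(iso_year = 2020L, cutoff_week = 37L, delay_weeks = 1L,
                   cpp_min = 13 * 60 + 14, cpp_hhmm = "13 h 14 min")
  ))
  expect_equal(avg$cpp_min, 13 * 60 + 22.5)
  expect_equal(avg$cpp_hhmm, "13 h 23 min")
  # order invariance and single-year identity
  one <- average_cpp(tibble::tibble(iso_year = 2019L, cutoff_week = 36L,
                                    delay_weeks = 1L, cpp_min = 800,
                                    cpp_hhmm = format_hm(800)))
  expect_equal(one$cpp_min, 800)
  expect_error(average_cpp(tibble::tibble(
    delay_weeks = c(0L, 1L), cpp_min = c(780, 800)
  )), "same maternal delay")
})

test_that("mortality series recovers a constant generative mortality", {
  set.seed(99)
  weeks <- 20:43
  n_per <- 200L
  eggs <- dplyr::bind_rows(lapply(weeks, function(w) {
    dead <- rbinom(1, n_per, 0.2)
    part <- rbinom(1, dead, 0.5)
    eggs_from_counts(2019, w, H = n_per - dead, P = part, U = dead - part)
  }))
  ms <- mortality_series(eggs)
  expect_equal(nrow(ms$weekly), length(weeks))
  expect_lt(abs(ms$mean_pct - 20), 3 * 100 * sqrt(0.2 * 0.8 / n_per) / sqrt(length(weeks)) * sqrt(length(weeks)))
  # weekly SD should be near the binomial sampling SD
  expect_lt(abs(ms$sd_pct - 100 * sqrt(0.2 * 0.8 / n_per)), 1.5)
  expect_false(ms$single_week)

  one_week <- mortality_series(eggs_from_counts(2019, 30, H = 10, U = 0))
  expect_equal(one_week$mean_pct, 0)
  expect_equal(one_week$sd_pct, 0)
  expect_true(one_week$single_week)
})
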