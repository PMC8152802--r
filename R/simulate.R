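# Seeded generator of synthetic ovitrap seasons with the statistical
# structure the analysis assumes: bimodal weekly egg abundance, a
# constitutive diapause floor plus a photoperiodically driven logistic rise
# crossing 50% at a known week, seasonal egg-width drift with an early-
# spring regime, and constant egg mortality.

#' Configuration of a synthetic ovitrap season
#'
#' Defaults emulate a two-year temperate surveillance season (weeks 20-45,
#' 12 ovitraps): bimodal abundance peaking in mid-summer (week 28) and
#' again, lower, in October (week 40); a 10% early-season diapause floor
#' rising to ~100% by mid-October, with the 50% crossing in week 36; egg
#' width drifting up 0.7474 um/week (intercept 151.24 um) in the late
#' regime with a distinct early-spring offset; ~17% egg mortality split
#' between partially embryonated and unfertilised eggs; and ~10% of eggs
#' receiving triplicate morphometry.
#'
#' @param seed RNG seed (integer).
#' @param years calendar years simulated.
#' @param week_range inclusive ISO week span of the season.
#' @param n_traps number of ovitraps.
#' @param peak1_week,peak1_height,peak1_sd first (summer) abundance peak:
#'   mode week, eggs/week at mode, Gaussian width in weeks.
#' @param peak2_week,peak2_height,peak2_sd second (autumn) abundance peak.
#' @param baseline_eggs baseline eggs/week outside the peaks.
#' @param p0 constitutive diapause floor (0 <= p0 < 0.5).
#' @param crossing_week week at which diapause probability equals 0.5.
#' @param steepness logistic slope per week (may be `Inf` for a step).
#' @param width_slope,width_intercept late-regime weekly drift of mean egg
#'   width (um/week) and its intercept (um).
#' @param width_sd per-egg width SD around the weekly mean (um).
#' @param early_offset_um additive width offset for the early regime.
#' @param early_last_week last week of the early regime.
#' @param length_mean,length_sd per-egg length distribution (um).
#' @param rep_sd SD of replicate measurement error (um).
#' @param mortality probability an egg is non-viable (0 <= m < 1).
#' @param partial_frac fraction of non-viable eggs that are partially
#'   embryonated (the rest are unfertilised).
#' @param morph_fraction fraction of eggs receiving morphometry.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       years = c(2019L, 2020L),
                       week_range = c(20L, 45L),
                       n_traps = 12L,
                       peak1_week = 28, peak1_height = 2000, peak1_sd = 3,
                       peak2_week = 40, peak2_height = 600, peak2_sd = 2,
                       baseline_eggs = 20,
                       p0 = 0.10,
                       crossing_week = 36,
                       steepness = 0.9,
                       width_slope = 0.7474,
                       width_intercept = 151.24,
                       width_sd = 7,
                       early_offset_um = 3,
                       early_last_week = 24L,
                       length_mean = 616,
                       length_sd = 29,
                       rep_sd = 1.5,
                       mortality = 0.17,
                       partial_frac = 0.5,
                       morph_fraction = 0.10) {
  cfg <- as.list(environment())
  if (cfg$p0 < 0 || cfg$p0 >= 0.5) {
    abort("`p0` must satisfy 0 <= p0 < 0.5, or the 50% crossing is unreachable")
  }
  if (cfg$mortality < 0 || cfg$mortality >= 1) abort("`mortality` must be in [0, 1)")
  if (cfg$morph_fraction < 0 || cfg$morph_fraction > 1) {
    abort("`morph_fraction` must be in [0, 1]")
  }
  if (any(c(cfg$peak1_height, cfg$peak2_height, cfg$baseline_eggs) < 0)) {
    abort("abundance intensities must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

#' Generative diapause probability by week
#'
#' Mixture of a constitutive floor `p0` and a photoperiodically driven
#' logistic component,
#' \eqn{p(w) = p_0 + (1 - p_0) \, \mathrm{logistic}(k (w - w_0))},
#' with \eqn{w_0} located so that \eqn{p(w^*) = 0.5} exactly at the
#' configured crossing week. A pure logistic cannot hold a persistent ~10%
#' early-season incidence, hence the mixture. With infinite steepness the
#' probability is `p0` before the crossing week and 1 from it onwards.
#'
#' @param week numeric vector of weeks.
#' @param config a [sim_config()].
#' @return diapause probabilities.
#' @export
diapause_probability <- function(week, config) {
  stopifnot(inherits(config, "sim_config"))
  p0 <- config$p0
  k <- config$steepness
  wstar <- config$crossing_week
  if (is.infinite(k)) {
    return(ifelse(week >= wstar, 1, p0))
  }
  target <- (0.5 - p0) / (1 - p0) # logistic value needed at the crossing
  w0 <- wstar - qlogis(target) / k
  p0 + (1 - p0) * plogis(k * (week - w0))
}

#' Cohort-average diapause probability of a collection week
#'
#' Eggs collected at the end of ISO week `w` were laid throughout that
#' week, so the cohort's diapause probability is the within-week average
#' of [diapause_probability()] over laying times in `[w, w + 1)`. Because
#' the continuous probability reaches 0.5 exactly at the start of the
#' crossing week, the crossing week is the first collection week whose
#' cohort probability exceeds one half -- the generative counterpart of
#' the observed 50% cut-off week.
#'
#' @inheritParams diapause_probability
#' @return cohort-level diapause probabilities.
#' @export
cohort_diapause_probability <- function(week, config) {
  mids <- (seq_len(7) - 0.5) / 7 # mid-day laying times of the 7 days
  vapply(
    week,
    function(w) mean(diapause_probability(w + mids, config)),
    numeric(1)
  )
}

# expected eggs laid in a week (all traps combined)
.weekly_intensity <- function(week, config) {
  config$baseline_eggs +
    config$peak1_height * exp(-(week - config$peak1_week)^2 / (2 * config$peak1_sd^2)) +
    config$peak2_height * exp(-(week - config$peak2_week)^2 / (2 * config$peak2_sd^2))
}

# mean egg width in a given week
.mean_width <- function(week, config) {
  config$width_intercept + config$width_slope * week +
    ifelse(week <= config$early_last_week, config$early_offset_um, 0)
}

#' Simulate a synthetic ovitrap season
#'
#' Draws per trap-week egg counts from Poisson(lambda_week / n_traps),
#' assigns each egg a laying time uniform within its collection week and a
#' status (non-viable with the configured mortality, split between
#' partially embryonated and unfertilised; otherwise in diapause with
#' probability [diapause_probability()] at its laying time -- the cohort
#' aggregate is [cohort_diapause_probability()]), gives a configured
#' fraction of eggs triplicate length/width measurements, and generates a
#' matching daily meteorological series (seasonal sinusoids plus noise;
#' only the ordering invariants, not climatological realism, are promised).
#' Identical seeds give identical output.
#'
#' @param config a [sim_config()].
#' @return a list with `eggs` (validated egg tibble), `meteo` (daily
#'   tibble) and `truth` (the generative parameters, the weekly diapause
#'   probabilities, per-status tallies and a `run_id` shared with the
#'   `eggs` attribute of the same name).
#' @export
simulate_season <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  weeks <- seq(config$week_range[1], config$week_range[2])
  rows <- list()
  tally <- list()
  for (year in config$years) {
    for (w in weeks) {
      lam <- .weekly_intensity(w, config) / config$n_traps
      n_per_trap <- rpois(config$n_traps, lam)
      n_week <- sum(n_per_trap)
      if (n_week == 0) next
      trap_id <- rep(sprintf("T%02d", seq_len(config$n_traps)), n_per_trap)
      # collection at the end of the ISO week (Sunday)
      cdate <- iso_week_start(year, w) + 6L
      dead <- runif(n_week) < config$mortality
      partial <- dead & (runif(n_week) < config$partial_frac)
      # each egg is laid at some time during the collection week
      laying_time <- w + runif(n_week)
      p_egg <- diapause_probability(laying_time, config)
      dia <- !dead & (runif(n_week) < p_egg)
      status <- ifelse(dead, ifelse(partial, "PARTIAL_EMBRYO", "UNFERTILISED"),
                       ifelse(dia, "EMBRYONATED_UNHATCHED", "HATCHED"))
      measured <- runif(n_week) < config$morph_fraction
      mu_w <- .mean_width(w, config)
      true_w <- rnorm(n_week, mu_w, config$width_sd)
      true_w <- pmax(true_w, 60)
      true_l <- pmax(rnorm(n_week, config$length_mean, config$length_sd),
                     true_w + 50)
      reps <- function(mu) {
        m <- matrix(rnorm(3 * n_week, rep(mu, each = 3), config$rep_sd),
                    ncol = 3, byrow = TRUE)
        m[!measured, ] <- NA_real_
        m
      }
      lrep <- reps(true_l)
      wrep <- reps(true_w)
      rows[[length(rows) + 1]] <- tibble::tibble(
        egg_id = sprintf("%d-W%02d-%05d", year, w, seq_len(n_week)),
        site_id = "SYN",
        trap_id = trap_id,
        collection_date = cdate,
        status = status,
        length_rep1_um = lrep[, 1], length_rep2_um = lrep[, 2],
        length_rep3_um = lrep[, 3],
        width_rep1_um = wrep[, 1], width_rep2_um = wrep[, 2],
        width_rep3_um = wrep[, 3]
      )
      tally[[length(tally) + 1]] <- tibble::tibble(
        iso_year = year, iso_week = w, n_eggs = n_week,
        p_diapause = cohort_diapause_probability(w, config),
        n_diapause = sum(dia), n_dead = sum(dead),
        n_measured = sum(measured)
      )
    }
  }
  eggs <- validate_eggs(dplyr::bind_rows(rows), source = "simulated eggs")
  weekly_truth <- dplyr::bind_rows(tally)

  meteo <- .simulate_meteo(config)

  run_id <- sprintf("sim-seed%d-n%d", config$seed, nrow(eggs))
  attr(eggs, "run_id") <- run_id
  truth <- list(
    run_id = run_id,
    config = unclass(config),
    weekly = weekly_truth,
    n_eggs = nrow(eggs),
    n_viable = sum(eggs$status %in% VIABLE_STATUSES),
    n_with_morph = sum(!is.na(eggs$width_rep1_um))
  )
  list(eggs = eggs, meteo = meteo, truth = truth)
}

.simulate_meteo <- function(config) {
  days <- do.call(c, lapply(config$years, function(year) {
    seq(iso_week_start(year, config$week_range[1]),
        iso_week_start(year, config$week_range[2]) + 6L, by = "day")
  }))
  doy <- as.integer(format(days, "%j"))
  tmin <- 9 - 9 * cos(2 * pi * (doy - 15) / 365.25) + rnorm(length(days), 0, 2)
  spread <- pmax(0.5, 8 + rnorm(length(days), 0, 2))
  sun <- pmax(0, 250 + 250 * sin(2 * pi * (doy - 80) / 365.25) +
                rnorm(length(days), 0, 120))
  wet <- runif(length(days)) < 0.45
  rain <- ifelse(wet, round(stats::rgamma(length(days), shape = 1.2, scale = 4), 1), 0)
  tibble::tibble(
    date = days,
    tmin_C = round(tmin, 1),
    tmax_C = round(tmin + spread, 1),
    sunshine_min = round(sun),
    rainfall_mm = rain
  )
}

#' Compare generative truth with pipeline estimates
#'
#' Recovery report for a simulated season analysed by [run_all()]: the
#' constitutive diapause floor (estimated as the mean incidence over the
#' pre-rise weeks), the 50% crossing week, the late-regime width slope and
#' the mortality rate, each with its generative value, estimation error and
#' a tolerance verdict.
#'
#' @param truth the `truth` element of a [simulate_season()] result.
#' @param report a [run_all()] report computed from the same run's eggs.
#' @param tol named list of absolute tolerances: `p0` (proportion),
#'   `crossing_week` (weeks), `width_slope_se` (multiple of the estimated
#'   slope SE), `mortality` (percentage points).
#' @return a tibble with one row per recovered parameter: `parameter`,
#'   `generative`, `estimated`, `error`, `tolerance`, `ok`.
#' @export
truth_vs_estimate <- function(truth, report,
                              tol = list(p0 = 0.05, crossing_week = 1,
                                         width_slope_se = 2, mortality = 3)) {
  if (!identical(truth$run_id, report$run_id)) {
    abort(sprintf("run IDs differ: truth %s vs report %s",
                  truth$run_id %||% "<none>", report$run_id %||% "<none>"))
  }
  cfg <- truth$config
  rows <- list()

  early <- dplyr::filter(report$rates,
                         .data$iso_week <= cfg$crossing_week - 4)
  if (nrow(early) > 0) {
    est_p0 <- mean(early$diapause_incidence_pct) / 100
    rows$p0 <- tibble::tibble(
      parameter = "p0", generative = cfg$p0, estimated = est_p0,
      error = est_p0 - cfg$p0, tolerance = tol$p0,
      ok = abs(est_p0 - cfg$p0) <= tol$p0
    )
  }

  cuts <- vapply(report$seasons, function(s) {
    if (is.null(s$cutoff) || is.na(s$cutoff$cutoff_week)) NA_real_
    else as.numeric(s$cutoff$cutoff_week)
  }, numeric(1))
  est_cut <- mean(cuts, na.rm = TRUE)
  rows$cut <- tibble::tibble(
    parameter = "crossing_week", generative = cfg$crossing_week,
    estimated = est_cut, error = est_cut - cfg$crossing_week,
    tolerance = tol$crossing_week,
    ok = is.finite(est_cut) &&
      abs(est_cut - cfg$crossing_week) <= tol$crossing_week
  )

  slopes <- purrr::compact(lapply(report$seasons, function(s) s$width_fit))
  if (length(slopes) > 0) {
    est <- mean(vapply(slopes, function(f) f$slope, numeric(1)))
    se <- mean(vapply(slopes, function(f) f$slope_se, numeric(1)))
    rows$slope <- tibble::tibble(
      parameter = "width_slope", generative = cfg$width_slope,
      estimated = est, error = est - cfg$width_slope,
      tolerance = tol$width_slope_se * se,
      ok = abs(est - cfg$width_slope) <= tol$width_slope_se * se
    )
  }

  est_mort <- report$mortality$mean_pct
  rows$mort <- tibble::tibble(
    parameter = "mortality_pct", generative = 100 * cfg$mortality,
    estimated = est_mort, error = est_mort - 100 * cfg$mortality,
    tolerance = tol$mortality,
    ok = abs(est_mort - 100 * cfg$mortality) <= tol$mortality
  )

  dplyr::bind_rows(rows)
}
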