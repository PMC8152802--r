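#' Run the full season analysis
#'
#' Chains every stage over one or more surveillance seasons: two-week
#' abundance binning, weekly rate series, sustained 50% cut-off detection,
#' maternal CPP at several delays with the cross-year average, late-season
#' morphometric regressions on weekly medians, ND/M/D group contrasts,
#' AIC-selected logistic diapause model, and (when meteorology is
#' supplied) the activity temperature threshold and covariate
#' correlations. Every number in the report is a stage output; nothing is
#' recomputed in the report layer. The report is deterministic given its
#' inputs.
#'
#' @param eggs a validated egg tibble (see [read_eggs()], [validate_eggs()]).
#' @param meteo optional daily meteorological tibble (see [read_meteo()]).
#' @param site a [site()] used for photoperiod and CPP.
#' @param min_n smallest weekly cohort retained.
#' @param threshold_pct,sustain cut-off detection parameters
#'   (see [detect_cutoff()]).
#' @param delays integer maternal delays (weeks) at which to report the CPP.
#' @param early_range,late_range regimes for the seasonal regressions
#'   (see [split_season()]).
#' @param candidates candidate GLM terms (see [select_by_aic()]).
#' @param zenith_deg sunrise/sunset zenith convention.
#' @return a `season_report` list; serialize with [write_summary()].
#' @export
run_all <- function(eggs, meteo = NULL, site = site_strasbourg(),
                    min_n = 6, threshold_pct = 50, sustain = 2,
                    delays = 0:2,
                    early_range = c(20, 24), late_range = c(26, 43),
                    candidates = c("x1", "x2", "year", "x1:x2"),
                    zenith_deg = 90.567) {
  run_id <- attr(eggs, "run_id", exact = TRUE)
  eggs <- validate_eggs(eggs, source = "run_all input")

  abundance <- abundance_series(eggs, bin_width = 2)
  rates <- suppressMessages(weekly_incidence(eggs, min_n = min_n))
  mortality <- mortality_series(eggs, min_n = min_n)
  morph <- suppressMessages(summarize_reps(eggs))
  have_morph <- nrow(morph) > 0
  weekly_morph <- if (have_morph) weekly_median_morphometry(morph, min_n = min_n)

  years <- sort(unique(rates$iso_year))
  seasons <- lapply(years, function(yr) {
    s <- list(iso_year = yr)
    yr_rates <- rates[rates$iso_year == yr, ]
    s$rates <- yr_rates
    s$cutoff <- if (nrow(yr_rates) > 0) {
      detect_cutoff(yr_rates, threshold_pct = threshold_pct, sustain = sustain)
    }
    if (!is.null(s$cutoff) && !is.na(s$cutoff$cutoff_week)) {
      cpps <- lapply(delays, function(d) {
        tryCatch(compute_cpp(s$cutoff, site, d, zenith_deg),
                 error = function(e) NULL)
      })
      s$cpp <- dplyr::bind_rows(purrr::compact(cpps))
      s$groups <- assign_groups(s$cutoff$cutoff_week, yr_rates$iso_week)
    }
    if (have_morph) {
      wm <- weekly_morph[weekly_morph$iso_year == yr, ]
      halves <- tryCatch(
        suppressWarnings(split_season(wm, early_range, late_range)),
        error = function(e) NULL
      )
      fit_or_null <- function(data, response) {
        tryCatch(seasonal_regression(data, response), error = function(e) NULL)
      }
      if (!is.null(halves)) {
        s$width_fit <- fit_or_null(halves$late, "width_um")
        s$volume_fit <- fit_or_null(halves$late, "volume_e3mm3")
        s$width_fit_early <- fit_or_null(halves$early, "width_um")
      }
    }
    s
  })
  names(seasons) <- as.character(years)

  # CPP averages across the years for which every delay is available
  cpp_all <- dplyr::bind_rows(purrr::compact(
    lapply(seasons, function(s) s$cpp)
  ))
  cpp_average <- if (nrow(cpp_all) > 0) {
    lapply(split(cpp_all, cpp_all$delay_weeks), average_cpp)
  }

  # pooled ND/D morphometric contrasts with year-specific group labels
  group_tests <- NULL
  if (have_morph) {
    labelled <- dplyr::bind_rows(lapply(seasons, function(s) {
      if (is.null(s$groups)) return(NULL)
      dplyr::inner_join(
        morph[morph$iso_year == s$iso_year, ],
        s$groups,
        by = "iso_week"
      )
    }))
    if (!is.null(labelled) && nrow(labelled) > 0 &&
        all(c("ND", "D") %in% labelled$group)) {
      d_w <- labelled$width_um[labelled$group == "D"]
      nd_w <- labelled$width_um[labelled$group == "ND"]
      d_v <- labelled$volume_e3mm3[labelled$group == "D"]
      nd_v <- labelled$volume_e3mm3[labelled$group == "ND"]
      group_tests <- list(
        width = wilcoxon_one_tailed(d_w, nd_w),
        volume = wilcoxon_one_tailed(d_v, nd_v)
      )
      m_sub <- labelled[labelled$group == "M", ]
      if (length(unique(m_sub$iso_week)) >= 2) {
        group_tests$m_homogeneity <- kruskal_wallis(
          split(m_sub$width_um, m_sub$iso_week)
        )
      }
    }
  }

  glm <- NULL
  if (have_morph) {
    glm <- tryCatch(
      select_by_aic(build_design(eggs), candidates = candidates),
      error = function(e) {
        inform(paste("GLM stage skipped:", conditionMessage(e)))
        NULL
      }
    )
  }

  activity <- NULL
  correlations <- NULL
  if (!is.null(meteo)) {
    mw <- suppressMessages(weekly_meteo(meteo, site = site,
                                        zenith_deg = zenith_deg))
    activity <- tryCatch(activity_threshold(rates, mw),
                         error = function(e) NULL)
    joined <- dplyr::inner_join(
      rates, mw, by = c("iso_year", "iso_week")
    )
    if (nrow(joined) >= 3) {
      correlations <- dplyr::bind_rows(
        spearman(joined$iso_week, joined$diapause_incidence_pct,
                 "week", "diapause_incidence_pct"),
        spearman(joined$avPhotoperiod_min, joined$diapause_incidence_pct,
                 "avPhotoperiod_min", "diapause_incidence_pct"),
        spearman(joined$avTmin, joined$diapause_incidence_pct,
                 "avTmin", "diapause_incidence_pct")
      )
    }
  }

  structure(
    list(
      run_id = run_id,
      params = list(
        site = unclass(site), min_n = min_n,
        threshold_pct = threshold_pct, sustain = sustain,
        delays = delays, early_range = early_range,
        late_range = late_range, zenith_deg = zenith_deg
      ),
      abundance = abundance,
      rates = rates,
      omitted = attr(rates, "omitted"),
      n_excluded = sum(eggs$status == "EXCLUDED"),
      mortality = mortality,
      seasons = seasons,
      cpp_average = cpp_average,
      group_tests = group_tests,
      glm = glm,
      activity = activity,
      correlations = correlations
    ),
    class = "season_report"
  )
}

#' @export
print.season_report <- function(x, ...) {
  cat("== Season report ==\n")
  print(x$abundance)
  cat(sprintf("Mortality: %.1f +/- %.1f %% across %d weeks\n",
              x$mortality$mean_pct, x$mortality$sd_pct,
              nrow(x$mortality$weekly)))
  for (s in x$seasons) {
    if (!is.null(s$cutoff)) print(s$cutoff)
    if (!is.null(s$cpp) && nrow(s$cpp) > 0) {
      for (i in seq_len(nrow(s$cpp))) {
        cat(sprintf("  CPP (delay %d wk): %s\n",
                    s$cpp$delay_weeks[i], s$cpp$cpp_hhmm[i]))
      }
    }
    if (!is.null(s$width_fit)) {
      cat(sprintf("  late-season width slope: %.4f um/week (adj R2 %.2f)\n",
                  s$width_fit$slope, s$width_fit$r_squared))
    }
  }
  if (!is.null(x$cpp_average)) {
    for (a in x$cpp_average) {
      cat(sprintf("Average CPP (delay %d wk, %d year(s)): %s\n",
                  a$delay_weeks, a$n_years, a$cpp_hhmm))
    }
  }
  if (!is.null(x$group_tests)) {
    cat(sprintf("Group D vs ND width: +%.2f%% (W = %.0f, p = %.3g)\n",
                x$group_tests$width$effect_pct,
                x$group_tests$width$statistic,
                x$group_tests$width$p_value))
  }
  if (!is.null(x$glm)) {
    cat("GLM selection (best first):\n")
    print(as.data.frame(head(x$glm$table, 4)))
  }
  if (!is.null(x$activity)) {
    cat(sprintf("Activity temperature threshold: %.1f C\n",
                x$activity$threshold_C))
  }
  invisible(x)
}
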