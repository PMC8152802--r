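#' Egg-status rates from cohort counts
#'
#' The four complementary rates of the egg-status taxonomy, per cohort:
#' \itemize{
#'   \item hatching success = 100 H / (H + E)
#'   \item diapause incidence = 100 E / (H + E) = 100 - hatching success
#'   \item viability = 100 (H + E) / (H + E + P + U)
#'   \item mortality = 100 (P + U) / (H + E + P + U)
#' }
#' where H = hatched, E = embryonated unhatched (the operational marker of
#' diapause), P = partially embryonated and U = unfertilised. EXCLUDED eggs
#' are outside every denominator by construction (see [tally_cohorts()]).
#'
#' @param counts a tibble with columns `iso_year`, `iso_week`, `H`, `E`,
#'   `P`, `U` (one row per cohort), as produced by [tally_cohorts()].
#' @return a tibble with `iso_year`, `iso_week`, `n_tested` and the four
#'   rate columns (`hatching_success_pct`, `diapause_incidence_pct`,
#'   `viability_pct`, `mortality_pct`), all in \[0, 100\].
#' @export
rates_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  req <- c("iso_year", "iso_week", "H", "E", "P", "U")
  if (!all(req %in% names(counts))) {
    abort(sprintf("`counts` must have columns %s", paste(req, collapse = ", ")))
  }
  if (any(counts[, c("H", "E", "P", "U")] < 0)) {
    abort("counts must be non-negative")
  }
  tested <- counts$H + counts$E + counts$P + counts$U
  if (any(tested == 0)) {
    abort("cohort with no tested eggs: all rates undefined")
  }
  viable <- counts$H + counts$E
  if (any(viable == 0)) {
    bad <- counts[viable == 0, ]
    abort(sprintf(
      "no viable eggs in cohort(s) %s: hatching success and diapause incidence are undefined",
      paste(sprintf("%d-W%02d", bad$iso_year, bad$iso_week), collapse = ", ")
    ))
  }
  tibble::tibble(
    iso_year = counts$iso_year,
    iso_week = counts$iso_week,
    n_tested = tested,
    hatching_success_pct = 100 * counts$H / viable,
    diapause_incidence_pct = 100 * counts$E / viable,
    viability_pct = 100 * viable / tested,
    mortality_pct = 100 * (counts$P + counts$U) / tested
  )
}

#' Weekly diapause-incidence series
#'
#' Tallies egg records per ISO week, drops small cohorts (and cohorts with
#' no viable eggs, whose diapause incidence is undefined), and computes the
#' four rates per remaining week, ordered in time. Omitted weeks are
#' reported in the `omitted` attribute and via a message.
#'
#' @param eggs a validated egg tibble.
#' @param min_n smallest cohort size retained (default 6; a season week
#'   with n = 5 tested eggs is dropped).
#' @return ordered tibble of weekly rates (see [rates_from_counts()]);
#'   attribute `omitted` lists dropped cohorts with a reason.
#' @export
weekly_incidence <- function(eggs, min_n = 6) {
  stopifnot(min_n >= 1)
  counts <- tally_cohorts(eggs, group_by = "week")
  if (nrow(counts) == 0) {
    out <- rates_from_counts(counts[0, ])
    attr(out, "omitted") <- counts[0, ]
    return(out)
  }
  small <- counts$n_tested < min_n
  noviable <- counts$H + counts$E == 0
  omitted <- counts[small | noviable, ]
  if (nrow(omitted) > 0) {
    omitted$reason <- ifelse(omitted$n_tested < min_n, "n_tested < min_n",
                             "no viable eggs")
    inform(sprintf(
      "weekly_incidence: omitted %d cohort(s): %s",
      nrow(omitted),
      paste(sprintf("%d-W%02d (%s)", omitted$iso_year, omitted$iso_week,
                    omitted$reason), collapse = ", ")
    ))
  }
  kept <- counts[!(small | noviable), ]
  out <- rates_from_counts(kept) |>
    dplyr::arrange(.data$iso_year, .data$iso_week)
  attr(out, "omitted") <- omitted
  out
}

#' Detect the sustained 50% diapause cut-off week
#'
#' Scans a single season's ordered weekly incidence series for the earliest
#' week at or above `threshold_pct` such that the next `sustain` observed
#' weeks (or all remaining weeks, if fewer are observed) also stay at or
#' above the threshold. Exact equality counts as a crossing. Field series
#' are noisy, so the sustained rule ignores isolated early spikes.
#'
#' @param series a weekly rate tibble for one season (one `iso_year`),
#'   ordered or orderable by `iso_week`, with `diapause_incidence_pct`.
#' @param threshold_pct crossing threshold (default 50).
#' @param sustain number of subsequent observed weeks that must also be at
#'   or above the threshold (default 2).
#' @return a `cutoff_result` list: `iso_year`, `cutoff_week`,
#'   `incidence_at_cutoff_pct`, `weeks_used`, `threshold_pct`, `sustain`.
#'   When no sustained crossing exists, `cutoff_week` is `NA` and `reason`
#'   explains (this is a result, not an error).
#' @export
detect_cutoff <- function(series, threshold_pct = 50, sustain = 2) {
  series <- tibble::as_tibble(series)
  if (nrow(series) == 0) abort("`series` is empty")
  if (length(unique(series$iso_year)) != 1) {
    abort("`series` must cover a single season (one iso_year)")
  }
  series <- dplyr::arrange(series, .data$iso_week)
  inc <- series$diapause_incidence_pct
  wk <- series$iso_week
  above <- inc >= threshold_pct
  hit <- NA_integer_
  for (i in seq_along(above)) {
    if (!above[i]) next
    follow <- above[seq_len(length(above)) > i]
    look <- head(follow, sustain)
    if (all(look)) {
      hit <- i
      break
    }
  }
  res <- list(
    iso_year = series$iso_year[1],
    cutoff_week = if (is.na(hit)) NA_integer_ else wk[hit],
    incidence_at_cutoff_pct = if (is.na(hit)) NA_real_ else inc[hit],
    weeks_used = wk,
    threshold_pct = threshold_pct,
    sustain = sustain
  )
  if (is.na(hit)) res$reason <- "no sustained crossing this season"
  structure(res, class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  if (is.na(x$cutoff_week)) {
    cat(sprintf("Season %d: no sustained %g%% diapause crossing\n",
                x$iso_year, x$threshold_pct))
  } else {
    cat(sprintf(
      "Season %d: %g%% diapause cut-off at week %d (incidence %.1f%%)\n",
      x$iso_year, x$threshold_pct, x$cutoff_week, x$incidence_at_cutoff_pct
    ))
  }
  invisible(x)
}

#' Maternal critical photoperiod from a cut-off week
#'
#' The critical photoperiod (CPP) is the maternal day length at which half
#' of the eggs laid are in diapause. Ovipositing females sense photoperiod
#' `delay_weeks` before their eggs are collected, so the CPP is the weekly
#' mean photoperiod of week `cutoff_week - delay_weeks`. During the
#' declining-photoperiod half of the season the CPP therefore increases
#' with the assumed delay.
#'
#' @param cutoff a [detect_cutoff()] result with a non-missing cut-off week.
#' @param site a [site()] object.
#' @param delay_weeks maternal delay in whole weeks (default 1).
#' @param zenith_deg passed to [day_length_min()].
#' @return a one-row tibble: `iso_year`, `cutoff_week`, `delay_weeks`,
#'   `cpp_min`, `cpp_hhmm`.
#' @export
compute_cpp <- function(cutoff, site, delay_weeks = 1, zenith_deg = 90.567) {
  stopifnot(inherits(cutoff, "cutoff_result"))
  if (is.na(cutoff$cutoff_week)) {
    abort("cutoff has no crossing week; CPP undefined")
  }
  if (delay_weeks < 0 || delay_weeks != round(delay_weeks)) {
    abort("`delay_weeks` must be a non-negative integer")
  }
  target <- cutoff$cutoff_week - delay_weeks
  if (target < min(cutoff$weeks_used)) {
    abort(sprintf(
      "maternal delay of %d week(s) points to week %d, before the observed season start (week %d)",
      delay_weeks, target, min(cutoff$weeks_used)
    ))
  }
  pp <- weekly_photoperiod(cutoff$iso_year, target, site, zenith_deg)
  tibble::tibble(
    iso_year = cutoff$iso_year,
    cutoff_week = cutoff$cutoff_week,
    delay_weeks = as.integer(delay_weeks),
    cpp_min = pp$av_daylength_min,
    cpp_hhmm = pp$hhmm
  )
}

#' Average critical photoperiod across seasons
#'
#' Arithmetic mean of yearly CPP values computed at the same maternal delay.
#'
#' @param cpps a tibble of [compute_cpp()] rows (one per season).
#' @return a list with `delay_weeks`, `n_years`, `cpp_min`, `cpp_hhmm`.
#' @export
average_cpp <- function(cpps) {
  cpps <- tibble::as_tibble(cpps)
  if (nrow(cpps) < 1) abort("need at least one yearly CPP")
  if (length(unique(cpps$delay_weeks)) != 1) {
    abort("all CPP values must use the same maternal delay")
  }
  avg <- mean(cpps$cpp_min)
  list(
    delay_weeks = cpps$delay_weeks[1],
    n_years = nrow(cpps),
    cpp_min = avg,
    cpp_hhmm = format_hm(avg)
  )
}

#' Weekly mortality series with season summary
#'
#' Weekly mortality (partially embryonated + unfertilised, over all tested
#' eggs) plus the season mean and standard deviation across weeks. With a
#' single retained week the SD is reported as 0 and flagged.
#'
#' @inheritParams weekly_incidence
#' @return a list: `weekly` (tibble of `iso_year`, `iso_week`, `n_tested`,
#'   `mortality_pct`), `mean_pct`, `sd_pct`, `single_week` flag.
#' @export
mortality_series <- function(eggs, min_n = 6) {
  counts <- tally_cohorts(eggs, group_by = "week")
  kept <- counts[counts$n_tested >= min_n, ]
  if (nrow(kept) == 0) abort("no cohorts of at least `min_n` tested eggs")
  weekly <- tibble::tibble(
    iso_year = kept$iso_year,
    iso_week = kept$iso_week,
    n_tested = kept$n_tested,
    mortality_pct = 100 * (kept$P + kept$U) / kept$n_tested
  )
  single <- nrow(weekly) == 1
  list(
    weekly = weekly,
    mean_pct = mean(weekly$mortality_pct),
    sd_pct = if (single) 0 else sd(weekly$mortality_pct),
    single_week = single
  )
}
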