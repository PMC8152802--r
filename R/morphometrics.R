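#' Spheroid egg volume
#'
#' Volume of an egg modelled as a prolate spheroid,
#' \eqn{V = (\pi/6) \, L \, W^2}, with length and width in micrometres and
#' the result in units of \eqn{10^{-3}} mm\eqn{^3} (division by \eqn{10^6}).
#'
#' @param length_um egg length in micrometres (> 0).
#' @param width_um egg width in micrometres (> 0).
#' @return volume in \eqn{10^{-3}} mm\eqn{^3}.
#' @examples
#' egg_volume(616, 177) # ~10.1
#' egg_volume(625, 179) # ~10.5
#' @export
egg_volume <- function(length_um, width_um) {
  if (any(!is.finite(length_um)) || any(!is.finite(width_um)) ||
      any(length_um <= 0) || any(width_um <= 0)) {
    abort("`length_um` and `width_um` must be positive finite numbers")
  }
  (pi / 6) * length_um * width_um^2 / 1e6
}

#' Per-egg morphometry from triplicate measurements
#'
#' Each axis of each egg is measured three times to limit observation bias;
#' this collapses the replicates to their arithmetic mean and derives the
#' spheroid volume. Eggs without morphometry are skipped (logged via the
#' `n_skipped` attribute).
#'
#' @param eggs a validated egg tibble.
#' @return a tibble with `egg_id`, `iso_year`, `iso_week`, `status`,
#'   `length_um`, `width_um`, `volume_e3mm3`; attribute `n_skipped` counts
#'   eggs lacking replicate measurements.
#' @export
summarize_reps <- function(eggs) {
  eggs <- validate_eggs(eggs, source = "summarize_reps input")
  lmat <- as.matrix(eggs[, c("length_rep1_um", "length_rep2_um", "length_rep3_um")])
  wmat <- as.matrix(eggs[, c("width_rep1_um", "width_rep2_um", "width_rep3_um")])
  has <- complete.cases(lmat) & complete.cases(wmat)
  n_skipped <- sum(!has)
  if (n_skipped > 0) {
    inform(sprintf("summarize_reps: %d egg(s) without morphometry skipped",
                   n_skipped))
  }
  out <- tibble::tibble(
    egg_id = eggs$egg_id[has],
    iso_year = eggs$iso_year[has],
    iso_week = eggs$iso_week[has],
    status = eggs$status[has],
    length_um = rowMeans(lmat[has, , drop = FALSE]),
    width_um = rowMeans(wmat[has, , drop = FALSE])
  )
  out$volume_e3mm3 <- if (nrow(out) > 0) {
    egg_volume(out$length_um, out$width_um)
  } else {
    numeric(0)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Weekly median morphometry
#'
#' Median egg length, width and volume per ISO week, over non-EXCLUDED eggs
#' with morphometry; the unit of analysis for the seasonal regressions.
#'
#' @param morph per-egg morphometry from [summarize_reps()].
#' @param min_n smallest weekly egg count retained (default 6).
#' @return a tibble with `iso_year`, `iso_week`, `n_eggs`, `length_um`,
#'   `width_um`, `volume_e3mm3` (weekly medians).
#' @export
weekly_median_morphometry <- function(morph, min_n = 6) {
  morph <- tibble::as_tibble(morph)
  morph |>
    dplyr::filter(.data$status != "EXCLUDED") |>
    dplyr::group_by(.data$iso_year, .data$iso_week) |>
    dplyr::summarise(
      n_eggs = dplyr::n(),
      length_um = median(.data$length_um),
      width_um = median(.data$width_um),
      volume_e3mm3 = median(.data$volume_e3mm3),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_eggs >= min_n) |>
    dplyr::arrange(.data$iso_year, .data$iso_week)
}

#' Seasonal linear regression of a weekly morphometric value
#'
#' Ordinary least squares of a weekly (typically median) morphometric value
#' on the week of collection, \eqn{y = \beta_0 + \beta_1 \, week + \epsilon},
#' restricted to a week range. Reports the slope with its standard error,
#' the intercept, adjusted \eqn{R^2} and the slope p-value.
#'
#' @param weekly a tibble with a `iso_week` column and the response column.
#' @param response name of the response column (string).
#' @param week_range inclusive `c(first, last)` week filter, or `NULL` for
#'   all weeks present.
#' @return a `seasonal_fit` list: `response_name`, `slope`, `slope_se`,
#'   `intercept`, `r_squared` (adjusted), `p_value`, `weeks_used`, `n`.
#' @export
seasonal_regression <- function(weekly, response, week_range = NULL) {
  weekly <- tibble::as_tibble(weekly)
  if (!response %in% names(weekly)) {
    abort(sprintf("response column %s not found", response))
  }
  if (!is.null(week_range)) {
    weekly <- weekly[weekly$iso_week >= week_range[1] &
                       weekly$iso_week <= week_range[2], ]
  }
  if (nrow(weekly) < 3) abort("need at least 3 weekly values to fit a line")
  if (length(unique(weekly$iso_week)) < 2) {
    abort("zero variance in week: regression undefined")
  }
  df <- data.frame(week = weekly$iso_week, y = weekly[[response]])
  fit <- lm(y ~ week, data = df)
  sm <- suppressWarnings(summary(fit)) # exact fits warn harmlessly
  structure(
    list(
      response_name = response,
      slope = unname(coef(fit)["week"]),
      slope_se = unname(sm$coefficients["week", "Std. Error"]),
      intercept = unname(coef(fit)["(Intercept)"]),
      r_squared = sm$adj.r.squared,
      p_value = unname(sm$coefficients["week", "Pr(>|t|)"]),
      weeks_used = sort(unique(weekly$iso_week)),
      n = nrow(weekly)
    ),
    class = "seasonal_fit"
  )
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat(sprintf(
    "%s = %.4f x week + %.2f  (adj R2 %.3f, p %.3g, n %d weeks)\n",
    x$response_name, x$slope, x$intercept, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' Split a weekly series into early and late season regimes
#'
#' Egg width and volume follow two regimes over the season (an early,
#' spring window and a later rising window); regressions are fitted per
#' regime. Ranges must not overlap; an empty early subset downgrades to a
#' late-only analysis with a warning.
#'
#' @param weekly weekly series with an `iso_week` column.
#' @param early_range inclusive `c(first, last)` weeks of the early regime
#'   (default weeks 20--24).
#' @param late_range inclusive weeks of the late regime (default 26--43).
#' @return a list with tibbles `early` and `late`.
#' @export
split_season <- function(weekly, early_range = c(20, 24),
                         late_range = c(26, 43)) {
  if (early_range[2] >= late_range[1] && early_range[1] <= late_range[2]) {
    abort("`early_range` and `late_range` must be disjoint")
  }
  weekly <- tibble::as_tibble(weekly)
  early <- weekly[weekly$iso_week >= early_range[1] &
                    weekly$iso_week <= early_range[2], ]
  late <- weekly[weekly$iso_week >= late_range[1] &
                   weekly$iso_week <= late_range[2], ]
  if (nrow(early) == 0) {
    warn("no weeks in the early range; late-only analysis")
  }
  list(early = early, late = late)
}

#' Assign ND / M / D diapause groups around the cut-off week
#'
#' With the 50% cut-off in week *n*, weeks n-1..n+1 hold a mix of diapausing
#' and non-diapausing eggs (group M), earlier weeks are non-diapausing (ND)
#' and later weeks diapausing (D). Labels are produced only for observed
#' weeks.
#'
#' @param cutoff_week the cut-off week *n*.
#' @param weeks integer vector of observed weeks.
#' @return a tibble with `iso_week` and `group` (factor ND/M/D).
#' @export
assign_groups <- function(cutoff_week, weeks) {
  stopifnot(length(cutoff_week) == 1, !is.na(cutoff_week))
  weeks <- sort(unique(as.integer(weeks)))
  group <- dplyr::case_when(
    weeks < cutoff_week - 1 ~ "ND",
    weeks > cutoff_week + 1 ~ "D",
    TRUE ~ "M"
  )
  tibble::tibble(
    iso_week = weeks,
    group = factor(group, levels = c("ND", "M", "D"))
  )
}
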