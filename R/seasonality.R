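#' Read daily meteorological records
#'
#' CSV columns: `date` (ISO 8601), `tmin_C`, `tmax_C`, `sunshine_min`,
#' `rainfall_mm`. Rows must satisfy tmin <= tmax, sunshine >= 0 and
#' rainfall >= 0.
#'
#' @param path file path.
#' @return a validated tibble of daily records.
#' @export
read_meteo <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  days <- readr::read_csv(
    path,
    col_types = readr::cols(
      date = readr::col_date(),
      tmin_C = readr::col_double(),
      tmax_C = readr::col_double(),
      sunshine_min = readr::col_double(),
      rainfall_mm = readr::col_double()
    ),
    progress = FALSE
  )
  validate_meteo(days, source = path)
}

#' Validate daily meteorological records
#'
#' @param days a data frame with `date`, `tmin_C`, `tmax_C`,
#'   `sunshine_min`, `rainfall_mm`.
#' @param source label for error messages.
#' @return the validated tibble.
#' @export
validate_meteo <- function(days, source = "meteo records") {
  days <- tibble::as_tibble(days)
  req <- c("date", "tmin_C", "tmax_C", "sunshine_min", "rainfall_mm")
  miss <- setdiff(req, names(days))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s): %s", source,
                  paste(miss, collapse = ", ")))
  }
  days$date <- as.Date(days$date)
  bad <- which(days$tmin_C > days$tmax_C | days$sunshine_min < 0 |
                 days$rainfall_mm < 0 | is.na(days$date))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: %d invalid row(s) (need tmin <= tmax, sunshine >= 0, rainfall >= 0): rows %s",
      source, length(bad), paste(bad, collapse = ", ")
    ))
  }
  days
}

#' Weekly meteorological aggregates
#'
#' Collapses daily records to the per-ISO-week covariates of the
#' surveillance analysis: mean/min/max of the daily minima and maxima
#' (`avTmin`, `minTmin`, `maxTmin`, `avTmax`, `minTmax`, `maxTmax`),
#' mean and cumulative sunshine (`avSun`, `cumulSun`, minutes) and rainfall
#' (`avRain`, `cumulRain`, mm). Weeks with fewer than 7 days are aggregated
#' over the available days and flagged `partial`. When a [site()] is given,
#' the weekly mean photoperiod `avPhotoperiod_min` is appended.
#'
#' @param days a validated daily meteo tibble.
#' @param site optional [site()] for photoperiod.
#' @param zenith_deg passed to [day_length_min()].
#' @return a tibble with one row per ISO week.
#' @export
weekly_meteo <- function(days, site = NULL, zenith_deg = 90.567) {
  days <- validate_meteo(days)
  wk <- iso_week_of(days$date)
  days$iso_year <- wk$iso_year
  days$iso_week <- wk$iso_week
  out <- days |>
    dplyr::group_by(.data$iso_year, .data$iso_week) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      avTmin = mean(.data$tmin_C),
      avTmax = mean(.data$tmax_C),
      minTmin = min(.data$tmin_C),
      minTmax = min(.data$tmax_C),
      maxTmin = max(.data$tmin_C),
      maxTmax = max(.data$tmax_C),
      avSun = mean(.data$sunshine_min),
      cumulSun = sum(.data$sunshine_min),
      avRain = mean(.data$rainfall_mm),
      cumulRain = sum(.data$rainfall_mm),
      .groups = "drop"
    ) |>
    dplyr::mutate(partial = .data$n_days < 7L) |>
    dplyr::arrange(.data$iso_year, .data$iso_week)
  if (any(out$partial)) {
    inform(sprintf("weekly_meteo: %d partial week(s) aggregated over < 7 days",
                   sum(out$partial)))
  }
  if (!is.null(site)) {
    out$avPhotoperiod_min <- mapply(
      function(y, w) weekly_photoperiod(y, w, site, zenith_deg)$av_daylength_min,
      out$iso_year, out$iso_week
    )
  }
  out
}

#' Egg-laying activity temperature threshold
#'
#' Over the weeks in which eggs were collected, takes the minimum of the
#' weekly average minimal temperatures and the minimum of the weekly
#' average maximal temperatures, and returns their mean: the temperature
#' above which oviposition activity was observed (e.g. minima of 4 and
#' 11 degrees C give a 7.5 degrees C threshold).
#'
#' @param egg_weeks tibble with `iso_year`, `iso_week` of egg-positive weeks.
#' @param meteo_weeks a [weekly_meteo()] tibble.
#' @return a list: `threshold_C`, `min_avTmin`, `min_avTmax`, `n_weeks`.
#' @export
activity_threshold <- function(egg_weeks, meteo_weeks) {
  egg_weeks <- dplyr::distinct(
    tibble::as_tibble(egg_weeks)[, c("iso_year", "iso_week")]
  )
  joined <- dplyr::inner_join(egg_weeks, tibble::as_tibble(meteo_weeks),
                              by = c("iso_year", "iso_week"))
  if (nrow(joined) == 0) {
    abort("no overlap between egg-positive weeks and meteorological weeks")
  }
  lo_min <- min(joined$avTmin)
  lo_max <- min(joined$avTmax)
  list(
    threshold_C = mean(c(lo_min, lo_max)),
    min_avTmin = lo_min,
    min_avTmax = lo_max,
    n_weeks = nrow(joined)
  )
}

#' Binned egg-abundance series
#'
#' Bins per-week egg counts into 1- or 2-week bins (two-week bins start at
#' the first observed week of each season) and summarises the season:
#' total, and mean and SD of the per-bin counts.
#'
#' @param counts a tibble with `iso_year`, `iso_week`, `egg_count`
#'   (pre-summed over traps), or a validated egg tibble (each row one egg).
#' @param bin_width 1 or 2 weeks.
#' @return an `abundance_series` list: `bins` (tibble `iso_year`,
#'   `start_week`, `egg_count`), `bin_width`, and per-season `summary`
#'   (`iso_year`, `total`, `mean_per_bin`, `sd_per_bin`, `n_bins`).
#' @export
abundance_series <- function(counts, bin_width = 2) {
  if (!bin_width %in% c(1, 2)) abort("`bin_width` must be 1 or 2")
  counts <- tibble::as_tibble(counts)
  if (!"egg_count" %in% names(counts)) {
    # egg records: one row per egg
    counts <- counts |>
      dplyr::count(.data$iso_year, .data$iso_week, name = "egg_count")
  }
  binned <- counts |>
    dplyr::group_by(.data$iso_year) |>
    dplyr::mutate(
      start_week = min(.data$iso_week) +
        bin_width * ((.data$iso_week - min(.data$iso_week)) %/% bin_width)
    ) |>
    dplyr::group_by(.data$iso_year, .data$start_week) |>
    dplyr::summarise(egg_count = sum(.data$egg_count), .groups = "drop") |>
    dplyr::arrange(.data$iso_year, .data$start_week)
  summary <- binned |>
    dplyr::group_by(.data$iso_year) |>
    dplyr::summarise(
      total = sum(.data$egg_count),
      mean_per_bin = mean(.data$egg_count),
      sd_per_bin = if (dplyr::n() > 1) sd(.data$egg_count) else 0,
      n_bins = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(bins = binned, bin_width = bin_width, summary = summary),
    class = "abundance_series"
  )
}

#' @export
print.abundance_series <- function(x, ...) {
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf(
      "Season %d: %d eggs in %d bin(s) of %d week(s); mean %.0f +/- %.0f per bin\n",
      s$iso_year, s$total, s$n_bins, x$bin_width, s$mean_per_bin, s$sd_per_bin
    ))
  }
  invisible(x)
}
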