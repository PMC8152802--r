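#' ISO 8601 week date of a calendar date
#'
#' Maps calendar dates to the ISO 8601 week date system: weeks start on
#' Monday and week 1 is the week containing the year's first Thursday.
#' Near 1 January the ISO week-year can differ from the calendar year
#' (e.g. 2021-01-01 belongs to week 53 of ISO year 2020).
#'
#' @param date a `Date` vector (or anything `as.Date()` accepts).
#' @return a tibble with columns `iso_year` and `iso_week` (integers),
#'   one row per input date.
#' @examples
#' iso_week_of(as.Date("2020-03-02")) # week 10 of 2020
#' iso_week_of(as.Date("2021-01-01")) # week 53 of 2020
#' @export
iso_week_of <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) {
    abort("`date` contains values that cannot be parsed as dates.")
  }
  tibble::tibble(
    iso_year = as.integer(format(date, "%G")),
    iso_week = as.integer(format(date, "%V"))
  )
}

#' First day (Monday) of an ISO week
#'
#' @param iso_year ISO week-year (integer vector).
#' @param iso_week ISO week number, 1--53 (integer vector).
#' @return a `Date` vector of Mondays.
#' @export
iso_week_start <- function(iso_year, iso_week) {
  iso_year <- as.integer(iso_year)
  iso_week <- as.integer(iso_week)
  if (any(is.na(iso_year)) || any(is.na(iso_week))) {
    abort("`iso_year` and `iso_week` must be integers.")
  }
  if (any(iso_week < 1L | iso_week > 53L)) {
    abort("`iso_week` must be in 1..53.")
  }
  # week 1 contains 4 January; back up to its Monday, then step forward
  jan4 <- as.Date(sprintf("%d-01-04", iso_year))
  monday1 <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  start <- monday1 + 7L * (iso_week - 1L)
  bad <- as.integer(format(start, "%V")) != iso_week |
    as.integer(format(start, "%G")) != iso_year
  if (any(bad)) {
    abort(sprintf(
      "invalid ISO week(s): %s",
      paste(sprintf("%d-W%02d", iso_year[bad], iso_week[bad]), collapse = ", ")
    ))
  }
  start
}

#' All seven dates (Monday--Sunday) of an ISO week
#'
#' @inheritParams iso_week_start
#' @return a `Date` vector of length 7.
#' @export
iso_week_dates <- function(iso_year, iso_week) {
  stopifnot(length(iso_year) == 1L, length(iso_week) == 1L)
  iso_week_start(iso_year, iso_week) + 0:6
}
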