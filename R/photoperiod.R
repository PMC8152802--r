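#' Define an observation site
#'
#' @param name site label.
#' @param latitude_deg latitude in decimal degrees, -90..90 (north positive).
#' @param longitude_deg longitude in decimal degrees, -180..180 (east positive).
#' @return a `site` object (named list).
#' @examples
#' site("Strasbourg", 48.58, 7.75)
#' @export
site <- function(name, latitude_deg, longitude_deg) {
  if (!is.numeric(latitude_deg) || abs(latitude_deg) > 90) {
    abort("`latitude_deg` must be in [-90, 90].")
  }
  if (!is.numeric(longitude_deg) || abs(longitude_deg) > 180) {
    abort("`longitude_deg` must be in [-180, 180].")
  }
  structure(
    list(
      name = as.character(name),
      latitude_deg = as.numeric(latitude_deg),
      longitude_deg = as.numeric(longitude_deg)
    ),
    class = "site"
  )
}

#' Default site: Strasbourg, northeastern France
#'
#' Reference location for reproduction runs of the Alsace *Aedes japonicus*
#' surveillance analysis; the Reichstett trap site (48.64 N) differs from the
#' city coordinates by a negligible amount of day length.
#'
#' @return a [site()] object.
#' @export
site_strasbourg <- function() site("Strasbourg", 48.58, 7.75)

# Julian day number at a given UTC hour (Gregorian calendar)
.julian_day <- function(date, hour_utc = 12) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  a <- (14L - m) %/% 12L
  yy <- y + 4800L - a
  mm <- m + 12L * a - 3L
  jdn <- d + (153L * mm + 2L) %/% 5L + 365L * yy + yy %/% 4L -
    yy %/% 100L + yy %/% 400L - 32045L
  jdn + (hour_utc - 12) / 24
}

#' Apparent solar declination
#'
#' Declination of the sun from the standard truncated-series solar position
#' model (mean longitude, equation of centre, apparent longitude and true
#' obliquity as polynomial/harmonic functions of the Julian century), accurate
#' to well under 0.1 degrees over the surveillance years. Evaluated once per
#' day; `hour_utc` selects the evaluation epoch (default solar noon at
#' Greenwich).
#'
#' @param date a `Date` vector.
#' @param hour_utc decimal UTC hour at which to evaluate (default 12).
#' @return declination in radians.
#' @export
solar_declination <- function(date, hour_utc = 12) {
  jc <- (.julian_day(date, hour_utc) - 2451545) / 36525
  mean_long <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  mean_anom <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ma <- mean_anom * pi / 180
  eq_centre <- sin(ma) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * ma) * (0.019993 - 0.000101 * jc) +
    sin(3 * ma) * 0.000289
  true_long <- mean_long + eq_centre
  omega <- (125.04 - 1934.136 * jc) * pi / 180
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)
  obliq0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- (obliq0 + 0.00256 * cos(omega)) * pi / 180
  asin(sin(obliq) * sin(app_long * pi / 180))
}

#' Astronomical day length in minutes
#'
#' Sunrise-to-sunset duration from the sunrise equation,
#' \eqn{\cos \omega_0 = (\cos z - \sin\phi \sin\delta)/(\cos\phi \cos\delta)},
#' with duration \eqn{2\omega_0 / 15^\circ \times 60} minutes. Polar day and
#' polar night clip to 1440 and 0. Declination is evaluated once per day at
#' the site's local solar noon.
#'
#' The default zenith angle of 90 deg 34 min (90.567 deg) places the *centre*
#' of the solar disc at the horizon after standard atmospheric refraction;
#' this is the convention that reproduces the day lengths quoted by the
#' Strasbourg surveillance study. The common upper-limb almanac convention
#' (90.833 deg, refraction plus solar semidiameter) is available by argument,
#' as is the purely geometric 90 deg.
#'
#' @param date a `Date` vector.
#' @param site a [site()] object.
#' @param zenith_deg solar zenith angle defining sunrise/sunset, in (0, 180).
#' @return day length(s) in minutes, in \[0, 1440\].
#' @examples
#' day_length_min(as.Date("2019-09-05"), site_strasbourg())
#' @export
day_length_min <- function(date, site, zenith_deg = 90.567) {
  stopifnot(inherits(site, "site"))
  if (zenith_deg <= 0 || zenith_deg >= 180) {
    abort("`zenith_deg` must lie in (0, 180).")
  }
  noon_utc <- 12 - site$longitude_deg / 15
  decl <- solar_declination(date, hour_utc = noon_utc)
  phi <- site$latitude_deg * pi / 180
  cos_h <- (cos(zenith_deg * pi / 180) - sin(phi) * sin(decl)) /
    (cos(phi) * cos(decl))
  out <- numeric(length(cos_h))
  out[cos_h >= 1] <- 0      # polar night
  out[cos_h <= -1] <- 1440  # polar day
  mid <- cos_h > -1 & cos_h < 1
  out[mid] <- 2 * acos(cos_h[mid]) * 180 / pi / 15 * 60
  out
}

#' Weekly mean photoperiod
#'
#' Mean sunrise-to-sunset day length over the seven days (Monday--Sunday)
#' of an ISO week at a site; the `avPhotoperiod` covariate of the
#' surveillance analysis.
#'
#' @inheritParams iso_week_start
#' @inheritParams day_length_min
#' @return a one-row tibble with `iso_year`, `iso_week`, `av_daylength_min`
#'   and a formatted `hhmm` string.
#' @examples
#' weekly_photoperiod(2019, 36, site_strasbourg()) # about 13 h 07 min
#' @export
weekly_photoperiod <- function(iso_year, iso_week, site, zenith_deg = 90.567) {
  days <- iso_week_dates(iso_year, iso_week)
  avg <- mean(day_length_min(days, site, zenith_deg))
  tibble::tibble(
    iso_year = as.integer(iso_year),
    iso_week = as.integer(iso_week),
    av_daylength_min = avg,
    hhmm = format_hm(avg)
  )
}

#' Format minutes as "H h MM min"
#'
#' @param minutes numeric vector of durations in minutes.
#' @return character vector like `"13 h 07 min"` (minutes rounded).
#' @export
format_hm <- function(minutes) {
  m <- floor(minutes + 0.5) # round half up, as almanac tables do
  sprintf("%d h %02d min", m %/% 60, m %% 60)
}
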