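# Covariate reference frames: sun azimuth (monthly/hourly table) and wind
# direction suitability for olfactory piloting.
#
# Wind convention: `wind_from` is the direction the wind blows FROM
# (meteorological convention). Air moving from the owner towards the dog
# therefore arrives from the owner's bearing as seen from the dog, i.e. from
# azimuth B.

# Low-accuracy solar position (NOAA-style): solar declination and hour angle
# to azimuth. Good to well under a degree at mid-latitudes, which is all the
# monthly reference table needs.
solar_declination <- function(doy, hour) {
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

month_doy15 <- function(month) {
  c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)[month]
}

#' Solar azimuth at a given month, hour and location
#'
#' Computed for the 15th day of the month at the given local solar hour.
#' Returns the azimuth in degrees true (clockwise from geographic north), or
#' `NA` when the sun is below the horizon at that time.
#'
#' @param month 1-12.
#' @param hour local solar hour (0-23; solar noon is 12).
#' @param lat,lon degrees (longitude only documents the reference; local
#'   solar time already absorbs it).
#' @return degrees true in `[0, 360)`, or `NA` if the sun is down.
#' @export
sun_azimuth <- function(month, hour, lat = 49.8, lon = 15.5) {
  stopifnot(month %in% 1:12, hour >= 0, hour <= 24)
  doy <- month_doy15(month)
  dec <- solar_declination(doy, hour)
  phi <- deg2rad(lat)
  H <- deg2rad(15 * (hour - 12))
  sin_el <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H)
  if (sin_el <= 0) return(NA_real_)   # sun below horizon
  az <- rad2deg(atan2(sin(H), cos(H) * sin(phi) - tan(dec) * cos(phi))) + 180
  wrap360(az)
}

#' Monthly/hourly sun-azimuth reference table
#'
#' One row per (month, hour) with the sun above the horizon, computed for the
#' 15th day of each month. The default reference location is 49.8 N, 15.5 E
#' (central Czech Republic).
#'
#' @inheritParams sun_azimuth
#' @return data.frame with columns `month`, `hour`, `sun_azimuth` (degrees
#'   true).
#' @export
sun_table <- function(lat = 49.8, lon = 15.5) {
  grid <- expand.grid(hour = 0:23, month = 1:12)
  az <- mapply(function(m, h) sun_azimuth(m, h, lat, lon),
               grid$month, grid$hour)
  out <- data.frame(month = grid$month, hour = grid$hour, sun_azimuth = az)
  out[!is.na(out$sun_azimuth), , drop = FALSE]
}

#' Orientation of a compass run relative to the sun
#'
#' Converts the magnetic compass-run azimuth to true (adding the declination)
#' and subtracts the tabulated sun azimuth at the nearest daylight hour of
#' the trial's month. Night-time trials (no table entry at the nearest hour)
#' return `NA` and should be excluded.
#'
#' @param azimuth_c magnetic azimuth of the compass run, degrees.
#' @param month,hour trial month (1-12) and local solar hour (may be
#'   fractional; the nearest tabulated hour is used).
#' @param table output of [sun_table()].
#' @param declination degrees east positive.
#' @return degrees in `[0, 360)`, or `NA` for night-time trials.
#' @export
relative_to_sun <- function(azimuth_c, month, hour, table = sun_table(),
                            declination = 0) {
  rows <- table[table$month == month, , drop = FALSE]
  if (!nrow(rows)) return(NA_real_)
  k <- which.min(abs(rows$hour - hour))
  if (abs(rows$hour[k] - hour) > 0.5) return(NA_real_)  # nearest hour is dark
  true_c <- wrap360(azimuth_c + declination)
  wrap360(true_c - rows$sun_azimuth[k])
}

#' Wind suitability for olfactory piloting
#'
#' A scouting return could in principle be guided by smell only if the wind
#' carries air from the owner to the dog at the turning point: the wind must
#' blow from within `halfwidth` degrees of azimuth B (the owner's bearing
#' from the dog). Returns `NA` ("not assessable") when no wind was detected.
#'
#' @param azimuth_b magnetic bearing from the turning point to the owner.
#' @param wind_from direction the wind blows from, degrees magnetic, or `NA`.
#' @param halfwidth sector half-width in degrees (default 22.5, one of eight
#'   45-degree bins centred on the 45s).
#' @return `TRUE`, `FALSE`, or `NA` when not assessable.
#' @export
wind_suitable <- function(azimuth_b, wind_from, halfwidth = 22.5) {
  ifelse(is.na(wind_from), NA,
         abs(circ_diff(wind_from, azimuth_b)) <= halfwidth)
}

#' Wind-direction bin
#'
#' Assigns a wind direction to one of eight 45-degree bins centred on 0, 45,
#' ..., 315 degrees.
#'
#' @param wind_from degrees in `[0, 360)` or `NA`.
#' @return bin centre in degrees, or `NA`.
#' @export
wind_bin <- function(wind_from) {
  ifelse(is.na(wind_from), NA_real_, wrap360(round(wind_from / 45) * 45))
}
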