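# Azimuths A, B and C (the compass run), cardinal sectors and axes.
# All azimuths are magnetic: true bearing minus the per-trial declination.

#' Azimuth A: magnetic direction of the initial outbound segment
#'
#' Bearing from the dog's first excursion point to the fix closest to 5 s
#' later (2nd point after the start at 2.5 s sampling, 1st at 5.0 s).
#'
#' @param exc an `excursion`.
#' @param declination degrees east positive; defaults to the excursion's own.
#' @param config a [homing_config()].
#' @return magnetic bearing in degrees `[0, 360)`.
#' @export
azimuth_a <- function(exc, declination = exc$declination,
                      config = homing_config()) {
  target <- exc$time[1] + config$azimuth_a_lag_s
  k <- which.min(abs(exc$time - target))
  if (abs(exc$time[k] - target) > exc$nominal_interval / 2 || k == 1L) {
    stop("missing fix: no point within half an interval of start + ",
         config$azimuth_a_lag_s, " s")
  }
  magnetic_bearing(true_bearing(exc$x[1], exc$y[1], exc$x[k], exc$y[k]),
                   declination)
}

#' Azimuth B: magnetic direction of the owner from the turning point
#'
#' @inheritParams azimuth_a
#' @return magnetic bearing in degrees `[0, 360)`.
#' @export
azimuth_b <- function(exc, declination = exc$declination) {
  tp <- exc$turning_point
  if (is.na(tp)) stop("turning point not located; call locate_turning() first")
  if (exc$x[tp] == exc$owner_x && exc$y[tp] == exc$owner_y) {
    stop("undefined bearing: turning point coincides with owner")
  }
  magnetic_bearing(true_bearing(exc$x[tp], exc$y[tp], exc$owner_x, exc$owner_y),
                   declination)
}

#' Extract the compass run (azimuth C)
#'
#' Walks forward from a start point (by default the turning point): at each
#' candidate point k (k >= start + 2) the step heading (k to k+1) is compared
#' with the chord bearing (start to k); the run terminates at the first k
#' where the absolute circular difference exceeds `deflection_deg` and
#' remains above it for `persistence_pts` further points ("without an
#' immediate return"). Candidates whose chord from the start is shorter than
#' `min_chord_m`, or whose step is shorter than `min_step_m`, are skipped:
#' bearings at displacements comparable to GPS noise are meaningless. If no
#' sustained deflection occurs the run extends to the end of the scanned
#' range and is flagged `truncated`.
#'
#' @param exc an `excursion` with a located turning point.
#' @param declination degrees east positive.
#' @param from,to point-index range to scan (defaults: turning point to
#'   excursion end).
#' @param config a [homing_config()].
#' @return list with `azimuth_c` (degrees magnetic), `length_m` (chord or
#'   along-track path per `config$run_length_measure`), `end_index` and
#'   `truncated`.
#' @export
extract_compass_run <- function(exc, declination = exc$declination,
                                from = exc$turning_point,
                                to = length(exc$x),
                                config = homing_config()) {
  if (is.na(from)) stop("turning point not located")
  if (to - from < 2) stop("need at least 3 points after the run start")
  x <- exc$x; y <- exc$y
  chord_len <- sqrt((x[from:to] - x[from])^2 + (y[from:to] - y[from])^2)
  deflect <- function(k) {
    # absolute deflection of step k->k+1 from the chord from->k
    if (k >= to) return(NA_real_)
    step <- sqrt((x[k + 1] - x[k])^2 + (y[k + 1] - y[k])^2)
    chord <- chord_len[k - from + 1L]
    if (chord < config$min_chord_m || step < config$min_step_m) return(0)
    abs(circ_diff(true_bearing(x[k], y[k], x[k + 1], y[k + 1]),
                  true_bearing(x[from], y[from], x[k], y[k])))
  }
  end <- to
  truncated <- TRUE
  for (k in seq(from + 2L, to - 1L)) {
    if (deflect(k) > config$deflection_deg) {
      persist <- TRUE
      for (j in seq_len(config$persistence_pts)) {
        dj <- deflect(k + j)
        if (is.na(dj) || dj <= config$deflection_deg) { persist <- FALSE; break }
      }
      if (persist) { end <- k; truncated <- FALSE; break }
    }
  }
  if (chord_len[end - from + 1L] <= 0) {
    stop("undefined bearing: run end coincides with run start")
  }
  az <- magnetic_bearing(true_bearing(x[from], y[from], x[end], y[end]),
                         declination)
  len <- if (config$run_length_measure == "chord") {
    chord_len[end - from + 1L]
  } else {
    exc$cum[end] - exc$cum[from]
  }
  list(azimuth_c = az, length_m = len, end_index = end, truncated = truncated)
}

#' Cardinal sector of an azimuth
#'
#' Azimuths are rounded half-up to whole degrees, then mapped by the closed
#' integer ranges ~north 316-45, ~east 46-135, ~south 136-225, ~west 226-315
#' (0 and 360 are north).
#'
#' @param azimuth degrees in `[0, 360)` (vectorised).
#' @return character vector in `c("N", "E", "S", "W")`.
#' @export
sector_of <- function(azimuth) {
  a <- floor(wrap360(azimuth) + 0.5) %% 360   # round half-up, 360 -> 0
  ifelse(a <= 45 | a >= 316, "N",
         ifelse(a <= 135, "E",
                ifelse(a <= 225, "S", "W")))
}

#' Axis class (north-south vs east-west) of an azimuth
#'
#' @inheritParams sector_of
#' @return character vector in `c("NS", "EW")`.
#' @export
axis_of <- function(azimuth) {
  ifelse(sector_of(azimuth) %in% c("N", "S"), "NS", "EW")
}
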