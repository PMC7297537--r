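# GPX 1.1 track I/O and the per-trial metadata table.

GPX_NS <- "http://www.topografix.com/GPX/1/1"

#' Construct a track
#'
#' A track is an ordered sequence of timestamped geographic points for one
#' animal or person. Times are seconds since the first fix and must be
#' strictly increasing.
#'
#' @param time numeric vector, seconds since track start (first element 0).
#' @param lat,lon degrees WGS84.
#' @param nominal_interval nominal sampling interval in seconds (2.5 or 5.0
#'   for the collars used; any positive value accepted).
#' @param start_time optional POSIXct of the first fix (UTC); carried for GPX
#'   round trips and the sun analysis.
#' @return an object of class `track`.
#' @export
track <- function(time, lat, lon, nominal_interval = 5.0, start_time = NULL) {
  n <- length(time)
  if (n < 2) stop("a track needs at least 2 points")
  if (length(lat) != n || length(lon) != n) stop("time/lat/lon length mismatch")
  if (!all(is.finite(time)) || any(time < 0)) stop("times must be finite and non-negative")
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    stop("track times not strictly increasing at index ", bad[1] + 1L)
  }
  if (any(!is.finite(lat)) || any(abs(lat) > 90)) stop("latitude out of [-90, 90]")
  if (any(!is.finite(lon)) || any(abs(lon) > 180)) stop("longitude out of [-180, 180]")
  structure(list(points = data.frame(time = time, lat = lat, lon = lon),
                 nominal_interval = nominal_interval,
                 start_time = start_time),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat("<track> ", nrow(x$points), " points, ",
      round(max(x$points$time), 1), " s, nominal interval ",
      x$nominal_interval, " s\n", sep = "")
  invisible(x)
}

#' Read a GPX 1.1 track file
#'
#' All track segments are concatenated in time order; times are converted to
#' seconds since the first fix. Fractional-second timestamps are preserved.
#' Gaps longer than 3x the nominal interval are reported with a message but
#' never interpolated; downstream speeds always use actual time deltas.
#'
#' @param path GPX file path.
#' @param nominal_interval sampling interval in seconds; if `NULL`, inferred
#'   as the median time delta.
#' @return a [track()].
#' @export
read_gpx <- function(path, nominal_interval = NULL) {
  doc <- xml2::read_xml(path)
  pts <- xml2::xml_find_all(doc, ".//d1:trkseg/d1:trkpt",
                            ns = c(d1 = GPX_NS))
  if (length(pts) == 0) {
    # tolerate GPX written without the default namespace
    pts <- xml2::xml_find_all(doc, ".//trkseg/trkpt")
  }
  if (length(pts) < 2) stop("GPX format error: fewer than 2 track points in ", path)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tnode <- xml2::xml_find_first(pts, "./d1:time", ns = c(d1 = GPX_NS))
  tstr <- xml2::xml_text(tnode)
  if (anyNA(tstr) || any(tstr == "")) {
    stop("GPX format error: track point without timestamp in ", path)
  }
  tt <- as.POSIXct(tstr, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(tt)) stop("GPX format error: unparseable timestamp in ", path)
  ord <- order(tt)
  tt <- tt[ord]; lat <- lat[ord]; lon <- lon[ord]
  secs <- as.numeric(difftime(tt, tt[1], units = "secs"))
  if (is.null(nominal_interval)) {
    nominal_interval <- stats::median(diff(secs))
  }
  gaps <- which(diff(secs) > 3 * nominal_interval)
  if (length(gaps)) {
    message(length(gaps), " gap(s) > 3x nominal interval in ", basename(path),
            " (first after point ", gaps[1], "); kept, not interpolated")
  }
  track(secs, lat, lon, nominal_interval = nominal_interval, start_time = tt[1])
}

#' Write a track as GPX 1.1
#'
#' @param trk a [track()].
#' @param path output file.
#' @param start_time POSIXct (UTC) of the first fix; defaults to the track's
#'   own `start_time` or a fixed epoch.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(trk, path, start_time = NULL) {
  if (is.null(start_time)) start_time <- trk$start_time
  if (is.null(start_time)) {
    start_time <- as.POSIXct("2015-06-15 08:00:00", tz = "UTC")
  }
  abs_t <- start_time + trk$points$time
  tstr <- format(abs_t, "%Y-%m-%dT%H:%M:%OS2Z", tz = "UTC")
  pts <- sprintf('   <trkpt lat="%.8f" lon="%.8f"><time>%s</time></trkpt>',
                 trk$points$lat, trk$points$lon, tstr)
  xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
           sprintf('<gpx version="1.1" creator="compassrun" xmlns="%s">', GPX_NS),
           ' <trk>', '  <trkseg>', pts, '  </trkseg>', ' </trk>', '</gpx>')
  writeLines(xml, path)
  invisible(path)
}

#' Construct a trial record
#'
#' One field trial: a dog track, the owner's track, and trial covariates.
#' Absent wind is encoded as `NA` (meaning "no wind detected"), never as 0
#' degrees.
#'
#' @param dog_id,sex,breed,shoulder_height,site_id,familiarity trial
#'   covariates; `sex` one of "M"/"F", `familiarity` "familiar"/"unfamiliar".
#' @param wind_from direction the wind blows from, degrees magnetic in
#'   `[0, 360)`, or `NA` when no wind was detected.
#' @param wind_speed m/s or `NA`.
#' @param datetime POSIXct of the trial start (UTC).
#' @param utc_offset hours to add to UTC for local time (sun analysis only).
#' @param declination magnetic declination at the site, degrees east positive.
#' @param dog_track,owner_track [track()] objects.
#' @param trial_id optional identifier.
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(dog_id, sex, breed, shoulder_height, site_id,
                         familiarity, wind_from, wind_speed, datetime,
                         declination, dog_track, owner_track,
                         utc_offset = 0, trial_id = NA_character_) {
  if (!is.na(wind_from) && (wind_from < 0 || wind_from >= 360)) {
    stop("wind_from must be in [0, 360) or NA")
  }
  if (!is.finite(declination)) stop("declination must be finite")
  stopifnot(inherits(dog_track, "track"), inherits(owner_track, "track"))
  structure(list(trial_id = trial_id, dog_id = dog_id, sex = sex,
                 breed = breed, shoulder_height = shoulder_height,
                 site_id = site_id, familiarity = familiarity,
                 wind_from = wind_from, wind_speed = wind_speed,
                 datetime = datetime, utc_offset = utc_offset,
                 declination = declination,
                 dog_track = dog_track, owner_track = owner_track),
            class = "trial_record")
}

#' Read a trial metadata table and its referenced GPX files
#'
#' The table is a UTF-8 CSV with one row per trial and the columns
#' `trial_id, dog_id, sex, breed, shoulder_height_cm, site_id, familiarity,
#' wind_from_deg, wind_speed_ms, datetime_utc, utc_offset_h,
#' declination_deg, dog_gpx, owner_gpx`. GPX paths are resolved relative to
#' the CSV's directory. An empty `wind_from_deg` cell means "no wind
#' detected" and is loaded as `NA`.
#'
#' @param path CSV file path.
#' @return list of [trial_record()] objects.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(wind_from_deg = "numeric"),
                         na.strings = c("", "NA"))
  req <- c("trial_id", "dog_id", "sex", "breed", "shoulder_height_cm",
           "site_id", "familiarity", "wind_from_deg", "wind_speed_ms",
           "datetime_utc", "utc_offset_h", "declination_deg",
           "dog_gpx", "owner_gpx")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop("trial table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  base <- dirname(path)
  failures <- character(0)
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    rec <- tryCatch({
      dg <- read_gpx(file.path(base, row$dog_gpx))
      ow <- read_gpx(file.path(base, row$owner_gpx))
      trial_record(
        trial_id = as.character(row$trial_id), dog_id = as.character(row$dog_id),
        sex = row$sex, breed = row$breed,
        shoulder_height = row$shoulder_height_cm, site_id = as.character(row$site_id),
        familiarity = row$familiarity,
        wind_from = row$wind_from_deg, wind_speed = row$wind_speed_ms,
        datetime = as.POSIXct(row$datetime_utc, tz = "UTC"),
        utc_offset = row$utc_offset_h,
        declination = row$declination_deg,
        dog_track = dg, owner_track = ow)
    }, error = function(e) {
      failures <<- c(failures, paste0("row ", i, " (", row$trial_id, "): ",
                                      conditionMessage(e)))
      NULL
    })
    out[[i]] <- rec
  }
  if (length(failures)) {
    stop("failed to load ", length(failures), " trial(s):\n  ",
         paste(failures, collapse = "\n  "))
  }
  out
}
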