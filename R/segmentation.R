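# Excursion detection and turning-point location.
#
# An excursion opens at the first dog fix >= 100 m (straight line) from the
# concurrent (time-interpolated) owner position; the owner's location is
# frozen at that instant and the excursion closes at the first later dog fix
# within 10 m of that frozen location. Excursions shorter than 200 m of path
# and excursions with no return before the track ends are discarded.

new_excursion <- function(x, y, time, start_index, end_index,
                          owner_x, owner_y, nominal_interval, declination,
                          trial_id = NA_character_, dog_id = NA_character_) {
  cum <- cum_path_length(x, y)
  structure(list(x = x, y = y, time = time,
                 start_index = start_index, end_index = end_index,
                 owner_x = owner_x, owner_y = owner_y,
                 cum = cum, total_length = cum[length(cum)],
                 nominal_interval = nominal_interval,
                 declination = declination,
                 trial_id = trial_id, dog_id = dog_id,
                 turning_segment = NA_integer_,
                 turning_point = NA_integer_),
            class = "excursion")
}

#' @export
print.excursion <- function(x, ...) {
  cat("<excursion> ", length(x$x), " points, ", round(x$total_length), " m",
      if (!is.na(x$turning_point)) paste0(", turning point at index ", x$turning_point),
      "\n", sep = "")
  invisible(x)
}

#' Detect excursions in one trial
#'
#' @param trial a [trial_record()].
#' @param frame a [local_frame()]; defaults to a frame centred on the first
#'   owner fix.
#' @param config a [homing_config()].
#' @param quiet suppress messages about discarded excursions.
#' @return list of `excursion` objects (possibly empty).
#' @export
detect_excursions <- function(trial, frame = NULL, config = homing_config(),
                              quiet = FALSE) {
  if (nrow(trial$dog_track$points) < 2 || nrow(trial$owner_track$points) < 2) {
    stop("empty or degenerate tracks")
  }
  if (is.null(frame)) {
    frame <- local_frame(trial$owner_track$points$lat[1],
                         trial$owner_track$points$lon[1])
  }
  dog <- project_track(trial$dog_track, frame)
  own <- project_track(trial$owner_track, frame)
  ox <- stats::approx(own$time, own$x, xout = dog$time, rule = 2, ties = "ordered")$y
  oy <- stats::approx(own$time, own$y, xout = dog$time, rule = 2, ties = "ordered")$y
  sep <- sqrt((dog$x - ox)^2 + (dog$y - oy)^2)

  out <- list()
  n <- nrow(dog)
  i <- 1L
  while (i <= n) {
    open <- which(sep[i:n] >= config$separation_m)
    if (!length(open)) break
    s <- i + open[1] - 1L
    owner_x <- ox[s]; owner_y <- oy[s]
    d_home <- sqrt((dog$x[s:n] - owner_x)^2 + (dog$y[s:n] - owner_y)^2)
    close <- which(d_home <= config$closure_m)
    if (!length(close)) {
      if (!quiet) message("unreturned excursion starting at dog point ", s,
                          " discarded (track ends before closure)")
      break
    }
    e <- s + close[1] - 1L
    exc <- new_excursion(dog$x[s:e], dog$y[s:e], dog$time[s:e],
                         start_index = s, end_index = e,
                         owner_x = owner_x, owner_y = owner_y,
                         nominal_interval = trial$dog_track$nominal_interval,
                         declination = trial$declination,
                         trial_id = trial$trial_id, dog_id = trial$dog_id)
    if (exc$total_length >= config$min_excursion_m) {
      out[[length(out) + 1L]] <- exc
    } else if (!quiet) {
      message("excursion of ", round(exc$total_length), " m < ",
              config$min_excursion_m, " m discarded")
    }
    i <- e + 1L
  }
  out
}

#' Decile speed profile of an excursion
#'
#' The excursion path is split into ten segments of equal path length.
#' Segment boundary times are linearly interpolated within steps; the mean
#' speed of a segment is its path length divided by its duration. The maximal
#' straight-line distance of each segment's points from the excursion-start
#' location (the frozen owner position) is also recorded, for the
#' turning-trajectory fallback rule.
#'
#' @param exc an `excursion`.
#' @return list with `boundaries` (11 path positions), `boundary_times`,
#'   `speeds` (10 mean speeds, m/s), `distances_from_start` (10 maxima, m),
#'   and `max_gap_s` (10 largest inter-point intervals).
#' @export
segment_profile <- function(exc) {
  L <- exc$total_length
  bounds <- L * (0:10) / 10
  bounds[11] <- L   # guard: L*10/10 can exceed L in floating point
  bt <- stats::approx(exc$cum, exc$time, xout = bounds, ties = "ordered")$y
  dur <- diff(bt)
  if (any(dur <= 0)) stop("degenerate data: zero-duration decile segment")
  speeds <- (L / 10) / dur
  mid <- (exc$cum[-length(exc$cum)] + exc$cum[-1]) / 2
  seg_of_pt <- pmin(10L, pmax(1L, findInterval(exc$cum, bounds,
                                               rightmost.closed = TRUE)))
  seg_of_step <- pmin(10L, pmax(1L, findInterval(mid, bounds,
                                                 rightmost.closed = TRUE)))
  d_start <- sqrt((exc$x - exc$owner_x)^2 + (exc$y - exc$owner_y)^2)
  dist_max <- vapply(1:10, function(k) {
    idx <- which(seg_of_pt == k)
    if (!length(idx)) return(NA_real_)
    max(d_start[idx])
  }, numeric(1))
  gaps <- diff(exc$time)
  gap_max <- vapply(1:10, function(k) {
    idx <- which(seg_of_step == k)
    if (!length(idx)) return(0)
    max(gaps[idx])
  }, numeric(1))
  # a segment with no interior point still has interpolated boundaries;
  # use the boundary positions for its distance
  if (anyNA(dist_max)) {
    bx <- stats::approx(exc$cum, exc$x, xout = bounds, ties = "ordered")$y
    by <- stats::approx(exc$cum, exc$y, xout = bounds, ties = "ordered")$y
    bd <- sqrt((bx - exc$owner_x)^2 + (by - exc$owner_y)^2)
    miss <- which(is.na(dist_max))
    dist_max[miss] <- pmax(bd[miss], bd[miss + 1])
  }
  list(boundaries = bounds, boundary_times = bt, speeds = speeds,
       distances_from_start = dist_max, max_gap_s = gap_max)
}

segment_is_improbable <- function(k, profile, config) {
  (k %in% config$improbable_segments) ||
    (profile$max_gap_s[k] > config$long_pause_s)
}

#' Locate the turning trajectory (decile segment)
#'
#' Returns the slowest decile segment unless it is improbable (in the first
#' or last decile, or containing a single pause longer than
#' `config$long_pause_s`); then the second slowest; if that is also
#' improbable, the remaining segments are considered from slowest upward and
#' the first whose maximal distance from the excursion start exceeds the
#' median point distance is returned (falling back to the farthest one).
#'
#' @param profile output of [segment_profile()].
#' @param exc the `excursion`.
#' @param config a [homing_config()].
#' @return integer segment index in 1..10.
#' @export
locate_turning_trajectory <- function(profile, exc, config = homing_config()) {
  ord <- order(profile$speeds)
  if (!segment_is_improbable(ord[1], profile, config)) return(ord[1])
  if (!segment_is_improbable(ord[2], profile, config)) return(ord[2])
  rest <- ord[-(1:2)]
  d_start <- sqrt((exc$x - exc$owner_x)^2 + (exc$y - exc$owner_y)^2)
  med <- stats::median(d_start)
  for (k in rest) {
    if (profile$distances_from_start[k] > med) return(k)
  }
  rest[which.max(profile$distances_from_start[rest])]
}

#' Locate the turning point within the turning trajectory
#'
#' Over all consecutive point pairs whose midpoint path position lies in the
#' chosen decile segment, finds the pair with the minimum speed (step length
#' over step duration) and returns the index (into the excursion points) of
#' the pair's first point. Ties break to the earliest pair.
#'
#' @param exc an `excursion`.
#' @param segment decile index from [locate_turning_trajectory()].
#' @param profile output of [segment_profile()] (recomputed if missing).
#' @return integer point index.
#' @export
locate_turning_point <- function(exc, segment, profile = NULL) {
  if (is.null(profile)) profile <- segment_profile(exc)
  lo <- profile$boundaries[segment]
  hi <- profile$boundaries[segment + 1]
  mid <- (exc$cum[-length(exc$cum)] + exc$cum[-1]) / 2
  cand <- which(mid >= lo & (if (segment == 10L) mid <= hi else mid < hi))
  if (length(cand) < 1) stop("degenerate data: turning segment has no point pair")
  step_len <- sqrt(diff(exc$x)^2 + diff(exc$y)^2)[cand]
  step_dur <- diff(exc$time)[cand]
  v <- step_len / step_dur
  cand[which.min(v)]
}

#' Run the full turning-point location on an excursion
#'
#' Convenience wrapper: computes the decile profile, the turning trajectory
#' and the turning point, and returns the excursion with `turning_segment`
#' and `turning_point` filled in.
#'
#' @inheritParams locate_turning_trajectory
#' @return the `excursion`, annotated.
#' @export
locate_turning <- function(exc, config = homing_config()) {
  profile <- segment_profile(exc)
  seg <- locate_turning_trajectory(profile, exc, config)
  tp <- locate_turning_point(exc, seg, profile)
  n <- length(exc$x)
  if (tp <= 1L) tp <- 2L
  if (tp >= n) tp <- n - 1L
  exc$turning_segment <- seg
  exc$turning_point <- tp
  exc
}
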