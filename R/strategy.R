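# Corridor-based classification of inbound returns: tracking (retracing the
# outbound track within a +-30 m corridor), scouting (novel route separated
# by more than 30 m), or a combination with sub-track splits.

#' Corridor profile of an excursion's inbound return
#'
#' For every inbound point (turning point to excursion end), the minimum
#' distance to the outbound polyline (excursion start to turning point).
#' Points within the first and last `terminal_buffer_m` of inbound path
#' length are masked out: the return's endpoints coincide with the outbound
#' track by construction.
#'
#' @param exc an `excursion` with a located turning point.
#' @param config a [homing_config()].
#' @return list with `indices` (inbound point indices into the excursion),
#'   `distances` (m), `evaluated` (logical mask), and `inbound_cum`
#'   (path position of each inbound point, m from the turning point).
#' @export
corridor_profile <- function(exc, config = homing_config()) {
  tp <- exc$turning_point
  if (is.na(tp)) stop("turning point not located")
  n <- length(exc$x)
  if (tp < 2) stop("degenerate outbound: fewer than 2 points")
  if (tp > n - 1) stop("degenerate inbound: fewer than 2 points")
  inbound <- tp:n
  d <- min_dist_to_polyline(exc$x[inbound], exc$y[inbound],
                            exc$x[1:tp], exc$y[1:tp])
  icum <- exc$cum[inbound] - exc$cum[tp]
  total <- icum[length(icum)]
  evaluated <- icum >= config$terminal_buffer_m &
    icum <= total - config$terminal_buffer_m
  list(indices = inbound, distances = d, evaluated = evaluated,
       inbound_cum = icum)
}

#' Classify a return as tracking, scouting or combined
#'
#' Evaluated inbound points are labelled IN (distance to the outbound track
#' `<= corridor_m`) or OUT. Runs of equal labels shorter than `min_run_m` of
#' path are merged into their neighbour. All IN gives `TRACKING`; all OUT,
#' `SCOUTING`; otherwise `COMBINED`, with the alternating sub-tracks
#' returned. Consecutive sub-tracks share a boundary point, so their path
#' lengths sum exactly to the evaluated inbound path length.
#'
#' @param profile output of [corridor_profile()].
#' @param exc the `excursion` (for path positions).
#' @param config a [homing_config()].
#' @return list with `label`, `subtracks` (data.frame of `label`, `start`,
#'   `end` point indices into the excursion), and `frac_in` (fraction of
#'   evaluated points inside the corridor).
#' @export
classify_return <- function(profile, exc, config = homing_config()) {
  keep <- which(profile$evaluated)
  if (!length(keep)) stop("classification error: no evaluated inbound points")
  idx <- profile$indices[keep]           # excursion point indices
  inside <- profile$distances[keep] <= config$corridor_m

  r <- rle(inside)
  runs <- data.frame(val = r$values,
                     from = cumsum(c(1L, utils::head(r$lengths, -1L))),
                     to = cumsum(r$lengths))
  run_len <- function(runs) {
    exc$cum[idx[runs$to]] - exc$cum[idx[runs$from]]
  }
  repeat {
    if (nrow(runs) <= 1L) break
    len <- run_len(runs)
    i <- which.min(len)
    if (len[i] >= config$min_run_m) break
    nb <- if (i == 1L) 2L else if (i == nrow(runs)) i - 1L else {
      if (len[i - 1L] >= len[i + 1L]) i - 1L else i + 1L
    }
    runs$val[i] <- runs$val[nb]
    # coalesce adjacent equal-label runs
    r2 <- rle(runs$val)
    ends <- cumsum(r2$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    runs <- data.frame(val = r2$values,
                       from = runs$from[starts],
                       to = runs$to[ends])
  }

  subtracks <- data.frame(
    label = ifelse(runs$val, "TRACKING", "SCOUTING"),
    start = idx[runs$from],
    end = idx[runs$to],
    stringsAsFactors = FALSE)
  # contiguous coverage: neighbouring sub-tracks share a boundary point
  if (nrow(subtracks) > 1L) {
    subtracks$start[-1L] <- subtracks$end[-nrow(subtracks)]
  }
  label <- if (all(runs$val)) "TRACKING" else if (!any(runs$val)) "SCOUTING" else "COMBINED"
  list(label = label, subtracks = subtracks, frac_in = mean(inside))
}
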