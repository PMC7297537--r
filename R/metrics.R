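# Homing metrics and dataset summaries.

#' Mean inbound speed of an excursion
#'
#' Inbound path length (turning point to excursion end) divided by inbound
#' duration, in km/h.
#'
#' @param exc an `excursion` with a located turning point.
#' @return speed in km/h.
#' @export
inbound_speed <- function(exc) {
  tp <- exc$turning_point
  if (is.na(tp)) stop("turning point not located")
  n <- length(exc$x)
  dur <- exc$time[n] - exc$time[tp]
  if (dur <= 0) stop("degenerate data: zero inbound duration")
  len <- exc$cum[n] - exc$cum[tp]
  (len / dur) * 3.6
}

#' Homing efficiency index
#'
#' Ratio (in %) between the inbound path length and the beeline from the
#' turning point to the point where the return ends (the dog's arrival at
#' the excursion start, within 10 m of the owner). Always >= 100 by the
#' triangle inequality.
#'
#' @param exc an `excursion` with a located turning point.
#' @return list with `inbound_length`, `beeline` (m) and `index` (percent).
#' @export
homing_efficiency <- function(exc) {
  tp <- exc$turning_point
  if (is.na(tp)) stop("turning point not located")
  n <- length(exc$x)
  beeline <- sqrt((exc$x[n] - exc$x[tp])^2 + (exc$y[n] - exc$y[tp])^2)
  if (beeline <= 0) stop("undefined efficiency: return ends at the turning point")
  inbound <- exc$cum[n] - exc$cum[tp]
  list(inbound_length = inbound, beeline = beeline,
       index = 100 * inbound / beeline)
}

#' Odds ratio of a 2x2 contingency table
#'
#' `(a*d)/(b*c)`. When any off-diagonal cell is zero, the Haldane 0.5
#' continuity correction is added to every cell (with a message).
#'
#' @param tab 2x2 matrix or a numeric vector `c(a, b, c, d)` filled by row.
#' @return the odds ratio.
#' @export
odds_ratio <- function(tab) {
  x <- as.numeric(tab)
  if (length(x) != 4 || any(x < 0)) stop("need a 2x2 table of non-negative counts")
  if (all(x == 0)) stop("all-zero table")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  if (b * cc == 0) {
    message("zero off-diagonal cell: applying 0.5 continuity correction")
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  (a * d) / (b * cc)
}

#' Percentage share of a count over a base
#'
#' @param count event count(s).
#' @param base denominator (e.g. classified return events, or trials).
#' @param digits rounding for reporting (default 1, matching 1-decimal
#'   percentage reporting).
#' @return percent.
#' @export
percent_share <- function(count, base, digits = 1) {
  round(100 * count / base, digits)
}

#' Summarise an analysed dataset
#'
#' Takes the per-excursion and per-run tables produced by [analyze_trials()]
#' and returns strategy counts with both percentage bases (classified return
#' events, and trials), per-strategy circular statistics (angular Rayleigh
#' for azimuths A and B; axial Rayleigh for azimuth C), compass-run length
#' summaries, axis counts, and NS vs EW homing-efficiency group means.
#'
#' @param excursions per-excursion data.frame from [analyze_trials()].
#' @param runs per-(excursion, sub-track) data.frame from [analyze_trials()].
#' @param n_trials number of trials analysed (denominator of the trial base).
#' @return list of summary tables.
#' @export
summarize_dataset <- function(excursions, runs, n_trials) {
  labs <- c("TRACKING", "SCOUTING", "COMBINED")
  counts <- vapply(labs, function(l) sum(excursions$strategy == l), numeric(1))
  n_events <- sum(counts)
  strategy <- data.frame(
    strategy = labs, events = counts,
    share_of_events_pct = percent_share(counts, n_events),
    share_of_trials_pct = percent_share(counts, n_trials))

  circ_one <- function(bearings, axial) {
    if (length(bearings) < 2) {
      return(data.frame(n = length(bearings), mu = NA, r = NA, Z = NA, p = NA))
    }
    rt <- rayleigh_test(circ_sample(bearings, axial = axial))
    data.frame(n = rt$n, mu = round(rt$mu, 1), r = round(rt$r, 3),
               Z = round(rt$Z, 3), p = round(rt$p, 4))
  }
  per_strategy <- do.call(rbind, lapply(labs, function(l) {
    e <- excursions[excursions$strategy == l, , drop = FALSE]
    r <- runs[runs$strategy == l, , drop = FALSE]
    cbind(strategy = l, rbind(
      cbind(azimuth = "A", circ_one(e$azimuth_A, axial = FALSE)),
      cbind(azimuth = "B", circ_one(e$azimuth_B, axial = FALSE)),
      cbind(azimuth = "C", circ_one(r$azimuth_C, axial = TRUE))))
  }))

  run_summary <- stats::aggregate(run_length_m ~ strategy, data = runs,
                                  FUN = function(v) round(mean(v), 1))
  axis_counts <- as.data.frame(table(strategy = runs$strategy,
                                     axis = runs$axis))

  eff <- NULL
  sc <- merge(excursions, runs[runs$leg == 1, c("trial_id", "excursion_no", "axis")],
              by = c("trial_id", "excursion_no"))
  if (nrow(sc)) {
    eff <- stats::aggregate(efficiency_pct ~ axis, data = sc,
                            FUN = function(v) round(mean(v), 1))
  }
  list(strategy = strategy, circular = per_strategy,
       run_length = run_summary, axis_counts = axis_counts,
       efficiency_by_axis = eff,
       n_events = n_events, n_trials = n_trials)
}
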