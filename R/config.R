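#' Analysis configuration
#'
#' Collects every threshold used by the excursion pipeline in one place.
#' Defaults are the study protocol's printed values; the remaining knobs
#' (terminal buffer, minimum run length, "improbable" turning-segment
#' criteria, deflection persistence) are documented conventions.
#'
#' @param separation_m straight-line dog-owner separation that opens an
#'   excursion (100 m: the handheld device alarms at this distance).
#' @param closure_m distance to the excursion-start location that closes an
#'   excursion (10 m).
#' @param min_excursion_m excursions with total path length below this are
#'   excluded (200 m).
#' @param corridor_m half-width of the tracking corridor around the outbound
#'   track (30 m).
#' @param deflection_deg heading deflection that terminates the compass run
#'   (20 degrees).
#' @param persistence_pts number of additional consecutive points at which
#'   the deflection must persist ("without an immediate return"); default 1.
#' @param min_chord_m candidate points closer than this (along the chord from
#'   the turning point) are skipped in the compass-run scan: bearings are
#'   ill-defined at displacements comparable to GPS noise, so the default is
#'   about 2.4 per-coordinate sigmas at the rated +-4.2 m accuracy.
#' @param min_step_m steps shorter than this never terminate the run, for the
#'   same reason.
#' @param terminal_buffer_m inbound path length masked out at each end of the
#'   corridor profile (endpoints trivially coincide with the outbound track).
#' @param min_run_m corridor runs shorter than this (path length) are merged
#'   into their neighbour before strategy labelling. Together with
#'   `terminal_buffer_m` this must absorb the apparent (noise) path of the
#'   turning pause plus the corridor-resident start of the return, so that
#'   GPS noise cannot flip labels; the defaults do so at the rated +-4.2 m
#'   accuracy and 2.5 s sampling.
#' @param improbable_segments decile indices treated as improbable turning
#'   trajectories (too close to start/goal).
#' @param long_pause_s a single inter-point interval longer than this marks
#'   the segment improbable (dog pausing too long at one spot).
#' @param azimuth_a_lag_s lag after the excursion start at which azimuth A is
#'   taken (5 s).
#' @param wind_halfwidth_deg half-width of the wind suitability sector
#'   (22.5 degrees).
#' @param run_length_measure "chord" (turning point to run end, default) or
#'   "path" (along-track). The chord is robust to GPS jitter around the
#'   near-stationary turning point; both agree on noise-free straight runs.
#' @return an object of class `homing_config`.
#' @export
homing_config <- function(separation_m = 100, closure_m = 10,
                          min_excursion_m = 200, corridor_m = 30,
                          deflection_deg = 20, persistence_pts = 1,
                          min_chord_m = 10, min_step_m = 1,
                          terminal_buffer_m = 60, min_run_m = 150,
                          improbable_segments = c(1L, 10L),
                          long_pause_s = 120, azimuth_a_lag_s = 5,
                          wind_halfwidth_deg = 22.5,
                          run_length_measure = c("chord", "path")) {
  run_length_measure <- match.arg(run_length_measure)
  cfg <- list(separation_m = separation_m, closure_m = closure_m,
              min_excursion_m = min_excursion_m, corridor_m = corridor_m,
              deflection_deg = deflection_deg, persistence_pts = persistence_pts,
              min_chord_m = min_chord_m, min_step_m = min_step_m,
              terminal_buffer_m = terminal_buffer_m, min_run_m = min_run_m,
              improbable_segments = as.integer(improbable_segments),
              long_pause_s = long_pause_s, azimuth_a_lag_s = azimuth_a_lag_s,
              wind_halfwidth_deg = wind_halfwidth_deg,
              run_length_measure = run_length_measure)
  num <- setdiff(names(cfg), c("improbable_segments", "run_length_measure"))
  if (!all(vapply(cfg[num], function(v) is.numeric(v) && v > 0, logical(1)))) {
    stop("all thresholds must be positive numbers")
  }
  structure(cfg, class = "homing_config")
}
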