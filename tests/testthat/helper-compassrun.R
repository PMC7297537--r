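# Shared fixtures, all built in code.

# absolute axial difference between two bearings, in [0, 90]
axial_diff <- function(a, b) {
  abs(((a - b + 90) %% 180) - 90)
}

# absolute circular difference in [0, 180]
abs_circ_diff <- function(a, b) abs(circ_diff(a, b))

# build an `excursion` object directly from planar coordinates
make_excursion <- function(x, y, time = seq_along(x) * 2.5 - 2.5,
                           owner_x = 0, owner_y = 0,
                           nominal_interval = 2.5, declination = 0) {
  compassrun:::new_excursion(x, y, time,
                             start_index = 1L, end_index = length(x),
                             owner_x = owner_x, owner_y = owner_y,
                             nominal_interval = nominal_interval,
                             declination = declination)
}

# a trial with a stationary owner at the origin and a scripted planar dog
# path, converted to geographic tracks
make_trial <- function(dog_xy, dt = 2.5, owner_xy = NULL,
                       declination = 0, wind_from = NA_real_) {
  frame <- local_frame(49.8, 15.5)
  n <- nrow(dog_xy)
  tt <- (seq_len(n) - 1) * dt
  if (is.null(owner_xy)) {
    owner_xy <- cbind(rep(c(0, 0.5), length.out = n), 0)
  }
  d <- unproject_point(dog_xy[, 1], dog_xy[, 2], frame)
  o <- unproject_point(owner_xy[, 1], owner_xy[, 2], frame)
  trial_record(
    trial_id = "t1", dog_id = "d1", sex = "F", breed = "beagle",
    shoulder_height = 45, site_id = "s1", familiarity = "familiar",
    wind_from = wind_from, wind_speed = NA_real_,
    datetime = as.POSIXct("2015-06-15 09:00:00", tz = "UTC"),
    declination = declination,
    dog_track = track(tt, d$lat, d$lon, nominal_interval = dt),
    owner_track = track(tt, o$lat, o$lon, nominal_interval = dt))
}

# straight out-and-back dog path: origin -> (0, out_m) -> back to (0, end_m)
out_and_back <- function(out_m, end_m = 5, step = 7.5) {
  ys <- c(seq(0, out_m, by = step), rev(seq(end_m, out_m - step, by = step)))
  cbind(0, ys)
}
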