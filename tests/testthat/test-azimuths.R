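test_that("azimuth A uses the fix nearest to 5 s after the start", {
  # 2.5 s sampling: 2nd point after the start
  e <- make_excursion(c(0, 0, 0, 5), c(0, 25, 50, 75), time = c(0, 2.5, 5, 7.5))
  expect_equal(azimuth_a(e), 0)
  # 5.0 s sampling: 1st point after the start
  e5 <- make_excursion(c(0, 50, 50), c(0, 0, 50), time = c(0, 5, 10),
                       nominal_interval = 5)
  expect_equal(azimuth_a(e5), 90)
  # declination shifts the magnetic value
  expect_equal(azimuth_a(e5, declination = 4), 86)
  # no fix near start + 5 s
  e_bad <- make_excursion(c(0, 0, 0), c(0, 10, 20), time = c(0, 1, 20))
  expect_error(azimuth_a(e_bad), "missing fix")
})

test_that("azimuth B points from the turning point to the owner", {
  e <- make_excursion(c(0, 0, 0, 0, 0), c(0, 50, 100, 50, 5),
                      owner_x = 0, owner_y = 0)
  e$turning_point <- 3L
  expect_equal(azimuth_b(e), 180)
  # reverse bearing differs by 180
  fwd <- true_bearing(e$x[3], e$y[3], e$owner_x, e$owner_y)
  rev <- true_bearing(e$owner_x, e$owner_y, e$x[3], e$y[3])
  expect_equal((fwd - rev) %% 360, 180)
  # declination applied
  expect_equal(azimuth_b(e, declination = -10), 190)
})

test_that("compass run ends at the first sustained >20 degree deflection", {
  # 5 m steps north x4, then east: azimuth C = 0, length 20 m
  x <- c(0, 0, 0, 0, 0, 5, 10, 15)
  y <- c(0, 5, 10, 15, 20, 20, 20, 20)
  e <- make_excursion(x, y)
  e$turning_point <- 1L
  cr <- extract_compass_run(e)
  expect_equal(cr$azimuth_c, 0)
  expect_equal(cr$length_m, 20)
  expect_equal(cr$end_index, 5)
  expect_false(cr$truncated)
  # path and chord agree on a straight run
  cr_path <- extract_compass_run(e, config = homing_config(run_length_measure = "path"))
  expect_equal(cr_path$length_m, 20)
})

test_that("a one-point jiggle does not terminate the run", {
  # headings: 0, then one step at +45, then back to 0 for several steps,
  # then a sustained turn to 90
  step <- 6
  heads <- c(0, 45, 0, 0, 0, 0, 90, 90, 90)
  x <- cumsum(c(0, step * sin(heads * pi / 180)))
  y <- cumsum(c(0, step * cos(heads * pi / 180)))
  e <- make_excursion(x, y)
  e$turning_point <- 1L
  cr <- extract_compass_run(e)
  # the jiggle at point 2 is survived; the run ends at the sustained turn
  expect_gt(cr$end_index, 4)
  expect_false(cr$truncated)
  expect_lt(axial_diff(cr$azimuth_c, 0), 15)
})

test_that("a straight inbound yields a truncated full-span run", {
  e <- make_excursion(rep(0, 10), seq(0, 45, by = 5))
  e$turning_point <- 1L
  cr <- extract_compass_run(e)
  expect_true(cr$truncated)
  expect_equal(cr$end_index, 10)
  expect_equal(cr$azimuth_c, 0)
})

test_that("cardinal sectors follow the printed integer ranges", {
  expect_equal(sector_of(c(10, 45, 46, 135, 136, 225, 226, 315, 316, 0, 360)),
               c("N", "N", "E", "E", "S", "S", "W", "W", "N", "N", "N"))
  # rounding half-up to whole degrees before classification
  expect_equal(sector_of(45.4), "N")
  expect_equal(sector_of(45.5), "E")
  expect_equal(sector_of(315.5), "N")
})

test_that("axis classes are axial-symmetric", {
  expect_equal(axis_of(c(350, 90, 226)), c("NS", "EW", "EW"))
  th <- seq(0, 179.5, by = 0.5)
  expect_equal(axis_of(th), axis_of((th + 180) %% 360))
})

test_that("compass run is invariant to rotation with matched declination", {
  cfg <- sim_config(n_trials = 1, seed = 44, p_scouting = 1,
                    p_tracking = 0, p_combined = 0)
  st <- simulate_trial(cfg, 1)
  e <- locate_turning(detect_excursions(st$trial, quiet = TRUE)[[1]])
  cr <- extract_compass_run(e)

  phi <- 73 * pi / 180
  rot <- function(x, y) list(x = cos(phi) * x - sin(phi) * y,
                             y = sin(phi) * x + cos(phi) * y)
  r <- rot(e$x, e$y)
  e2 <- e
  e2$x <- r$x; e2$y <- r$y
  ow <- rot(e$owner_x, e$owner_y)
  e2$owner_x <- ow$x; e2$owner_y <- ow$y
  # rotating coordinates by phi (counter-clockwise) subtracts phi from
  # bearings; matching declination change leaves magnetic azimuths unchanged
  cr2 <- extract_compass_run(e2, declination = e$declination - 73)
  expect_equal(cr2$azimuth_c, cr$azimuth_c, tolerance = 1e-9)
  expect_equal(cr2$length_m, cr$length_m, tolerance = 1e-9)
  expect_equal(cr2$end_index, cr$end_index)
})
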