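gpx_text <- function(times, lat, lon) {
  pts <- sprintf('<trkpt lat="%.7f" lon="%.7f"><time>%s</time></trkpt>',
                 lat, lon, times)
  paste0('<?xml version="1.0"?><gpx version="1.1" creator="t" ',
         'xmlns="http://www.topografix.com/GPX/1/1"><trk><trkseg>',
         paste(pts, collapse = ""), '</trkseg></trk></gpx>')
}

test_that("GPX times convert to seconds from the first fix", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines(gpx_text(c("2015-06-15T08:00:00Z", "2015-06-15T08:00:05Z",
                        "2015-06-15T08:00:10Z"),
                      c(49.8, 49.8001, 49.8002), c(15.5, 15.5, 15.5)), f)
  trk <- read_gpx(f)
  expect_equal(trk$points$time, c(0, 5, 10))
  expect_equal(nrow(trk$points), 3)
  expect_equal(trk$nominal_interval, 5)
})

test_that("duplicate or missing timestamps are rejected", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines(gpx_text(rep("2015-06-15T08:00:00Z", 2), c(49.8, 49.81),
                      c(15.5, 15.5)), f)
  expect_error(read_gpx(f), "increasing")

  f2 <- withr::local_tempfile(fileext = ".gpx")
  txt <- paste0('<?xml version="1.0"?><gpx version="1.1" creator="t" ',
                'xmlns="http://www.topografix.com/GPX/1/1"><trk><trkseg>',
                '<trkpt lat="49.8" lon="15.5"/><trkpt lat="49.9" lon="15.5"/>',
                '</trkseg></trk></gpx>')
  writeLines(txt, f2)
  expect_error(read_gpx(f2), "timestamp")
})

test_that("write/read round trip preserves a 500-point track", {
  set.seed(10)
  n <- 500
  trk <- track(time = seq(0, by = 2.5, length.out = n),
               lat = 49.8 + cumsum(rnorm(n, 0, 1e-5)),
               lon = 15.5 + cumsum(rnorm(n, 0, 1e-5)),
               nominal_interval = 2.5,
               start_time = as.POSIXct("2015-06-15 08:00:00", tz = "UTC"))
  f <- withr::local_tempfile(fileext = ".gpx")
  write_gpx(trk, f)
  back <- read_gpx(f)
  expect_equal(nrow(back$points), n)
  expect_true(max(abs(back$points$lat - trk$points$lat)) < 1e-7)
  expect_true(max(abs(back$points$lon - trk$points$lon)) < 1e-7)
  expect_equal(back$points$time, trk$points$time, tolerance = 0.011)
})

test_that("gaps beyond 3x the nominal interval are flagged, not dropped", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines(gpx_text(c("2015-06-15T08:00:00Z", "2015-06-15T08:00:05Z",
                        "2015-06-15T08:01:00Z", "2015-06-15T08:01:05Z"),
                      rep(49.8, 4), rep(15.5, 4)), f)
  expect_message(trk <- read_gpx(f, nominal_interval = 5), "gap")
  expect_equal(nrow(trk$points), 4)
})

test_that("trial table round-trips a simulated dataset", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_trials = 3, seed = 5)
  ds <- simulate_dataset(cfg, dir = dir)
  trials <- read_trial_table(file.path(dir, "trials.csv"))
  expect_length(trials, 3)
  for (i in 1:3) {
    a <- trials[[i]]$dog_track$points
    b <- ds$trials[[i]]$dog_track$points
    expect_equal(nrow(a), nrow(b))
    expect_true(max(abs(a$lat - b$lat)) < 1e-7)
    expect_true(max(abs(a$lon - b$lon)) < 1e-7)
  }
  # wind: NA cells stay NA, and values survive
  winds <- vapply(ds$trials, function(t) t$wind_from, numeric(1))
  got <- vapply(trials, function(t) t$wind_from, numeric(1))
  expect_equal(is.na(got), is.na(winds))
})

test_that("trial table validation catches bad wind and missing files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_trials = 1, seed = 6)
  simulate_dataset(cfg, dir = dir)
  meta <- read.csv(file.path(dir, "trials.csv"))
  meta$wind_from_deg <- 400
  write.csv(meta, file.path(dir, "trials.csv"), row.names = FALSE, na = "")
  expect_error(read_trial_table(file.path(dir, "trials.csv")), "wind_from")

  meta$wind_from_deg <- 90
  meta$dog_gpx <- "missing.gpx"
  write.csv(meta, file.path(dir, "trials.csv"), row.names = FALSE, na = "")
  expect_error(read_trial_table(file.path(dir, "trials.csv")), "failed to load")
})

test_that("track constructor enforces ordering and ranges", {
  expect_error(track(c(0, 1, 1), c(49, 49, 49), c(15, 15, 15)), "index 3")
  expect_error(track(c(0, 1), c(49, 95), c(15, 15)), "latitude")
  expect_error(track(0, 49, 15), "at least 2")
})
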