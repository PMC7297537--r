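test_that("excursions open at 100 m separation and close within 10 m of the start", {
  # out to 160 m, back to 5 m of the owner: one excursion, path >= 200 m
  tr <- make_trial(out_and_back(160))
  exc <- detect_excursions(tr, quiet = TRUE)
  expect_length(exc, 1)
  e <- exc[[1]]
  expect_gte(e$total_length, 200)
  n <- length(e$x)
  expect_lte(sqrt((e$x[n] - e$owner_x)^2 + (e$y[n] - e$owner_y)^2), 10)
  # opens at the first point >= 100 m from the owner
  expect_gte(sqrt((e$x[1] - e$owner_x)^2 + (e$y[1] - e$owner_y)^2), 100)

  # max separation 90 m: no excursion
  expect_length(detect_excursions(make_trial(out_and_back(90)), quiet = TRUE), 0)
})

test_that("short and unreturned excursions are discarded with a message", {
  # opens at 100 m, returns immediately: path from the opening ~ 190 m < 200
  tr <- make_trial(out_and_back(105, end_m = 8))
  expect_message(exc <- detect_excursions(make_trial(out_and_back(105, end_m = 8))),
                 "discarded")
  expect_length(detect_excursions(tr, quiet = TRUE), 0)

  # never returns: track ends away from the owner
  out_only <- cbind(0, seq(0, 300, by = 7.5))
  expect_message(detect_excursions(make_trial(out_only)), "unreturned")
  expect_length(detect_excursions(make_trial(out_only), quiet = TRUE), 0)
})

test_that("decile profile: equal speeds when uniform, pause makes its decile slowest", {
  e <- make_excursion(rep(0, 101), seq(0, 500, by = 5))
  pr <- segment_profile(e)
  expect_equal(pr$speeds, rep(2, 10))
  expect_equal(sum(diff(pr$boundaries)), e$total_length, tolerance = 1e-6)

  # a 60 s pause entirely inside segment 6
  y <- seq(0, 500, by = 5)
  tt <- seq_along(y) * 2.5
  pause_at <- which.min(abs(y - 275))
  tt[pause_at:length(tt)] <- tt[pause_at:length(tt)] + 60
  e2 <- make_excursion(rep(0, length(y)), y, time = tt)
  pr2 <- segment_profile(e2)
  expect_equal(which.min(pr2$speeds), 6)
})

test_that("turning trajectory falls back when the slowest segment is improbable", {
  e <- make_excursion(rep(0, 101), seq(0, 500, by = 5))
  pr <- segment_profile(e)

  pr1 <- pr; pr1$speeds <- c(3, 3, 3, 3, 3, 1, 3, 3, 3, 3)
  expect_equal(locate_turning_trajectory(pr1, e), 6)

  pr2 <- pr; pr2$speeds <- c(1, 3, 3, 3, 3, 3, 2, 3, 3, 3)
  expect_equal(locate_turning_trajectory(pr2, e), 7)

  # slowest = 1, second slowest = 10: distance rule picks, among the rest
  # from slowest upward, the first farther than the median point distance
  pr3 <- pr
  pr3$speeds <- c(0.5, 3.0, 2.9, 2.8, 2.7, 2.6, 2.5, 2.4, 2.3, 0.6)
  got <- locate_turning_trajectory(pr3, e)
  # independent evaluation of the written rule
  d_start <- abs(e$y - e$owner_y)
  med <- median(sqrt((e$x - e$owner_x)^2 + (e$y - e$owner_y)^2))
  ord <- order(pr3$speeds)
  expected <- NA
  for (k in ord[-(1:2)]) {
    if (pr3$distances_from_start[k] > med) { expected <- k; break }
  }
  expect_equal(got, expected)

  # a long single gap marks a segment improbable
  pr4 <- pr; pr4$speeds <- c(3, 3, 1, 3, 3, 3, 2, 3, 3, 3)
  pr4$max_gap_s[3] <- 130
  expect_equal(locate_turning_trajectory(pr4, e), 7)
})

test_that("turning point is the slowest pair, ties to the earliest", {
  # pair speeds 2.0, 1.5, 0.5, 1.8: the 0.5 pair starts at point 3 and its
  # midpoint path position (12.5 of 20 m) lies in decile 7
  y <- cumsum(c(0, 5, 5, 5, 5))
  tt <- cumsum(c(0, 5 / 2, 5 / 1.5, 5 / 0.5, 5 / 1.8))
  e <- make_excursion(rep(0, 5), y, time = tt)
  tp <- locate_turning_point(e, segment = 7, profile = segment_profile(e))
  expect_equal(tp, 3)

  # all speeds equal: earliest pair in the segment wins
  e2 <- make_excursion(rep(0, 21), 0:20, time = 0:20)
  tp2 <- locate_turning_point(e2, 3, segment_profile(e2))
  expect_equal(tp2, 5)
})

test_that("turning location is invariant under uniform time shifts", {
  cfg <- sim_config(n_trials = 1, seed = 33)
  st <- simulate_trial(cfg, 1)
  e <- locate_turning(detect_excursions(st$trial, quiet = TRUE)[[1]])
  e2 <- e
  e2$time <- e2$time + 500
  e2 <- locate_turning(e2)
  expect_equal(e2$turning_segment, e$turning_segment)
  expect_equal(e2$turning_point, e$turning_point)
})

test_that("simulated excursions satisfy the excursion invariants", {
  cfg <- sim_config(n_trials = 12, seed = 21)
  ds <- simulate_dataset(cfg)
  for (tr in ds$trials) {
    for (e in detect_excursions(tr, quiet = TRUE)) {
      e <- locate_turning(e)
      expect_gte(e$total_length, 200)
      expect_gt(e$turning_point, 1)
      expect_lt(e$turning_point, length(e$x))
      n <- length(e$x)
      expect_lte(sqrt((e$x[n] - e$owner_x)^2 + (e$y[n] - e$owner_y)^2), 10)
    }
  }
})
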