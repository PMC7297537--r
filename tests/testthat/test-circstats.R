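test_that("mean vector handles angular and axial samples", {
  mv <- mean_vector(circ_sample(c(10, 190), axial = TRUE))
  expect_equal(mv$mu, 10)
  expect_equal(mv$mu2, 190)
  expect_equal(mv$r, 1)

  mv2 <- mean_vector(circ_sample(c(0, 90), axial = TRUE))
  expect_equal(mv2$r, 0, tolerance = 1e-12)

  mv3 <- mean_vector(circ_sample(c(0, 0, 90)))
  expect_equal(mv3$mu, 26.5651, tolerance = 1e-4)
  expect_equal(mv3$r, 0.745356, tolerance = 1e-5)
  expect_true(is.na(mv3$mu2))

  expect_error(circ_sample(numeric(0)), "empty")
})

test_that("Rayleigh p reproduces closed-form values and is monotone", {
  # printed worked value: n = 27, r = 0.021 gives p ~ 0.988-0.989
  p <- rayleigh_p(27, 0.021)
  expect_gte(p, 0.988)
  expect_lte(p, 0.989)

  expect_equal(rayleigh_p(50, 0), 1)
  expect_equal(rayleigh_p(100, 0.3), 1.0458e-4, tolerance = 1e-3)

  rs <- seq(0, 1, by = 0.02)
  ps <- vapply(rs, function(r) rayleigh_p(30, r), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(rayleigh_p(30, 1.2), "r must")
})

test_that("Rayleigh test detects axial clustering and degenerate samples", {
  set.seed(7)
  ax <- (rvonmises(100, 0, 2) / 2 + 180 * rbinom(100, 1, 0.5)) %% 360
  rt <- rayleigh_test(circ_sample(ax, axial = TRUE))
  expect_lt(rt$p, 1e-6)
  expect_lt(axial_diff(rt$mu, 0), 10)

  rt2 <- rayleigh_test(circ_sample(rep(77, 30)))
  expect_equal(rt2$r, 1)
  expect_equal(rt2$p, rayleigh_p(30, 1))
  expect_equal(rt2$mu, 77)
})

test_that("rotation equivariance: shifting bearings shifts mu only", {
  set.seed(8)
  b <- runif(40, 0, 360)
  r0 <- rayleigh_test(circ_sample(b))
  r1 <- rayleigh_test(circ_sample((b + 53) %% 360))
  expect_equal((r1$mu - r0$mu) %% 360, 53, tolerance = 1e-9)
  expect_equal(r1$r, r0$r)
  expect_equal(r1$Z, r0$Z)
  expect_equal(r1$p, r0$p)
})

test_that("Watson's U2 matches table bounds and elementary cases", {
  a <- circ_sample(c(10, 40, 70, 100, 130, 160, 190, 220, 250))
  w <- watson_u2(a, a)
  expect_equal(w$u2, 0, tolerance = 1e-12)
  expect_equal(w$p_bound, ">0.5")

  # the statistic 0.027 is far below the 5% critical value 0.187
  expect_gt(compassrun:::watson_u2_sf(0.027), 0.5)
  expect_equal(compassrun:::watson_u2_crit(0.05), 0.187, tolerance = 1e-2)
  expect_equal(compassrun:::watson_u2_crit(0.001), 0.385, tolerance = 1e-2)

  expect_error(watson_u2(circ_sample(1:10, axial = TRUE), circ_sample(1:10)),
               "mix")
})

test_that("Watson's U2 rejects a 90-degree shift by table and permutation", {
  set.seed(9)
  a <- circ_sample(rvonmises(50, 0, 2))
  b <- circ_sample(rvonmises(50, 90, 2))
  w <- watson_u2(a, b, permutations = 499)
  expect_gt(w$u2, 0.187)
  expect_true(startsWith(w$p_bound, "<"))
  expect_lt(w$p_perm, 0.05)
  expect_lt(w$p_asymptotic, 0.05)
})

test_that("bootstrap confidence arc behaves on degenerate and typical samples", {
  s <- circ_sample(rep(45, 20))
  ci <- circular_ci(s, resamples = 200)
  expect_equal(ci$lo, 45)
  expect_equal(ci$hi, 45)

  set.seed(10)
  s2 <- circ_sample(rvonmises(40, 120, 3))
  ci2 <- circular_ci(s2, resamples = 2000)
  # the arc contains the point estimate
  arc <- (ci2$hi - ci2$lo) %% 360
  off <- (ci2$mu - ci2$lo) %% 360
  expect_lte(off, arc)

  expect_error(circular_ci(circ_sample(c(0, 90), axial = TRUE)), "undefined CI")
})

test_that("bootstrap arc coverage is near nominal for von Mises samples", {
  set.seed(11)
  hits <- 0L
  n_sim <- 250
  for (k in seq_len(n_sim)) {
    s <- circ_sample(rvonmises(40, 50, 3))
    ci <- circular_ci(s, resamples = 600)
    arc <- (ci$hi - ci$lo) %% 360
    off <- (50 - ci$lo) %% 360
    if (off <= arc) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.90)
  expect_lte(hits / n_sim, 0.99)
})

test_that("dog-level means aggregate excursion bearings per dog", {
  out <- dog_level_means(c(10, 350, 200), c("a", "b", "c"))
  expect_equal(sort(out$bearings), sort(c(10, 350, 200)))
  expect_equal(out$level, "dog")

  out2 <- dog_level_means(c(0, 0), c("a", "a"))
  expect_equal(out2$bearings, 0)

  expect_message(out3 <- dog_level_means(c(0, 180, 90), c("a", "a", "b")),
                 "excluded")
  expect_equal(out3$bearings, 90)
})

test_that("dog-level grand mean is tighter than pooled excursion bearings", {
  # dogs share an axis but differ in their own scatter; the grand mean over
  # per-dog means concentrates relative to the pooled sample on average
  set.seed(12)
  rs <- replicate(15, {
    dogs <- rep(1:27, each = 8)
    mu_dog <- rvonmises(27, 0, 8) / 2
    bear <- (rep(mu_dog, each = 8) + rnorm(27 * 8, 0, 35)) %% 180
    pooled <- mean_vector(circ_sample(bear, axial = TRUE))$r
    grand <- mean_vector(dog_level_means(bear, dogs, axial = TRUE))$r
    grand - pooled
  })
  expect_gt(mean(rs), 0)
})

test_that("von Mises sampler concentrates and degrades to uniform", {
  set.seed(13)
  # kappa = 50: angular SD ~ 1/sqrt(50) rad ~ 8.1 degrees
  x <- rvonmises(400, 210, 50)
  expect_gte(mean(abs_circ_diff(x, 210) <= 20), 0.95)
  expect_lt(abs_circ_diff(mean_vector(circ_sample(x))$mu, 210), 2)

  u <- rvonmises(500, 0, 0)
  ks <- ks.test(u / 360, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("rose rounding is display-only 5-degree snapping", {
  expect_equal(rose_round(c(12, 13, 357.6)), c(10, 15, 0))
})
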