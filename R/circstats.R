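# Circular statistics for angular and axial bearing samples: mean vectors,
# Rayleigh test (series-corrected p), two-sample Watson's U2 with table
# bounds and a permutation option, bootstrap confidence arcs, and dog-level
# (grand mean) aggregation. Axial data (directions meaningful modulo 180)
# are analysed on doubled angles throughout.

#' Construct a circular sample
#'
#' @param bearings degrees; wrapped to `[0, 360)`.
#' @param axial if `TRUE` the bearings are axial (meaningful modulo 180) and
#'   all analyses double the angles first.
#' @param level "excursion" (one bearing per excursion) or "dog" (one mean
#'   bearing per dog).
#' @return object of class `circ_sample`.
#' @export
circ_sample <- function(bearings, axial = FALSE,
                        level = c("excursion", "dog")) {
  level <- match.arg(level)
  b <- wrap360(as.numeric(bearings))
  if (!length(b)) stop("empty circular sample")
  if (anyNA(b)) stop("NA bearings in circular sample")
  structure(list(bearings = b, axial = axial, level = level),
            class = "circ_sample")
}

#' Mean vector of a circular sample
#'
#' `C = mean(cos)`, `S = mean(sin)` (after doubling for axial data);
#' `r = sqrt(C^2 + S^2)`; `mu = atan2(S, C)`. For axial data the mean
#' direction of the doubled angles is halved back and reported as an axis
#' (`mu` in `[0, 180)`, the other end at `mu + 180`).
#'
#' @param sample a [circ_sample()].
#' @return list with `mu` (degrees), `mu2` (`NA` for angular data, the
#'   opposite axis end for axial), `r`, `n`, `axial`.
#' @export
mean_vector <- function(sample) {
  b <- sample$bearings
  a <- deg2rad(if (sample$axial) 2 * b else b)
  C <- mean(cos(a)); S <- mean(sin(a))
  r <- sqrt(C^2 + S^2)
  mu <- wrap360(rad2deg(atan2(S, C)))
  if (sample$axial) {
    mu <- (mu / 2) %% 180
    mu2 <- mu + 180
  } else {
    mu2 <- NA_real_
  }
  list(mu = mu, mu2 = mu2, r = r, n = length(b), axial = sample$axial)
}

#' Rayleigh p-value from sample size and mean vector length
#'
#' Series-corrected large-sample approximation: with `Z = n r^2`,
#' `p = exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`,
#' clamped to `[0, 1]`.
#'
#' @param n sample size (>= 2).
#' @param r mean vector length in `[0, 1]`.
#' @return p-value.
#' @export
rayleigh_p <- function(n, r) {
  if (n < 2) stop("need n >= 2")
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  Z <- n * r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  min(max(p, 0), 1)
}

#' Rayleigh test of circular uniformity
#'
#' For axial samples the angles are doubled before computing the mean vector
#' and the axis is reported after halving.
#'
#' @param sample a [circ_sample()].
#' @return list with `n`, `mu`, `mu2`, `r`, `Z = n r^2` and `p`.
#' @export
rayleigh_test <- function(sample) {
  mv <- mean_vector(sample)
  Z <- mv$n * mv$r^2
  list(n = mv$n, mu = mv$mu, mu2 = mv$mu2, r = mv$r, Z = Z,
       p = rayleigh_p(mv$n, mv$r), axial = sample$axial)
}

# Asymptotic survival function of Watson's U2:
# P(U2 >= u) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 pi^2 u).
# For small u the alternating series converges too slowly; the Jacobi theta
# transformation gives the complementary form
# P(U2 < u) = (2 / sqrt(2 pi u)) * sum_{m>=0} exp(-(2m+1)^2 / (8u)).
watson_u2_sf <- function(u, terms = 25L) {
  if (u <= 0) return(1)
  if (u < 0.12) {
    m <- 0:terms
    cdf <- (2 / sqrt(2 * pi * u)) * sum(exp(-(2 * m + 1)^2 / (8 * u)))
    return(min(max(1 - cdf, 0), 1))
  }
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u))
  min(max(p, 0), 1)
}

watson_u2_crit <- function(alpha) {
  stats::uniroot(function(u) watson_u2_sf(u) - alpha,
                 lower = 1e-6, upper = 5, tol = 1e-10)$root
}

# U2 statistic from two bearing vectors in degrees (already doubled if axial).
# Ties are handled by evaluating the ECDF difference at the end of each tied
# block (every tied point carries the block-end difference), so identical
# samples give exactly 0.
watson_u2_stat <- function(a, b) {
  n <- length(a); m <- length(b)
  N <- n + m
  v <- c(a, b)
  g <- c(rep(1L, n), rep(2L, m))
  ord <- order(v)
  v <- v[ord]; g <- g[ord]
  d <- cumsum(ifelse(g == 1L, 1 / n, 0)) - cumsum(ifelse(g == 2L, 1 / m, 0))
  if (anyDuplicated(v)) {
    # propagate block-end d backwards over tied values
    blocks <- rev(cumsum(rev(as.integer(diff(c(v, Inf)) != 0))))
    d <- ave(d, blocks, FUN = function(z) z[length(z)])
  }
  (n * m / N^2) * (sum(d^2) - sum(d)^2 / N)
}

#' Two-sample Watson's U2 test
#'
#' Nonparametric test for a difference between two circular distributions,
#' computed from the combined ranked empirical distribution functions and
#' therefore invariant to the choice of origin. The p-value is reported as a
#' bound from the standard critical-value table (generated from the
#' asymptotic distribution, e.g. 0.187 at the 5 % level), plus an exact
#' label-permutation p-value when `permutations > 0` (uses R's RNG stream;
#' set a seed for reproducibility).
#'
#' @param sample_a,sample_b [circ_sample()] objects with equal `axial` flags.
#' @param permutations number of label permutations (0 to skip).
#' @return list with `u2`, `p_bound` (text), `p_asymptotic`, and `p_perm`
#'   (`NA` when `permutations = 0`).
#' @export
watson_u2 <- function(sample_a, sample_b, permutations = 0) {
  if (sample_a$axial != sample_b$axial) {
    stop("cannot mix axial and angular samples")
  }
  f <- if (sample_a$axial) function(x) wrap360(2 * x) else wrap360
  a <- f(sample_a$bearings); b <- f(sample_b$bearings)
  u2 <- watson_u2_stat(a, b)
  p_asym <- watson_u2_sf(u2)
  levels <- c(0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001)
  crits <- vapply(levels, watson_u2_crit, numeric(1))
  if (u2 >= crits[1]) {
    p_bound <- paste0("<", format(levels[max(which(u2 >= crits))]))
  } else if (u2 < watson_u2_crit(0.5)) {
    p_bound <- ">0.5"
  } else if (u2 < watson_u2_crit(0.2)) {
    p_bound <- ">0.2"
  } else {
    p_bound <- ">0.1"
  }
  p_perm <- NA_real_
  if (permutations > 0) {
    pool <- c(a, b)
    n <- length(a)
    hits <- 0L
    for (i in seq_len(permutations)) {
      take <- sample.int(length(pool), n)
      if (watson_u2_stat(pool[take], pool[-take]) >= u2 - 1e-12) hits <- hits + 1L
    }
    p_perm <- (hits + 1) / (permutations + 1)
  }
  list(u2 = u2, p_bound = p_bound, p_asymptotic = p_asym, p_perm = p_perm)
}

#' Bootstrap confidence arc for the mean direction (or axis)
#'
#' Percentile bootstrap: resample the bearings with replacement, recompute
#' the mean direction, and take the central `level` arc of the signed
#' circular deviations around the point estimate. Axial samples are handled
#' on the doubled scale and mapped back to the axis. Uses R's RNG stream.
#'
#' @param sample a [circ_sample()].
#' @param level confidence level (default 0.95).
#' @param resamples bootstrap resamples (default 10000).
#' @return list with `lo`, `hi` (degrees; on the axis scale `[0, 180)` for
#'   axial data) and `mu` (the point estimate).
#' @export
circular_ci <- function(sample, level = 0.95, resamples = 10000) {
  mv <- mean_vector(sample)
  if (mv$r <= .Machine$double.eps) stop("undefined CI: mean vector length is 0")
  mult <- if (sample$axial) 2 else 1
  b <- deg2rad(mult * sample$bearings)
  mu_hat <- mult * mv$mu   # doubled-scale point estimate (degrees)
  n <- length(b)
  idx <- matrix(sample.int(n, n * resamples, replace = TRUE), nrow = resamples)
  C <- rowMeans(matrix(cos(b)[idx], nrow = resamples))
  S <- rowMeans(matrix(sin(b)[idx], nrow = resamples))
  mu_b <- wrap360(rad2deg(atan2(S, C)))
  dev <- circ_diff(mu_b, mu_hat)
  q <- stats::quantile(dev, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  lo <- wrap360(mu_hat + q[1]) / mult
  hi <- wrap360(mu_hat + q[2]) / mult
  if (sample$axial) { lo <- lo %% 180; hi <- hi %% 180 }
  list(lo = lo, hi = hi, mu = mv$mu)
}

#' Dog-level (grand) means from per-excursion bearings
#'
#' Computes one mean direction (axis) per dog from its excursion-level
#' bearings and returns the sample of per-dog means, for second-level
#' ("grand mean vector") analyses. Dogs whose own mean vector length is 0
#' (perfectly dispersed bearings) have no defined mean and are excluded with
#' a message.
#'
#' @param bearings numeric vector of degrees.
#' @param dog_id grouping vector, same length.
#' @param axial treat bearings as axial.
#' @return a [circ_sample()] with `level = "dog"`.
#' @export
dog_level_means <- function(bearings, dog_id, axial = FALSE) {
  stopifnot(length(bearings) == length(dog_id))
  groups <- split(bearings, dog_id)
  means <- vapply(names(groups), function(g) {
    mv <- mean_vector(circ_sample(groups[[g]], axial = axial))
    if (mv$r <= .Machine$double.eps) {
      message("dog ", g, " excluded: mean vector length 0")
      return(NA_real_)
    }
    mv$mu
  }, numeric(1))
  means <- means[!is.na(means)]
  if (!length(means)) stop("no dog has a defined mean direction")
  circ_sample(means, axial = axial, level = "dog")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` gives the circular
#' uniform distribution. Uses R's RNG stream.
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration (>= 0).
#' @return degrees in `[0, 360)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu_r <- deg2rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  bb <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + bb^2) / (2 * bb)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      theta <- mu_r + sign(u3 - 0.5) * acos(f)
      out[i] <- wrap360(rad2deg(theta))
      i <- i + 1L
    }
  }
  out
}

#' Round azimuths for rose-diagram display
#'
#' Display-only rounding to the nearest `resolution` degrees (default 5), as
#' used when binning bearings for rose plots. Never used in analyses.
#'
#' @param azimuth degrees.
#' @param resolution degrees.
#' @return rounded degrees in `[0, 360)`.
#' @export
rose_round <- function(azimuth, resolution = 5) {
  wrap360(round(wrap360(azimuth) / resolution) * resolution)
}
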