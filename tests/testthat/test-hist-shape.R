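test_that("histogram features match hand arithmetic and direct formulas", {
  v <- array(c(1, 2, 3, 4), c(4, 1, 1))
  m <- array(TRUE, c(4, 1, 1))
  f <- histogram_features(v, m)
  expect_equal(unname(f[c("hist_mean", "hist_median", "hist_range",
                          "hist_min", "hist_max")]),
               c(2.5, 2.5, 3, 1, 4))
  # constant volume conventions
  fc <- histogram_features(array(2, c(3, 1, 1)), array(TRUE, c(3, 1, 1)))
  expect_equal(unname(fc[c("hist_sd", "hist_range", "hist_skewness",
                           "hist_kurtosis")]), c(0, 0, 0, 0))
  expect_equal(fc[["hist_min"]], fc[["hist_max"]])
  # random sample against direct formula evaluation
  set.seed(3)
  x <- rnorm(500, 10, 2)
  v2 <- array(x, c(500, 1, 1))
  f2 <- histogram_features(v2, array(TRUE, c(500, 1, 1)))
  expect_equal(f2[["hist_mean"]], mean(x))
  expect_equal(f2[["hist_sd"]], sd(x))
  expect_equal(f2[["hist_median"]], median(x))
  expect_equal(f2[["hist_iqr"]],
               unname(quantile(x, 0.75) - quantile(x, 0.25)))
  mu <- mean(x); s <- sd(x); n <- length(x)
  expect_equal(f2[["hist_skewness"]],
               mean((x - mu)^3) / s^3 * (n / (n - 1))^1.5)
  expect_equal(f2[["hist_kurtosis"]],
               mean((x - mu)^4) / mean((x - mu)^2)^2)
  expect_equal(length(f2), 12)
})

test_that("a digital ball is nearly maximally compact", {
  d <- c(48, 48, 48)
  g <- expand.grid(x = 1:48, z = 1:48, y = 1:48)
  ball <- array((g$x - 24.5)^2 + (g$z - 24.5)^2 + (g$y - 24.5)^2 <= 20^2, d)
  f <- shape_features(ball, c(1, 1, 1))
  expect_gt(f[["shape_compactness_mean"]], 0.9)
  expect_lte(f[["shape_compactness_mean"]], 1.05)
  expect_equal(length(f), 17)
  expect_equal(f[["shape_volume_mm3"]], sum(ball))
})

test_that("a sinusoidally perturbed disk is less compact than a smooth one", {
  mk_cyl <- function(amp) {
    d <- c(4, 60, 60)
    out <- array(FALSE, d)
    th <- function(z, y) atan2(y - 30.5, z - 30.5)
    g <- expand.grid(z = 1:60, y = 1:60)
    r <- sqrt((g$z - 30.5)^2 + (g$y - 30.5)^2)
    rad <- 20 * (1 + amp * sin(8 * th(g$z, g$y)))
    sl <- matrix(r <= rad, 60, 60)
    for (i in 1:4) out[i, , ] <- sl
    out
  }
  f0 <- shape_features(mk_cyl(0), c(1, 1, 1))
  f1 <- shape_features(mk_cyl(0.15), c(1, 1, 1))
  expect_lt(f1[["shape_compactness_mean"]], f0[["shape_compactness_mean"]])
})

test_that("orientation rotates with the mask while shape is invariant", {
  d <- c(40, 40, 40)
  g <- expand.grid(x = 1:40, z = 1:40, y = 1:40)
  # horizontal elongated bar along the ML axis
  bar <- array(abs(g$x - 20.5) <= 15 & abs(g$z - 20.5) <= 4 &
                 abs(g$y - 20.5) <= 4, d)
  o1 <- orientation_features(bar, c(1, 1, 1))
  rot <- array(FALSE, d)  # rotate 90 degrees about the vertical axis
  for (i in 1:40) for (k in 1:40) rot[i, , k] <- bar[41 - k, , i]
  o2 <- orientation_features(rot, c(1, 1, 1))
  expect_equal(abs(o2[["orient_azimuth1"]] - o1[["orient_azimuth1"]]) %% 180,
               90, tolerance = 1e-6)
  # a circular cylinder's shape features are unchanged by the same rotation
  cyl <- array((g$x - 20.5)^2 + (g$y - 20.5)^2 <= 12^2 &
                 abs(g$z - 20.5) <= 14, d)
  rcyl <- array(FALSE, d)
  for (i in 1:40) for (k in 1:40) rcyl[i, , k] <- cyl[41 - k, , i]
  f1 <- shape_features(cyl, c(1, 1, 1))
  f2 <- shape_features(rcyl, c(1, 1, 1))
  expect_equal(unname(f1), unname(f2), tolerance = 0.02)
})

test_that("single-voxel slices are skipped, not fatal", {
  d <- c(3, 10, 10)
  m <- array(FALSE, d)
  m[1, 3:8, 3:8] <- TRUE
  m[2, 5, 5] <- TRUE  # single voxel slice
  f <- shape_features(m, c(1, 1, 1))
  expect_true(all(is.finite(f)))
})
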