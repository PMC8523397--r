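test_that("LBP on a constant volume is a single all-equal code", {
  d <- c(4, 12, 12)
  v <- array(5, d)
  m <- array(TRUE, d)
  f <- lbp_features(v, m, radii = 1)
  nz <- f[f > 0]
  expect_equal(length(nz), 1)
  expect_equal(names(nz), "lbp_r1_bin8")  # all neighbours >= centre
  expect_equal(unname(nz), 1)
})

test_that("LBP code histogram matches per-pixel oracle on a checkerboard", {
  n <- 14
  sl <- outer(1:n, 1:n, function(i, j) (i + j) %% 2)
  v <- array(0, c(1, n, n)); v[1, , ] <- sl
  m <- array(TRUE, c(1, n, n))
  f <- lbp_features(v, m, radii = 1)
  codes <- vapply(as.vector(outer(2:(n - 1), 2:(n - 1), paste)),
                  function(key) {
                    ij <- as.integer(strsplit(key, " ")[[1]])
                    lbp_code_bf(sl, ij[1], ij[2])
                  }, integer(1))
  oracle <- tabulate(codes + 1L, nbins = 10)
  oracle <- oracle / sum(oracle)
  expect_equal(unname(f[sprintf("lbp_r1_bin%d", 0:9)]), oracle,
               tolerance = 1e-12)
})

test_that("rotation-invariant codes are unchanged by 90-degree rotation", {
  set.seed(13)
  n <- 16
  sl <- matrix(rnorm(n * n), n, n)
  make_vol <- function(s) {
    v <- array(0, c(1, n, n)); v[1, , ] <- s
    v
  }
  m <- array(TRUE, c(1, n, n))
  f1 <- lbp_features(make_vol(sl), m, radii = 1)
  rot <- t(sl)[, n:1]  # 90-degree rotation
  f2 <- lbp_features(make_vol(rot), m, radii = 1)
  expect_equal(unname(f1), unname(f2), tolerance = 1e-10)
})

test_that("a VOI thinner than the LBP neighbourhood errors", {
  v <- array(rnorm(4 * 5 * 5), c(4, 5, 5))
  m <- array(TRUE, dim(v))
  expect_error(lbp_features(v, m, radii = 3), "too thin")
})

test_that("Gabor bank is DC-free and peaks at the aligned orientation", {
  d <- c(2, 32, 32)
  m <- array(TRUE, d)
  # constant image: zero response at every frequency
  fc <- gabor_features(array(4, d), m, frequencies = 0.2,
                       angles = c(0, pi / 4))
  expect_lt(max(fc[grep("mean", names(fc))]), 1e-10)
  # grating along the first slice axis at the filter frequency
  g <- array(0, d)
  for (i in 1:2) g[i, , ] <- outer(sin(2 * pi * 0.25 * (1:32)), rep(1, 32))
  angles <- seq(0, pi - pi / 6, by = pi / 6)
  fg <- gabor_features(g, m, frequencies = 0.25, angles = angles)
  means <- fg[grep("^gabor_mean", names(fg))]
  expect_equal(unname(which.max(means)), 1L)  # variation along slice rows
  expect_true(all(fg[grep("mean", names(fg))] >= 0))
  expect_true(all(fg[grep("sd", names(fg))] >= 0))
  expect_error(gabor_features(g, m, frequencies = 0.6, angles = 0),
               "Nyquist")
})
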