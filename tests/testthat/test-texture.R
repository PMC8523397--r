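test_that("quantization bins match the direct computation", {
  d <- c(4, 2, 2)
  vol <- array(0:15, d)
  mask <- array(TRUE, d)
  q <- quantize(vol, mask, 16)
  expect_equal(as.integer(q$levels), 1:16)
  # constant volume: everything level 1
  qc <- quantize(array(3, d), mask, 8)
  expect_true(all(qc$levels == 1L))
  # random volume against direct edge computation
  set.seed(11)
  v <- array(rnorm(60), c(5, 4, 3))
  m <- array(runif(60) > 0.2, c(5, 4, 3))
  G <- 6
  q2 <- quantize(v, m, G)
  lo <- min(v[m]); hi <- max(v[m])
  direct <- pmin(as.integer(floor((v[m] - lo) / (hi - lo) * G)) + 1L, G)
  expect_equal(q2$levels[m], direct)
  expect_true(all(q2$levels[!m] == 0L))
})

test_that("GLCM counts a 1-D strip by hand and matches brute force", {
  q <- quantize(array(c(1, 1, 2, 2), c(4, 1, 1)),
                array(TRUE, c(4, 1, 1)), 2)
  raw <- glcm(q, c(1, 0, 0), normalize = FALSE)
  # each co-occurring pair is counted in both directions: the (1,1) and
  # (2,2) diagonal cells carry 2, the off-diagonal pair carries 2 split
  # symmetrically across (1,2) and (2,1)
  expect_equal(raw[1, 1], 2)
  expect_equal(raw[1, 2] + raw[2, 1], 2)
  expect_equal(raw[1, 2], raw[2, 1])
  expect_equal(raw[2, 2], 2)
  # constant volume: contrast 0, energy 1
  qc <- quantize(array(5, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 4)
  f <- glcm_features(glcm(qc, c(1, 0, 0)))
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["energy"]], 1)
  # random volumes equal the double-loop oracle
  for (s in 1:6) {
    q3 <- random_quantized(s, c(6, 6, 6), G = 4)
    off <- tibrad:::glcm_directions()[sample.int(13, 1), ]
    expect_equal(glcm(q3, off, normalize = FALSE), glcm_bf(q3, off))
  }
})

test_that("GLRLM counts maximal runs and matches brute force", {
  q <- quantize(array(c(1, 1, 1, 2), c(4, 1, 1)),
                array(TRUE, c(4, 1, 1)), 2)
  R <- glrlm(q, c(1, 0, 0))
  expect_equal(R[1, 3], 1)  # level 1, length 3
  expect_equal(R[2, 1], 1)  # level 2, length 1
  expect_equal(sum(R), 2)
  for (s in 1:6) {
    q3 <- random_quantized(100 + s, c(6, 5, 4), G = 3)
    dir <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1), c(1, -1, 0))[
      sample.int(4, 1), ]
    expect_equal(unname(glrlm(q3, dir))[, 1:6],
                 unname(glrlm_bf(q3, dir))[, 1:6])
  }
})

test_that("GLSZM zones match a flood-fill oracle; NGTDM matches sums", {
  # constant 4x4x4 volume: one zone of size 64
  qc <- quantize(array(1, c(4, 4, 4)), array(TRUE, c(4, 4, 4)), 4)
  z <- glszm(qc)
  expect_equal(nrow(z), 1)
  expect_equal(unname(z[1, "size"]), 64)
  # coarseness denominator zero -> documented large constant
  f <- ngtdm_features(ngtdm(qc))
  expect_true(is.finite(f[["coarseness"]]))
  for (s in 1:6) {
    q3 <- random_quantized(200 + s, c(5, 5, 5), G = 3)
    z1 <- glszm(q3)
    z1 <- z1[order(z1[, 1], z1[, 2]), , drop = FALSE]
    expect_equal(unname(z1), unname(glszm_bf(q3)))
    expect_equal(unname(ngtdm(q3)), unname(ngtdm_bf(q3)), tolerance = 1e-12)
  }
})

test_that("matrix features are invariant to intensity shifts", {
  set.seed(21)
  v <- array(rnorm(6^3), c(6, 6, 6))
  m <- array(TRUE, c(6, 6, 6))
  q1 <- quantize(v, m, 8)
  q2 <- quantize(v + 100, m, 8)
  expect_equal(q1$levels, q2$levels)
  expect_equal(glcm_features(glcm(q1, c(1, 0, 0))),
               glcm_features(glcm(q2, c(1, 0, 0))))
})

test_that("longer texture correlation raises homogeneity and zone size", {
  vals <- vapply(c(0.8, 1.4, 2.0), function(cl) {
    res <- vapply(3:5, function(s) {
      p <- small_params(seed = s,
                        texture_corr_len_mm = c(control = cl, oa = cl + 0.1))
      ph <- generate_tibia_phantom(p, FALSE)
      v <- extract_vois(ph$mask)
      b <- v$boxes$SBM
      vol <- ph$volume[b$x[1]:b$x[2], b$z[1]:b$z[2], b$y[1]:b$y[2]]
      mk <- ph$mask[b$x[1]:b$x[2], b$z[1]:b$z[2], b$y[1]:b$y[2]]
      q <- quantize(vol, mk, 16)
      c(glcm_features(glcm(q, c(1, 0, 0)))[["homogeneity"]],
        glszm_features(glszm(q), sum(mk), 16)[["lae"]])
    }, numeric(2))
    rowMeans(res)
  }, numeric(2))
  expect_true(all(diff(vals[1, ]) > 0))  # GLCM homogeneity mean
  expect_true(all(diff(vals[2, ]) > 0))  # GLSZM large-area emphasis
})
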