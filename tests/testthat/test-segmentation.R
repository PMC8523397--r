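test_that("label propagation averages warped masks exactly", {
  d <- c(10, 10, 10)
  m1 <- array(FALSE, d); m1[3:6, 3:6, 3:6] <- TRUE
  id <- identity_transform(d)
  p1 <- propagate_and_average(list(m1), list(id), d)
  expect_equal(p1, array(as.numeric(m1), d))
  # two identical masks plus one complement
  p <- propagate_and_average(list(m1, m1, !m1), list(id, id, id), d)
  expect_true(all(p[m1] == 2 / 3))
  expect_true(all(p[!m1] == 1 / 3))
  # 20 random masks equal the brute-force voxel-wise mean
  set.seed(31)
  masks <- lapply(1:20, function(i) array(runif(prod(d)) > 0.5, d))
  pm <- propagate_and_average(masks, rep(list(id), 20), d)
  bf <- Reduce(`+`, lapply(masks, function(m) array(as.numeric(m), d))) / 20
  expect_equal(pm, bf)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_error(propagate_and_average(list(m1), list(id), c(8, 8, 8)), "grid")
})

test_that("fusion follows the weighted voxel-wise rule", {
  d <- c(8, 8, 8)
  set.seed(5)
  pa <- array(runif(prod(d)), d)
  pb <- array(runif(prod(d)), d)
  # w = 1 depends only on the atlas map
  f1 <- fuse_and_threshold(pa, pb, w = 1, t = 0.5)
  f2 <- fuse_and_threshold(pa, array(0, d), w = 1, t = 0.5)
  expect_identical(as.logical(f1), as.logical(f2))
  # identical maps: any w gives the same mask
  fa <- fuse_and_threshold(pa, pa, w = 0.1, t = 0.5)
  fb <- fuse_and_threshold(pa, pa, w = 0.9, t = 0.5)
  expect_identical(as.logical(fa), as.logical(fb))
  # before component filtering, the rule is the voxel-wise threshold
  fused <- 0.5 * pa + 0.5 * pb >= 0.5
  lab <- tibrad:::label_components_cpp(array(fused, d), d, 6L)
  keep <- which.max(tabulate(lab[lab > 0]))
  expect_identical(as.logical(fuse_and_threshold(pa, pb, 0.5, 0.5)),
                   as.logical(lab == keep))
  expect_error(fuse_and_threshold(pa, array(0, c(4, 4, 4))), "grid")
})

test_that("Dice matches direct voxel counting and is symmetric", {
  d <- c(6, 6, 6)
  a <- array(FALSE, d); a[1:2, 1:2, 1:2] <- TRUE
  b <- a
  expect_equal(dice(a, b), 1.0)
  disjoint <- array(FALSE, d); disjoint[5:6, 5:6, 5:6] <- TRUE
  expect_equal(dice(a, disjoint), 0.0)
  # two 8-voxel cubes overlapping in 4 voxels
  c1 <- array(FALSE, d); c1[1:2, 1:2, 1:2] <- TRUE
  c2 <- array(FALSE, d); c2[1:2, 1:2, 2:3] <- TRUE
  expect_equal(dice(c1, c2), 2 * 4 / (8 + 8))
  set.seed(9)
  for (i in 1:5) {
    x <- array(runif(prod(d)) > 0.5, d)
    y <- array(runif(prod(d)) > 0.5, d)
    expect_equal(dice(x, y), dice(y, x))
  }
  expect_error(dice(array(FALSE, d), array(FALSE, d)), "empty")
})

test_that("appearance classifier learns the phantom and is reproducible", {
  ph <- small_phantom(seed = 41L)
  atl <- list(list(volume = ph$volume, mask = ph$mask))
  clf <- train_appearance_classifier(atl, n_per_class = 800, num_trees = 40,
                                     seed = 3L)
  p <- predict_voxel_probabilities(clf, ph$volume, downsample = 2)
  acc <- mean((p >= 0.5) == as.logical(ph$mask))
  expect_gt(acc, 0.9)
  expect_true(all(p >= 0 & p <= 1))
  # determinism
  clf2 <- train_appearance_classifier(atl, n_per_class = 800, num_trees = 40,
                                      seed = 3L)
  p2 <- predict_voxel_probabilities(clf2, ph$volume, downsample = 2)
  expect_identical(p, p2)
  # label inversion flips the probabilities
  atl_inv <- list(list(volume = ph$volume,
                       mask = image_volume(array(!ph$mask, dim(ph$mask)),
                                           voxel_spacing(ph$mask))))
  clf_inv <- train_appearance_classifier(atl_inv, n_per_class = 800,
                                         num_trees = 40, seed = 3L)
  p_inv <- predict_voxel_probabilities(clf_inv, ph$volume, downsample = 2)
  expect_lt(mean(abs(p_inv - (1 - p))), 0.1)
})

test_that("single-class atlas voxels are rejected", {
  d <- c(16, 16, 16)
  atl <- list(list(volume = image_volume(array(rnorm(prod(d)), d), c(1, 1, 1)),
                   mask = array(TRUE, d)))
  expect_error(train_appearance_classifier(atl, n_per_class = 50,
                                           num_trees = 10),
               "single class")
})
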