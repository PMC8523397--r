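# analytic two-spine slab mask for landmark tests: a block with two
# rectangular towers of configurable heights and positions
two_spine_slab <- function(d = c(40, 30, 20), base_top = 20,
                           c1 = 12, h1 = 6, c2 = 28, h2 = 4, width = 2) {
  m <- array(FALSE, d)
  m[3:(d[1] - 2), 1:base_top, 3:(d[3] - 2)] <- TRUE
  m[(c1 - width):(c1 + width), 1:(base_top + h1), 8:12] <- TRUE
  m[(c2 - width):(c2 + width), 1:(base_top + h2), 8:12] <- TRUE
  m
}

test_that("spine detection returns the planted landmark columns", {
  m <- two_spine_slab()
  sp <- detect_tibial_spines(m)
  expect_equal(sp$spine1[["x"]], 12)
  expect_equal(sp$spine1[["z"]], 26)
  expect_equal(sp$spine2[["x"]], 28)
  expect_equal(sp$spine2[["z"]], 24)
  # on generated phantoms the detected columns match the generator's
  # bookkeeping within one voxel
  for (s in c(51L, 52L)) {
    ph <- small_phantom(seed = s, oa = s %% 2 == 0)
    det <- detect_tibial_spines(ph$mask)
    planted <- attr(ph$mask, "spine_cols")
    expect_lte(max(abs(sort(c(det$spine1[["x"]], det$spine2[["x"]])) -
                         planted)), 1)
  }
})

test_that("equal-height spines break ties toward the smaller column", {
  m <- two_spine_slab(h1 = 5, h2 = 5)
  sp <- detect_tibial_spines(m)
  expect_equal(sp$spine1[["x"]], 12)
  expect_equal(sp$spine2[["x"]], 28)
})

test_that("a flat-top slab has no two separated maxima", {
  m <- array(FALSE, c(30, 20, 15))
  m[5:25, 1:10, 4:12] <- TRUE
  expect_error(detect_tibial_spines(m), "no two separated")
})

test_that("compartments partition the plateau columns around the spines", {
  m <- two_spine_slab(d = c(41, 30, 20), c1 = 13, c2 = 29, h1 = 6, h2 = 4)
  sp <- detect_tibial_spines(m)
  comps <- split_compartments(m, sp)
  expect_equal(comps$medial$x_range, c(3, 13))
  expect_equal(comps$lateral$x_range, c(29, 39))
  # symmetric geometry: equal column counts within 1
  wm <- diff(comps$medial$x_range)
  wl <- diff(comps$lateral$x_range)
  expect_lte(abs(wm - wl), 1)
  # union of regions plus inter-spine gap covers all occupied columns
  cols <- sort(c(comps$medial$x_range[1]:comps$medial$x_range[2],
                 (13 + 1):(29 - 1),
                 comps$lateral$x_range[1]:comps$lateral$x_range[2]))
  occupied <- which(apply(m, 1, any))
  expect_equal(cols, occupied)
  # laterality flip
  flipped <- split_compartments(m, sp, right_knee = FALSE)
  expect_equal(flipped$medial$x_range, comps$lateral$x_range)
})

test_that("spines closer than 4 voxels are rejected", {
  m <- two_spine_slab(c1 = 14, c2 = 17, width = 1)
  sp <- list(spine1 = c(x = 14, z = 26, y = 10),
             spine2 = c(x = 17, z = 24, y = 10))
  expect_error(split_compartments(m, sp), "too close")
})

test_that("interface anchor tracks the top surface at the middle column", {
  d <- c(30, 40, 20)
  m <- array(FALSE, d)
  m[3:28, 1:25, 3:18] <- TRUE
  comp <- list(x_range = c(3, 28), y_range = c(3, 18))
  flat <- find_interface_depth(m, comp)
  expect_true(all(flat$depth == 25))
  expect_equal(flat$anchor[["z"]], 25)
  # sloped interface: top height rises with the column index
  m2 <- array(FALSE, d)
  for (i in 3:28) m2[i, 1:(10 + i %/% 2), 3:18] <- TRUE
  sl <- find_interface_depth(m2, comp)
  mid <- 3:28
  mid <- mid[ceiling(length(mid) / 2)]
  expect_equal(sl$anchor[["z"]], 10 + mid %/% 2)
  # dilating the mask below the interface leaves the anchor unchanged
  m3 <- m2
  m3[2, 1:5, 3:18] <- TRUE
  sl3 <- find_interface_depth(m3, comp)
  expect_equal(sl3$anchor, sl$anchor)
})

test_that("VOI tiers are 10 mm high, stacked, and pairwise disjoint", {
  box_overlap <- function(a, b) {
    all(vapply(c("x", "z", "y"), function(ax) {
      a[[ax]][1] <= b[[ax]][2] && b[[ax]][1] <= a[[ax]][2]
    }, logical(1)))
  }
  for (s in 61:68) {
    ph <- generate_tibia_phantom(small_params(seed = s), oa = s %% 2 == 0)
    v <- extract_vois(ph$mask)
    expect_named(v$boxes, c("SBM", "MidM", "TBM", "SBL", "MidL", "TBL"))
    heights <- vapply(v$boxes, function(b) b$z[2] - b$z[1] + 1, numeric(1))
    expect_true(all(heights == round(10 / 0.5)))
    expect_equal(v$boxes$SBM$z[1] - 1, v$boxes$MidM$z[2])
    expect_equal(v$boxes$MidM$z[1] - 1, v$boxes$TBM$z[2])
    expect_equal(v$boxes$SBL$z[1] - 1, v$boxes$MidL$z[2])
    prs <- utils::combn(names(v$boxes), 2)
    for (cc in seq_len(ncol(prs))) {
      expect_false(box_overlap(v$boxes[[prs[1, cc]]], v$boxes[[prs[2, cc]]]))
    }
  }
})

test_that("VOI heights reproduce 10 mm for non-half-mm spacings", {
  m <- two_spine_slab(d = c(40, 70, 20), base_top = 55, c1 = 12, c2 = 28)
  m <- image_volume(m, c(1.2, 0.6, 1.2))
  v <- extract_vois(m)
  heights <- vapply(v$boxes, function(b) b$z[2] - b$z[1] + 1, numeric(1))
  expect_true(all(heights == round(10 / 0.6)))
})

test_that("extraction is translation-equivariant", {
  ph <- small_phantom(seed = 71L)
  d <- dim(ph$mask)
  m <- array(as.logical(ph$mask), d)
  shifted <- array(FALSE, d)
  shifted[3:d[1], , ] <- m[1:(d[1] - 2), , ]
  v0 <- extract_vois(image_volume(array(m, d), c(0.5, 0.5, 0.5)))
  v1 <- extract_vois(image_volume(shifted, c(0.5, 0.5, 0.5)))
  for (nm in names(v0$boxes)) {
    expect_equal(v1$boxes[[nm]]$x, v0$boxes[[nm]]$x + 2L)
    expect_equal(v1$boxes[[nm]]$z, v0$boxes[[nm]]$z)
    expect_equal(v1$boxes[[nm]]$y, v0$boxes[[nm]]$y)
  }
})

test_that("insufficient bone depth names the failing compartment", {
  m <- two_spine_slab(d = c(40, 30, 20), base_top = 20)  # ~13 mm at 1 mm
  m <- image_volume(m, c(1, 1, 1))
  expect_error(extract_vois(m), "insufficient bone depth.*medial")
})

test_that("VOI sets serialize losslessly to JSON", {
  ph <- small_phantom(seed = 61L)
  v <- extract_vois(ph$mask)
  path <- tempfile(fileext = ".json")
  write_voiset(v, path)
  v2 <- read_voiset(path)
  expect_equal(v2$boxes, v$boxes)
  expect_equal(v2$spacing_mm, v$spacing_mm)
  lm <- voi_label_map(v, dim(ph$mask))
  expect_equal(sort(unique(as.integer(lm))), 0:6)
})
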