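#' Mutual information between two volumes
#'
#' Joint-histogram estimate (default 32 bins per channel) of the mutual
#' information between two equally shaped scalar volumes, in nats.
#'
#' @param a,b numeric arrays of equal shape.
#' @param bins histogram bins per channel.
#' @return scalar mutual information (>= 0 up to estimation noise).
#' @export
mutual_information <- function(a, b, bins = 32) {
  stopifnot(length(a) == length(b), bins >= 2)
  a <- as.numeric(a); b <- as.numeric(b)
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ia <- pmin(bins, floor((a - ra[1]) / diff(ra) * bins) + 1L)
  ib <- pmin(bins, floor((b - rb[1]) / diff(rb) * bins) + 1L)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  pj <- matrix(p, bins, bins)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (px[row(pj)[nz]] * py[col(pj)[nz]])))
}

# block-mean downsampling by an integer factor (crops to a divisible extent)
downsample_volume <- function(vol, f) {
  if (f == 1) return(vol)
  d <- dim(vol)
  dd <- (d %/% f) * f
  v <- vol[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3]), drop = FALSE]
  nd <- dd %/% f
  a <- array(v, c(f, nd[1], f, nd[2], f, nd[3]))
  out <- apply(a, c(2, 4, 6), mean)
  array(out, nd)
}

# full coordinate grids (1-based voxel indices) for given dims
coord_grids <- function(d) {
  list(x = rep(seq_len(d[1]), times = d[2] * d[3]),
       z = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
       y = rep(seq_len(d[3]), each = d[1] * d[2]))
}

# Affine parameter vector p = c(t1,t2,t3, m11..m33 row-major deviation from I),
# acting about the centre c of the target grid, in full-resolution voxel
# coordinates: x_atlas = (I+M) (x - c) + c + t.
apply_affine_params <- function(p, xs, zs, ys, centre) {
  t <- p[1:3]
  M <- diag(3)
  if (length(p) > 3) M <- M + matrix(p[4:12], 3, 3, byrow = TRUE)
  dx <- xs - centre[1]; dz <- zs - centre[2]; dy <- ys - centre[3]
  list(x = M[1, 1] * dx + M[1, 2] * dz + M[1, 3] * dy + centre[1] + t[1],
       z = M[2, 1] * dx + M[2, 2] * dz + M[2, 3] * dy + centre[2] + t[2],
       y = M[3, 1] * dx + M[3, 2] * dz + M[3, 3] * dy + centre[3] + t[3])
}

#' Default registration configuration
#'
#' @param nonrigid run the non-rigid refinement stage.
#' @param affine_dof `"translation"` or `"affine"` (translation then full
#'   12-parameter refinement).
#' @param mi_bins joint-histogram bins for the mutual-information similarity.
#' @param coarse_range half-width (in 4x-downsampled voxels) of the initial
#'   integer translation search.
#' @param ctrl_spacing control-point spacing (voxels) of the non-rigid stage.
#' @param patch,search block-matching patch and search radii (voxels).
#' @param maxit Nelder-Mead iteration cap per affine stage.
#' @return a named list of settings.
#' @export
registration_config <- function(nonrigid = TRUE, affine_dof = "affine",
                                mi_bins = 32, coarse_range = 4,
                                ctrl_spacing = 12, patch = 5, search = 3,
                                maxit = 100) {
  list(nonrigid = nonrigid, affine_dof = affine_dof, mi_bins = mi_bins,
       coarse_range = coarse_range, ctrl_spacing = ctrl_spacing,
       patch = patch, search = search, maxit = maxit)
}

#' Register an atlas image to a target image
#'
#' Two-stage registration matching the multi-atlas contract: a global affine
#' stage (coarse integer translation search followed by Nelder-Mead
#' refinement of a 12-parameter affine, maximising 32-bin mutual
#' information), then a non-rigid refinement (control-grid block matching
#' interpolated to a dense displacement field). The returned transform is
#' guaranteed not to decrease mutual information with the target relative to
#' the identity: stages that fail this check are discarded and the transform
#' is flagged.
#'
#' @param atlas_image,target_image numeric 3-D arrays of equal shape.
#' @param config a [registration_config()] list.
#' @return a `tibrad_transform`: affine parameters, optional dense
#'   displacement field, per-stage mutual information diagnostics and a
#'   `converged` flag.
#' @export
register_atlas <- function(atlas_image, target_image,
                           config = registration_config()) {
  stopifnot(identical(dim(atlas_image), dim(target_image)))
  d <- dim(target_image)
  centre <- (d + 1) / 2
  bins <- config$mi_bins

  a2 <- downsample_volume(atlas_image, 2)
  t2 <- downsample_volume(target_image, 2)
  a4 <- downsample_volume(a2, 2)
  t4 <- downsample_volume(t2, 2)
  d4 <- dim(t4)

  # stage 0: coarse integer translation search at 4x downsampling, on
  # overlapping subarrays (no resampling needed)
  r <- config$coarse_range
  best <- c(0, 0, 0); best_mi <- -Inf
  for (sx in -r:r) for (sz in -r:r) for (sy in -r:r) {
    ax <- max(1, 1 - sx):min(d4[1], d4[1] - sx)
    az <- max(1, 1 - sz):min(d4[2], d4[2] - sz)
    ay <- max(1, 1 - sy):min(d4[3], d4[3] - sy)
    if (length(ax) < 4 || length(az) < 4 || length(ay) < 4) next
    mi <- mutual_information(a4[ax + sx, az + sz, ay + sy], t4[ax, az, ay], bins)
    if (mi > best_mi + 1e-12) { best_mi <- mi; best <- c(sx, sz, sy) }
  }

  # objective at 2x downsampling, affine defined in full-res coordinates
  g2 <- coord_grids(dim(t2))
  full_from_ds2 <- function(v) 2 * v - 0.5
  ds2_from_full <- function(v) (v + 0.5) / 2
  t2num <- as.numeric(t2)
  neg_mi <- function(p) {
    co <- apply_affine_params(p, full_from_ds2(g2$x), full_from_ds2(g2$z),
                              full_from_ds2(g2$y), centre)
    s <- sample_trilinear_cpp(as.numeric(a2), dim(a2), ds2_from_full(co$x),
                              ds2_from_full(co$z), ds2_from_full(co$y),
                              min(a2))
    -mutual_information(s, t2num, bins)
  }
  p_t <- c(best * 4, rep(0, 9))  # coarse shift in full-res voxels
  opt_t <- optim(p_t[1:3], function(q) neg_mi(c(q, rep(0, 9))),
                 method = "Nelder-Mead",
                 control = list(maxit = config$maxit, reltol = 1e-7))
  p_aff <- c(opt_t$par, rep(0, 9))
  if (identical(config$affine_dof, "affine")) {
    opt_a <- optim(p_aff, neg_mi, method = "Nelder-Mead",
                   control = list(maxit = 3 * config$maxit, reltol = 1e-7))
    if (opt_a$value <= opt_t$value) p_aff <- opt_a$par
  }

  # evaluate stages at full resolution
  gf <- coord_grids(d)
  atlas_num <- as.numeric(atlas_image)
  target_num <- as.numeric(target_image)
  bg <- min(atlas_num)
  resample_with <- function(p, disp = NULL) {
    xs <- gf$x; zs <- gf$z; ys <- gf$y
    if (!is.null(disp)) {
      xs <- xs + as.numeric(disp$x); zs <- zs + as.numeric(disp$z)
      ys <- ys + as.numeric(disp$y)
    }
    co <- apply_affine_params(p, xs, zs, ys, centre)
    sample_trilinear_cpp(atlas_num, d, co$x, co$z, co$y, bg)
  }
  mi_identity <- mutual_information(atlas_num, target_num, bins)
  mi_affine <- mutual_information(resample_with(p_aff), target_num, bins)

  disp <- NULL
  mi_final <- mi_affine
  if (isTRUE(config$nonrigid) && mi_affine >= mi_identity) {
    moving <- array(resample_with(p_aff), d)
    ctrl <- expand.grid(
      x = seq(config$patch + 1, d[1] - config$patch, by = config$ctrl_spacing),
      z = seq(config$patch + 1, d[2] - config$patch, by = config$ctrl_spacing),
      y = seq(config$patch + 1, d[3] - config$patch, by = config$ctrl_spacing))
    dm <- block_match_cpp(target_num, as.numeric(moving), d,
                          as.matrix(ctrl), config$patch, config$search)
    nc <- c(length(unique(ctrl$x)), length(unique(ctrl$z)),
            length(unique(ctrl$y)))
    smooth_ctrl <- function(v) {
      arr <- array(v, nc)
      if (min(nc) >= 3) arr <- gaussian_smooth(arr, 0.7)
      arr
    }
    cx <- smooth_ctrl(dm[, 1]); cz <- smooth_ctrl(dm[, 2]); cy <- smooth_ctrl(dm[, 3])
    # interpolate control displacements to the full grid
    to_ctrl <- function(v, first, spacing, n) {
      pmin(pmax((v - first) / spacing + 1, 1), n)
    }
    ccx <- to_ctrl(gf$x, min(ctrl$x), config$ctrl_spacing, nc[1])
    ccz <- to_ctrl(gf$z, min(ctrl$z), config$ctrl_spacing, nc[2])
    ccy <- to_ctrl(gf$y, min(ctrl$y), config$ctrl_spacing, nc[3])
    disp <- list(x = array(sample_trilinear_cpp(as.numeric(cx), nc, ccx, ccz, ccy, 0), d),
                 z = array(sample_trilinear_cpp(as.numeric(cz), nc, ccx, ccz, ccy, 0), d),
                 y = array(sample_trilinear_cpp(as.numeric(cy), nc, ccx, ccz, ccy, 0), d))
    mi_nr <- mutual_information(resample_with(p_aff, disp), target_num, bins)
    if (mi_nr >= mi_affine) mi_final <- mi_nr else disp <- NULL
  }

  converged <- TRUE
  if (mi_final < mi_identity) {
    # fall back to the identity transform rather than degrade alignment
    p_aff <- rep(0, 12)
    disp <- NULL
    mi_final <- mi_identity
    converged <- FALSE
  }
  structure(list(affine = p_aff, disp = disp, centre = centre,
                 target_dim = d,
                 mi = c(identity = mi_identity, affine = mi_affine,
                        final = mi_final),
                 converged = converged),
            class = "tibrad_transform")
}

#' Identity transform on a grid (mainly for tests and single-atlas cases)
#' @param dims target grid dimensions.
#' @return a `tibrad_transform` representing the identity map.
#' @export
identity_transform <- function(dims) {
  structure(list(affine = rep(0, 12), disp = NULL, centre = (dims + 1) / 2,
                 target_dim = dims,
                 mi = c(identity = NA, affine = NA, final = NA),
                 converged = TRUE),
            class = "tibrad_transform")
}

#' Apply a spatial transform to a volume
#'
#' Resamples `vol` (defined on the atlas grid) onto the transform's target
#' grid: target voxel `x` receives `vol(A(x + d(x)))`.
#'
#' @param vol numeric or logical 3-D array on the atlas grid.
#' @param transform a `tibrad_transform`.
#' @param interpolation `"linear"` or `"nearest"` (use nearest for label maps).
#' @param background value used outside the atlas grid.
#' @return numeric array on the target grid.
#' @export
apply_transform <- function(vol, transform, interpolation = c("linear", "nearest"),
                            background = 0) {
  interpolation <- match.arg(interpolation)
  d <- transform$target_dim
  gf <- coord_grids(d)
  xs <- gf$x; zs <- gf$z; ys <- gf$y
  if (!is.null(transform$disp)) {
    xs <- xs + as.numeric(transform$disp$x)
    zs <- zs + as.numeric(transform$disp$z)
    ys <- ys + as.numeric(transform$disp$y)
  }
  co <- apply_affine_params(transform$affine, xs, zs, ys, transform$centre)
  f <- if (interpolation == "linear") sample_trilinear_cpp else sample_nearest_cpp
  array(f(as.numeric(vol), dim(vol), co$x, co$z, co$y, background), d)
}
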