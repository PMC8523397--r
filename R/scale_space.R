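#' Gaussian scale-space filtering and the 49-channel appearance stack
#'
#' The voxel-wise appearance model used for tibia segmentation operates on a
#' Gaussian scale-space decomposition of the image: the raw intensity plus,
#' at each of three scales, the smoothed image, the three first-order
#' derivatives, the six second-order (Hessian) entries, the gradient
#' magnitude, the Laplacian, the Gaussian curvature (Hessian determinant) and
#' the three Hessian eigenvalues sorted in descending order. With three
#' scales this yields 1 + 3 x 16 = 49 channels.
#'
#' @name scale_space
NULL

# 1-D Gaussian (derivative) kernel sampled on integer offsets.
gauss_kernel <- function(sigma, order = 0) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) {
    k <- x * g
    # normalize for exact unit response to a unit ramp (sum is 0 by symmetry)
    k / sum(k * x)
  } else {
    k <- (x^2 - sigma^2) / sigma^4 * g
    k <- k - mean(k)               # zero response to constants
    s2 <- sum(k * x^2) / 2         # unit response to x^2/2 curvature
    k / s2
  }
}

# Convolution matrix with replicated (clamped) boundaries.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + kernel[k]
  }
  K
}

# Separable filtering of a 3-D array: per-axis Gaussian kernels of the given
# derivative orders. sigma_vox is per-axis (voxels).
separable_filter <- function(vol, sigma_vox, orders = c(0, 0, 0)) {
  d <- dim(vol)
  out <- vol
  attributes(out) <- list(dim = d)
  # axis 1
  K <- conv_matrix(d[1], gauss_kernel(sigma_vox[1], orders[1]))
  out <- array(K %*% matrix(out, d[1], d[2] * d[3]), d)
  # axis 2
  K <- conv_matrix(d[2], gauss_kernel(sigma_vox[2], orders[2]))
  tmp <- aperm(out, c(2, 1, 3))
  tmp <- array(K %*% matrix(tmp, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
  out <- aperm(tmp, c(2, 1, 3))
  # axis 3
  K <- conv_matrix(d[3], gauss_kernel(sigma_vox[3], orders[3]))
  tmp <- aperm(out, c(3, 1, 2))
  tmp <- array(K %*% matrix(tmp, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
  aperm(tmp, c(2, 3, 1))
}

#' Gaussian smoothing of a 3-D volume
#'
#' @param vol numeric 3-D array.
#' @param sigma_vox per-axis standard deviation in voxels (scalar recycled).
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(vol, sigma_vox) {
  sigma_vox <- rep(as.numeric(sigma_vox), length.out = 3)
  if (all(sigma_vox <= 0)) return(vol)
  separable_filter(vol, pmax(sigma_vox, 1e-6))
}

# Eigenvalues of a symmetric 3x3 matrix field, vectorized; returns a list of
# three vectors sorted descending. Entries: xx, yy, zz, xy, xz, yz.
symeig3 <- function(xx, yy, zz, xy, xz, yz) {
  p1 <- xy^2 + xz^2 + yz^2
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 1e-12
  pe <- ifelse(ok, p, 1)
  bxx <- (xx - q) / pe; byy <- (yy - q) / pe; bzz <- (zz - q) / pe
  bxy <- xy / pe; bxz <- xz / pe; byz <- yz / pe
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  list(e1, e2, e3)
}

#' Compute the 49-channel Gaussian scale-space feature stack
#'
#' Channel layout: channel 1 is the raw intensity; for each scale (in order)
#' the 16 channels are smoothed, d/dx, d/dz, d/dy, Hxx, Hzz, Hyy, Hxz, Hxy,
#' Hzy, gradient magnitude, Laplacian, Gaussian curvature (det of Hessian),
#' and the three Hessian eigenvalues sorted descending. Derivatives are in
#' physical units (per mm), using the volume's voxel spacing.
#'
#' @param image numeric 3-D array with a `spacing` attribute (see
#'   [image_volume()]).
#' @param scales_mm three positive Gaussian scales in mm.
#' @return numeric matrix with one row per voxel and 49 named columns, plus
#'   attributes `dims` and `scales_mm`.
#' @export
compute_scale_space_features <- function(image, scales_mm = c(0.5, 1, 2)) {
  stopifnot(length(scales_mm) == 3, all(scales_mm > 0))
  sp <- voxel_spacing(image)
  d <- dim(image)
  nvox <- prod(d)
  out <- matrix(NA_real_, nvox, 49)
  nm <- character(49)
  out[, 1] <- as.numeric(image)
  nm[1] <- "intensity"
  col <- 2L
  for (s in scales_mm) {
    sig <- s / sp  # per-axis sigma in voxels
    base <- sprintf("s%g", s)
    sm <- separable_filter(image, sig, c(0, 0, 0))
    dx <- separable_filter(image, sig, c(1, 0, 0)) / sp[1]
    dz <- separable_filter(image, sig, c(0, 1, 0)) / sp[2]
    dy <- separable_filter(image, sig, c(0, 0, 1)) / sp[3]
    hxx <- separable_filter(image, sig, c(2, 0, 0)) / sp[1]^2
    hzz <- separable_filter(image, sig, c(0, 2, 0)) / sp[2]^2
    hyy <- separable_filter(image, sig, c(0, 0, 2)) / sp[3]^2
    hxz <- separable_filter(image, sig, c(1, 1, 0)) / (sp[1] * sp[2])
    hxy <- separable_filter(image, sig, c(1, 0, 1)) / (sp[1] * sp[3])
    hzy <- separable_filter(image, sig, c(0, 1, 1)) / (sp[2] * sp[3])
    grad <- sqrt(dx^2 + dz^2 + dy^2)
    lap <- hxx + hzz + hyy
    gc <- hxx * (hzz * hyy - hzy^2) - hxz * (hxz * hyy - hzy * hxy) +
      hxy * (hxz * hzy - hzz * hxy)
    ev <- symeig3(as.numeric(hxx), as.numeric(hzz), as.numeric(hyy),
                  as.numeric(hxz), as.numeric(hxy), as.numeric(hzy))
    chans <- list(sm, dx, dz, dy, hxx, hzz, hyy, hxz, hxy, hzy,
                  grad, lap, gc, ev[[1]], ev[[2]], ev[[3]])
    names(chans) <- paste0(base, "_", c(
      "smooth", "dx", "dz", "dy", "hxx", "hzz", "hyy", "hxz", "hxy", "hzy",
      "gradmag", "laplacian", "gausscurv", "eig1", "eig2", "eig3"))
    for (cn in seq_along(chans)) {
      out[, col] <- as.numeric(chans[[cn]])
      nm[col] <- names(chans)[cn]
      col <- col + 1L
    }
  }
  colnames(out) <- nm
  bad <- which(!is.finite(out), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite values in scale-space channel %d (%s)",
                 bad[1, 2], nm[bad[1, 2]]))
  }
  attr(out, "dims") <- d
  attr(out, "scales_mm") <- scales_mm
  out
}
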