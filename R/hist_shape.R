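#' Twelve histogram-based intensity features
#'
#' min, max, mean, median, SD, skewness, kurtosis (Pearson, i.e. 3 for a
#' normal), range, interquartile range, entropy and energy of a 16-bin
#' histogram of the in-mask intensities, and the peak (centre of the most
#' populated bin). Zero-variance input returns 0 for skewness and kurtosis
#' and the mean for the peak (documented convention).
#'
#' @param volume numeric 3-D array.
#' @param mask logical array of the same shape.
#' @param bins histogram bins for entropy/energy/peak.
#' @return named numeric vector of length 12.
#' @export
histogram_features <- function(volume, mask, bins = 16) {
  v <- volume[mask]
  if (length(v) < 2) stop("need at least 2 in-mask voxels")
  m <- mean(v); s <- sd(v)
  if (s > 0) {
    skew <- mean((v - m)^3) / s^3 * (length(v) / (length(v) - 1))^(3 / 2)
    kurt <- mean((v - m)^4) / (mean((v - m)^2))^2
  } else {
    skew <- 0; kurt <- 0
  }
  if (diff(range(v)) > 0) {
    h <- tabulate(pmin(bins, floor((v - min(v)) / diff(range(v)) * bins) + 1L),
                  nbins = bins)
    p <- h / sum(h)
    ent <- -sum(p[p > 0] * log2(p[p > 0]))
    ene <- sum(p^2)
    centres <- min(v) + (seq_len(bins) - 0.5) * diff(range(v)) / bins
    peak <- centres[which.max(h)]
  } else {
    ent <- 0; ene <- 1; peak <- m
  }
  c(hist_min = min(v), hist_max = max(v), hist_mean = m,
    hist_median = median(v), hist_sd = if (is.na(s)) 0 else s,
    hist_skewness = skew, hist_kurtosis = kurt,
    hist_range = diff(range(v)),
    hist_iqr = unname(quantile(v, 0.75) - quantile(v, 0.25)),
    hist_entropy = ent, hist_energy = ene, hist_peak = peak)
}

# one pass of Chaikin corner cutting on a closed polygon (x, y vectors);
# reduces the staircase bias of marching-squares contours so digital-circle
# perimeters land within a few percent of the true circumference
chaikin <- function(x, y) {
  n <- length(x)
  if (n < 4) return(list(x = x, y = y))
  closed <- x[1] == x[n] && y[1] == y[n]
  if (closed) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  xn <- c(rbind(0.75 * x + 0.25 * c(x[-1], x[1]),
                0.25 * x + 0.75 * c(x[-1], x[1])))
  yn <- c(rbind(0.75 * y + 0.25 * c(y[-1], y[1]),
                0.25 * y + 0.75 * c(y[-1], y[1])))
  list(x = c(xn, xn[1]), y = c(yn, yn[1]))
}

# marching-squares contour perimeter and pixel area of a binary 2-D slice
slice_contour_stats <- function(sl) {
  area <- sum(sl)
  if (area < 2) return(NULL)
  z <- matrix(0, nrow(sl) + 2, ncol(sl) + 2)
  z[2:(nrow(sl) + 1), 2:(ncol(sl) + 1)] <- sl * 1
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  per <- sum(vapply(cl, function(cc) {
    s1 <- chaikin(cc$x, cc$y)
    sm <- chaikin(s1$x, s1$y)
    sum(sqrt(diff(sm$x)^2 + diff(sm$y)^2))
  }, numeric(1)))
  list(area = area, perimeter = per)
}

# descriptors of one sagittal binary slice
slice_shape_descriptors <- function(sl) {
  st <- slice_contour_stats(sl)
  if (is.null(st)) return(NULL)
  idx <- which(sl, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  rr <- sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cy)^2)
  rmean <- mean(rr); rsd <- sd(rr)
  # circular variance: normalized radial spread (0 for a perfect disk edge)
  circ_var <- if (rmean > 0) (rsd / rmean)^2 else 0
  # solidity via the convex hull of the pixel centres
  hull <- grDevices::chull(idx[, 1], idx[, 2])
  hx <- idx[hull, 1]; hy <- idx[hull, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  solidity <- if (hull_area > 0) min(st$area / hull_area, 1) else 1
  # eccentricity from second moments
  mxx <- mean((idx[, 1] - cx)^2); myy <- mean((idx[, 2] - cy)^2)
  mxy <- mean((idx[, 1] - cx) * (idx[, 2] - cy))
  tr <- mxx + myy
  dt <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (tr + dt) / 2; l2 <- (tr - dt) / 2
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  c(compactness = 4 * pi * st$area / st$perimeter^2,
    solidity = solidity,
    circular_variance = circ_var,
    radial_mean = rmean / sqrt(st$area / pi),  # normalized, scale-free
    radial_sd = if (rmean > 0) rsd / rmean else 0,
    eccentricity = ecc)
}

#' Seventeen whole-bone shape features
#'
#' Six sagittal-slice descriptors (compactness `4*pi*A/P^2`, solidity,
#' circular variance, normalized radial mean, normalized radial SD,
#' eccentricity) aggregated as mean and SD across slices (12 features), plus
#' five volumetric descriptors: volume in mm^3, surface-to-volume ratio
#' (exposed voxel faces per volume, 1/mm), and the three bounding-box
#' extents in mm.
#'
#' @param mask logical 3-D array.
#' @param spacing_mm voxel spacing (defaults to the mask's attribute).
#' @return named numeric vector of length 17 (`shape_*`).
#' @export
shape_features <- function(mask, spacing_mm = voxel_spacing(mask)) {
  if (!any(mask)) stop("mask is empty")
  d <- dim(mask)
  descs <- list()
  for (i in seq_len(d[1])) {
    sl <- mask[i, , ]
    if (sum(sl) < 2) next   # single-voxel slices skipped
    ds <- slice_shape_descriptors(sl)
    if (!is.null(ds)) descs[[length(descs) + 1]] <- ds
  }
  if (length(descs) == 0) stop("no usable sagittal slices")
  M <- do.call(rbind, descs)
  agg <- c(colMeans(M), apply(M, 2, sd))
  names(agg) <- c(paste0("shape_", colnames(M), "_mean"),
                  paste0("shape_", colnames(M), "_sd"))
  agg[is.na(agg)] <- 0
  vol_mm3 <- sum(mask) * prod(spacing_mm)
  # exposed faces (6-neighbourhood) weighted by face area
  m <- array(as.integer(mask), d)
  fx <- sum(abs(m[-1, , , drop = FALSE] - m[-d[1], , , drop = FALSE])) +
    sum(m[1, , ]) + sum(m[d[1], , ])
  fz <- sum(abs(m[, -1, , drop = FALSE] - m[, -d[2], , drop = FALSE])) +
    sum(m[, 1, ]) + sum(m[, d[2], ])
  fy <- sum(abs(m[, , -1, drop = FALSE] - m[, , -d[3], drop = FALSE])) +
    sum(m[, , 1]) + sum(m[, , d[3]])
  surf <- fx * spacing_mm[2] * spacing_mm[3] +
    fz * spacing_mm[1] * spacing_mm[3] + fy * spacing_mm[1] * spacing_mm[2]
  bb <- mask_bbox(mask)
  ext <- c((diff(bb$x) + 1) * spacing_mm[1],
           (diff(bb$z) + 1) * spacing_mm[2],
           (diff(bb$y) + 1) * spacing_mm[3])
  c(agg,
    shape_volume_mm3 = vol_mm3,
    shape_surface_to_volume = surf / vol_mm3,
    shape_extent_ml_mm = ext[1], shape_extent_si_mm = ext[2],
    shape_extent_ap_mm = ext[3])
}

#' Three orientation angles from the second-moment tensor
#'
#' Principal axes of the in-mask voxel coordinates (in mm): azimuth of the
#' first principal axis in the horizontal plane, its inclination from the
#' vertical axis, and the azimuth of the second principal axis. Angles in
#' degrees; azimuths are reported modulo 180.
#'
#' @param mask logical 3-D array.
#' @param spacing_mm voxel spacing.
#' @return named numeric vector of length 3 (`orient_*`).
#' @export
orientation_features <- function(mask, spacing_mm = voxel_spacing(mask)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 4) stop("mask too small for orientation")
  P <- sweep(idx, 2, c(0, 0, 0)) * rep(spacing_mm, each = nrow(idx))
  C <- cov(P)
  e <- eigen(C, symmetric = TRUE)
  ax1 <- e$vectors[, 1]; ax2 <- e$vectors[, 2]
  azim <- function(v) {
    a <- atan2(v[3], v[1]) * 180 / pi   # horizontal plane: (ML, AP)
    a %% 180
  }
  incl <- acos(pmin(abs(ax1[2]) / sqrt(sum(ax1^2)), 1)) * 180 / pi
  c(orient_azimuth1 = azim(ax1), orient_inclination1 = unname(incl),
    orient_azimuth2 = azim(ax2))
}
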