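#' Rotation-invariant uniform local binary patterns (slice-wise)
#'
#' Computes riu2 LBP codes (P = 8 circular neighbours, bilinear sampling) on
#' every sagittal slice of the VOI and pools the code histogram over slices.
#' Codes: 0-8 = number of "neighbour >= centre" bits for uniform patterns
#' (at most two 0/1 transitions on the circle), 9 = non-uniform. Features
#' are the 10 histogram fractions per radius.
#'
#' @param volume numeric 3-D array.
#' @param mask logical array of the same shape.
#' @param radii integer radii in pixels (default 1, 2, 3).
#' @param points number of circular neighbours (8).
#' @return named numeric vector, `lbp_r<r>_bin<k>` per radius and code class.
#' @export
lbp_features <- function(volume, mask, radii = c(1, 2, 3), points = 8) {
  stopifnot(all(radii >= 1), points == 8)
  d <- dim(volume)
  thin <- min(d[2], d[3])
  if (thin < 2 * max(radii) + 1) {
    stop(sprintf("VOI too thin for LBP radius %d (slice extent %d < %d)",
                 max(radii), thin, 2 * max(radii) + 1))
  }
  out <- numeric(0)
  for (r in radii) {
    counts <- numeric(points + 2)  # classes 0..points, non-uniform
    for (i in seq_len(d[1])) {
      sl <- volume[i, , ]
      mk <- mask[i, , ]
      if (!any(mk)) next
      counts <- counts + lbp_slice_hist(sl, mk, r, points)
    }
    tot <- sum(counts)
    frac <- if (tot > 0) counts / tot else counts
    names(frac) <- sprintf("lbp_r%d_bin%d", r, 0:(points + 1))
    out <- c(out, frac)
  }
  out
}

# riu2 code histogram for one 2-D slice; only pixels whose full neighbour
# circle lies inside the slice are coded.
lbp_slice_hist <- function(sl, mk, r, points = 8) {
  n1 <- nrow(sl); n2 <- ncol(sl)
  counts <- numeric(points + 2)
  rows <- (r + 1):(n1 - r)
  cols <- (r + 1):(n2 - r)
  if (length(rows) < 1 || length(cols) < 1) return(counts)
  sub <- mk[rows, cols, drop = FALSE]
  if (!any(sub)) return(counts)
  centre <- sl[rows, cols, drop = FALSE]
  ang <- 2 * pi * (0:(points - 1)) / points
  bits <- array(0L, c(length(rows), length(cols), points))
  for (k in seq_len(points)) {
    dx <- r * cos(ang[k]); dy <- r * sin(ang[k])
    x0 <- floor(dx); y0 <- floor(dy)
    fx <- dx - x0; fy <- dy - y0
    # integer offsets: keep the zero-weight sample in bounds
    x1 <- x0 + (fx > 1e-9); y1 <- y0 + (fy > 1e-9)
    nb <- (1 - fx) * (1 - fy) * sl[rows + x0, cols + y0, drop = FALSE] +
      fx * (1 - fy) * sl[rows + x1, cols + y0, drop = FALSE] +
      (1 - fx) * fy * sl[rows + x0, cols + y1, drop = FALSE] +
      fx * fy * sl[rows + x1, cols + y1, drop = FALSE]
    bits[, , k] <- (nb >= centre - 1e-12) * 1L
  }
  trans <- abs(bits[, , 1] - bits[, , points])
  for (k in seq_len(points - 1)) {
    trans <- trans + abs(bits[, , k + 1] - bits[, , k])
  }
  ones <- apply(bits, c(1, 2), sum)
  code <- ifelse(trans <= 2, ones, points + 1)
  tab <- tabulate(code[sub] + 1L, nbins = points + 2)
  counts + tab
}

# cached DC-free complex Gabor kernel in the frequency domain for a slice size
gabor_kernel_fft <- function(n1, n2, freq, theta, cache = NULL) {
  key <- sprintf("%d_%d_%g_%g", n1, n2, freq, theta)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  sigma <- 0.56 / freq
  half1 <- floor(n1 / 2); half2 <- floor(n2 / 2)
  x <- c(0:half1, -(n1 - half1 - 1):-1)   # wrapped coordinates
  y <- c(0:half2, -(n2 - half2 - 1):-1)
  X <- outer(x, rep(1, n2)); Y <- outer(rep(1, n1), y)
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  ker <- env * exp(2i * pi * freq * xr)
  ker <- ker - env * (sum(ker) / sum(env))  # DC-free: kernel sums to zero
  kf <- fft(ker)
  if (!is.null(cache)) cache[[key]] <- kf
  kf
}

#' Gabor filter-bank features (slice-wise)
#'
#' Applies a 2-D complex Gabor filter bank (DC-free kernels, bandwidth-matched
#' Gaussian envelope sigma = 0.56/frequency) to every sagittal slice via FFT
#' and summarizes the response magnitude inside the mask as mean and SD per
#' (frequency, angle) pair.
#'
#' @param volume numeric 3-D array.
#' @param mask logical array of the same shape.
#' @param frequencies spatial frequencies in cycles/pixel (all < 0.5).
#' @param angles orientations in radians.
#' @return named numeric vector `gabor_{mean,sd}_f<freq>_a<deg>`.
#' @export
gabor_features <- function(volume, mask,
                           frequencies = c(0.05, 0.08, 0.12, 0.18, 0.25,
                                           0.33, 0.42),
                           angles = seq(0, pi - pi / 12, by = pi / 12)) {
  stopifnot(length(frequencies) >= 1, length(angles) >= 1)
  if (any(frequencies >= 0.5)) {
    stop("Gabor frequency at or above the Nyquist limit (0.5 cycles/pixel)")
  }
  d <- dim(volume)
  nb <- length(frequencies) * length(angles)
  sums <- numeric(nb); sqs <- numeric(nb); ns <- numeric(nb)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(d[1])) {
    mk <- mask[i, , ]
    if (!any(mk)) next
    sl <- volume[i, , ]
    slf <- fft(sl)
    b <- 0L
    for (f in frequencies) for (a in angles) {
      b <- b + 1L
      kf <- gabor_kernel_fft(d[2], d[3], f, a, cache)
      resp <- fft(slf * kf, inverse = TRUE) / length(sl)
      mag <- Mod(resp)[mk]
      sums[b] <- sums[b] + sum(mag)
      sqs[b] <- sqs[b] + sum(mag^2)
      ns[b] <- ns[b] + length(mag)
    }
  }
  if (all(ns == 0)) stop("mask is empty")
  mu <- sums / ns
  vv <- pmax(sqs / ns - mu^2, 0)
  nmf <- character(nb); b <- 0L
  for (f in frequencies) for (a in angles) {
    b <- b + 1L
    nmf[b] <- sprintf("f%g_a%d", f, round(a * 180 / pi))
  }
  setNames(c(mu, sqrt(vv)),
           c(paste0("gabor_mean_", nmf), paste0("gabor_sd_", nmf)))
}
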