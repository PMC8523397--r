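#' Detect the two tibial spines
#'
#' Builds the top-surface height profile over medial-lateral columns
#' (maximum superior extent of the mask per sagittal slice) and returns the
#' two separated local maxima: the global highest surface point and the
#' second-highest local maximum at least `min_separation` columns away.
#' Ties are broken toward the smaller medial-lateral index.
#'
#' @param mask logical 3-D mask (medial-lateral, vertical, antero-posterior).
#' @param min_separation minimum medial-lateral distance in voxels.
#' @return list with `spine1`/`spine2` (each `c(x, z, y)`, `spine1` the
#'   taller) and the column height profile.
#' @export
detect_tibial_spines <- function(mask, min_separation = 8) {
  if (!any(mask)) stop("mask is empty")
  d <- dim(mask)
  # height (top z) per ML column; -Inf where the slice is empty
  H <- vapply(seq_len(d[1]), function(i) {
    sl <- mask[i, , , drop = FALSE]
    if (!any(sl)) return(-Inf)
    max(which(apply(sl[1, , , drop = FALSE], 2, any)))
  }, numeric(1))
  occupied <- which(is.finite(H))
  # strict-neighbourhood local maxima (plateau runs count once, at their
  # smallest index)
  # runs of equal height among occupied columns; a run is a peak when it is
  # strictly above both flanking heights, and its position is the run centre
  peaks <- integer(0)
  i <- occupied[1]
  last <- occupied[length(occupied)]
  while (i <= last) {
    j <- i
    while (j + 1 <= last && is.finite(H[j + 1]) && H[j + 1] == H[i]) j <- j + 1
    left <- if (i - 1 >= 1 && is.finite(H[i - 1])) H[i - 1] else -Inf
    right <- if (j + 1 <= d[1] && is.finite(H[j + 1])) H[j + 1] else -Inf
    if (H[i] > left && H[i] > right) {
      peaks <- c(peaks, floor((i + j) / 2))
    }
    i <- j + 1
  }
  ord <- order(-H[peaks], peaks)   # height desc, then smaller index (tie rule)
  peaks <- peaks[ord]
  if (length(peaks) < 1) stop("no surface maxima found")
  p1 <- peaks[1]
  p2 <- NA_integer_
  for (p in peaks[-1]) {
    if (abs(p - p1) >= min_separation) { p2 <- p; break }
  }
  if (is.na(p2)) {
    stop("mask has no two separated surface maxima (flat or single-spine top)")
  }
  at_y <- function(i) {
    sl <- mask[i, , ]
    zi <- as.integer(H[i])
    ys <- which(sl[zi, ])
    ys[ceiling(length(ys) / 2)]
  }
  list(spine1 = c(x = p1, z = unname(H[p1]), y = at_y(p1)),
       spine2 = c(x = p2, z = unname(H[p2]), y = at_y(p2)),
       profile = H)
}

#' Split the plateau into medial and lateral compartments
#'
#' Each compartment spans medial-lateral columns from its spine to the outer
#' border of the tibia; the inter-spine gap belongs to neither. Laterality
#' follows the right-knee convention (medial = smaller medial-lateral index);
#' set `right_knee = FALSE` to flip.
#'
#' @param mask logical 3-D mask.
#' @param spines result of [detect_tibial_spines()].
#' @param right_knee logical laterality flag.
#' @return list with `medial` and `lateral`, each `list(x_range, y_range)`.
#' @export
split_compartments <- function(mask, spines, right_knee = TRUE) {
  s1 <- spines$spine1[["x"]]; s2 <- spines$spine2[["x"]]
  lo <- min(s1, s2); hi <- max(s1, s2)
  if (hi - lo < 4) stop("tibial spines too close (< 4 voxels apart)")
  cols <- which(vapply(seq_len(dim(mask)[1]),
                       function(i) any(mask[i, , ]), logical(1)))
  left <- list(x_range = c(min(cols), lo), side = "left")
  right <- list(x_range = c(hi, max(cols)), side = "right")
  region_y <- function(reg) {
    xs <- reg$x_range[1]:reg$x_range[2]
    sub <- mask[xs, , , drop = FALSE]
    ys <- which(apply(sub, 3, any))
    reg$y_range <- range(ys)
    reg
  }
  left <- region_y(left); right <- region_y(right)
  if (right_knee) list(medial = left, lateral = right)
  else list(medial = right, lateral = left)
}

#' Cartilage-bone interface depth map and anchor for a compartment
#'
#' The interface is proxied by the topmost bone voxel per (ML, AP) column;
#' the anchor is the interface height at the compartment's middle column.
#'
#' @param mask logical 3-D mask.
#' @param compartment one element of [split_compartments()] output.
#' @return list with `depth` (matrix of top-voxel heights, `NA` for empty
#'   columns) and `anchor` (`c(x, z, y)`).
#' @export
find_interface_depth <- function(mask, compartment) {
  xs <- compartment$x_range[1]:compartment$x_range[2]
  ys <- compartment$y_range[1]:compartment$y_range[2]
  depth <- matrix(NA_real_, length(xs), length(ys),
                  dimnames = list(xs, ys))
  for (a in seq_along(xs)) for (b in seq_along(ys)) {
    col <- mask[xs[a], , ys[b]]
    if (any(col)) depth[a, b] <- max(which(col))
  }
  if (all(is.na(depth))) stop("compartment contains no bone columns")
  mid_x <- xs[ceiling(length(xs) / 2)]
  mid_y <- ys[ceiling(length(ys) / 2)]
  # nearest non-empty column to the geometric middle
  if (is.na(depth[as.character(mid_x), as.character(mid_y)])) {
    idx <- which(!is.na(depth), arr.ind = TRUE)
    dist <- (xs[idx[, 1]] - mid_x)^2 + (ys[idx[, 2]] - mid_y)^2
    pick <- idx[which.min(dist), ]
    mid_x <- xs[pick[1]]; mid_y <- ys[pick[2]]
  }
  anchor_z <- depth[as.character(mid_x), as.character(mid_y)]
  list(depth = depth, anchor = c(x = mid_x, z = unname(anchor_z), y = mid_y))
}

#' Extract the six tibial VOIs
#'
#' Per compartment, three stacked boxes below the cartilage-bone interface
#' anchor: subchondral (interface down 10 mm), mid (next 10 mm), trabecular
#' (next 10 mm). Horizontal extent is the central fraction (default 0.8) of
#' the compartment span in both horizontal axes, clipped to the mask
#' bounding box. Box names: SBM, MidM, TBM (medial), SBL, MidL, TBL
#' (lateral).
#'
#' @param mask logical 3-D mask with spacing attribute.
#' @param spacing_mm voxel spacing (defaults to the mask's spacing).
#' @param central_fraction horizontal central fraction of the compartment span.
#' @param min_separation spine separation passed to [detect_tibial_spines()].
#' @param right_knee laterality flag.
#' @return a `tibrad_voiset`: named list of boxes, each with `x`, `z`, `y`
#'   inclusive index ranges, plus `spacing_mm`.
#' @export
extract_vois <- function(mask, spacing_mm = voxel_spacing(mask),
                         central_fraction = 0.8, min_separation = 8,
                         right_knee = TRUE) {
  spines <- detect_tibial_spines(mask, min_separation)
  comps <- split_compartments(mask, spines, right_knee)
  bbox <- mask_bbox(mask)
  h <- round_half_away(10 / spacing_mm[2])   # 10 mm tier height in voxels
  boxes <- list()
  for (side in c("medial", "lateral")) {
    comp <- comps[[side]]
    iface <- find_interface_depth(mask, comp)
    z_a <- iface$anchor[["z"]]
    if (z_a - 3 * h + 1 < bbox$z[1]) {
      stop(sprintf("insufficient bone depth (< 30 mm) in the %s compartment",
                   side))
    }
    shrink <- function(r) {
      span <- r[2] - r[1] + 1
      trim <- floor(span * (1 - central_fraction) / 2)
      c(r[1] + trim, r[2] - trim)
    }
    xr <- shrink(comp$x_range)
    yr <- shrink(comp$y_range)
    xr <- c(max(xr[1], bbox$x[1]), min(xr[2], bbox$x[2]))
    yr <- c(max(yr[1], bbox$y[1]), min(yr[2], bbox$y[2]))
    tag <- if (side == "medial") c("SBM", "MidM", "TBM")
           else c("SBL", "MidL", "TBL")
    zs <- list(c(z_a - h + 1, z_a),
               c(z_a - 2 * h + 1, z_a - h),
               c(z_a - 3 * h + 1, z_a - 2 * h))
    for (k in 1:3) {
      boxes[[tag[k]]] <- list(x = as.integer(xr), z = as.integer(zs[[k]]),
                              y = as.integer(yr))
    }
  }
  structure(list(boxes = boxes[c("SBM", "MidM", "TBM", "SBL", "MidL", "TBL")],
                 spacing_mm = as.numeric(spacing_mm)),
            class = "tibrad_voiset")
}

#' Serialize / read a VOI set as JSON
#' @param vois a `tibrad_voiset`.
#' @param path file path.
#' @return `write_voiset()` returns `path` invisibly; `read_voiset()` the set.
#' @export
write_voiset <- function(vois, path) {
  jsonlite::write_json(list(boxes = vois$boxes, spacing_mm = vois$spacing_mm),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_voiset
#' @export
read_voiset <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  boxes <- lapply(raw$boxes, function(b)
    list(x = as.integer(b$x), z = as.integer(b$z), y = as.integer(b$y)))
  structure(list(boxes = boxes, spacing_mm = as.numeric(raw$spacing_mm)),
            class = "tibrad_voiset")
}

#' VOI label map for visualization
#' @param vois a `tibrad_voiset`.
#' @param dims grid dimensions.
#' @return integer array with values 1-6 inside the boxes (order SBM, MidM,
#'   TBM, SBL, MidL, TBL), 0 elsewhere.
#' @export
voi_label_map <- function(vois, dims) {
  out <- array(0L, dims)
  for (k in seq_along(vois$boxes)) {
    b <- vois$boxes[[k]]
    out[b$x[1]:b$x[2], b$z[1]:b$z[2], b$y[1]:b$y[2]] <- k
  }
  out
}
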