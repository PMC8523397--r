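#' Radiomic feature extraction configuration
#'
#' Single source of truth for the per-VOI feature families and their
#' parameter grids. With the defaults the engine emits exactly 3 orientation,
#' 12 histogram and 271 texture features per VOI (GLCM 10 descriptors x
#' mean/SD over the 13 unique 3-D directions = 20; GLRLM 16 x mean/SD = 32;
#' GLSZM 16; NGTDM 5; LBP 3 radii x 10 riu2 bins = 30; Gabor 7 frequencies x
#' 12 angles x mean/SD = 168), plus 17 whole-bone shape features.
#'
#' @param n_levels grey levels for the matrix-based families.
#' @param lbp_radii LBP radii in pixels.
#' @param gabor_frequencies Gabor spatial frequencies (cycles/pixel).
#' @param gabor_angles Gabor orientations (radians).
#' @param scales_mm scale-space scales (segmentation appearance model).
#' @return a named configuration list.
#' @export
feature_config <- function(n_levels = 16,
                           lbp_radii = c(1, 2, 3),
                           gabor_frequencies = c(0.05, 0.08, 0.12, 0.18,
                                                 0.25, 0.33, 0.42),
                           gabor_angles = seq(0, pi - pi / 12, by = pi / 12),
                           scales_mm = c(0.5, 1, 2)) {
  list(n_levels = n_levels, lbp_radii = lbp_radii,
       gabor_frequencies = gabor_frequencies, gabor_angles = gabor_angles,
       scales_mm = scales_mm)
}

# texture features of one VOI (mask-aware), named family_statistic_parameter
extract_texture_features <- function(volume, mask, config = feature_config()) {
  q <- quantize(volume, mask, config$n_levels)
  nvox <- sum(mask)
  dirs <- glcm_directions()
  gl <- matrix(NA_real_, nrow(dirs), 10)
  rl <- matrix(NA_real_, nrow(dirs), 16)
  for (k in seq_len(nrow(dirs))) {
    gl[k, ] <- glcm_features(glcm(q, dirs[k, ]))
    rl[k, ] <- glrlm_features(glrlm(q, dirs[k, ]), nvox)
  }
  colnames(gl) <- names(glcm_features(glcm(q, c(1, 0, 0))))
  colnames(rl) <- names(glrlm_features(glrlm(q, c(1, 0, 0)), nvox))
  glcm_agg <- c(setNames(colMeans(gl), paste0("glcm_", colnames(gl), "_mean")),
                setNames(apply(gl, 2, sd), paste0("glcm_", colnames(gl), "_sd")))
  glrlm_agg <- c(setNames(colMeans(rl), paste0("glrlm_", colnames(rl), "_mean")),
                 setNames(apply(rl, 2, sd), paste0("glrlm_", colnames(rl), "_sd")))
  szmv <- glszm_features(glszm(q), nvox, q$G)
  szm <- setNames(szmv, paste0("glszm_", names(szmv)))
  ngv <- ngtdm_features(ngtdm(q))
  ng <- setNames(ngv, paste0("ngtdm_", names(ngv)))
  lbp <- lbp_features(volume, mask, config$lbp_radii)
  gab <- gabor_features(volume, mask, config$gabor_frequencies,
                        config$gabor_angles)
  c(glcm_agg, glrlm_agg, szm, ng, lbp, gab)
}

crop_box <- function(arr, box) {
  arr[box$x[1]:box$x[2], box$z[1]:box$z[2], box$y[1]:box$y[2], drop = FALSE]
}

#' Extract all radiomic features for one knee
#'
#' Per VOI: 3 orientation + 12 histogram + 271 texture features computed on
#' the VOI's box intersected with the tibia mask. Whole-bone: 17 shape
#' features. Output is a tidy tibble (one row per feature) with stable
#' ordering; any non-finite feature is an error naming the feature and VOI.
#'
#' @param volume image volume.
#' @param mask tibia mask on the same grid.
#' @param vois a `tibrad_voiset` from [extract_vois()].
#' @param config a [feature_config()] list.
#' @param subject_id optional id attached to every row.
#' @return tibble with columns `subject_id` (if given), `voi`, `family`,
#'   `name`, `value`.
#' @export
extract_all <- function(volume, mask, vois, config = feature_config(),
                        subject_id = NULL) {
  stopifnot(inherits(vois, "tibrad_voiset"))
  sp <- vois$spacing_mm
  rows <- list()
  add <- function(voi, family, vals) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      voi = voi, family = family, name = names(vals),
      value = unname(vals))
  }
  for (vn in names(vois$boxes)) {
    b <- vois$boxes[[vn]]
    v <- crop_box(volume, b)
    m <- crop_box(array(as.logical(mask), dim(mask)), b)
    if (sum(m) < 32) {
      stop(sprintf("VOI %s contains too little bone (%d voxels)", vn, sum(m)))
    }
    ornt <- orientation_features(m, sp)
    hst <- histogram_features(v, m)
    txt <- extract_texture_features(v, m, config)
    add(vn, "orientation", ornt)
    add(vn, "histogram", hst)
    add(vn, "texture", txt)
  }
  shp <- shape_features(array(as.logical(mask), dim(mask)), sp)
  add("whole", "shape", shp)
  out <- dplyr::bind_rows(rows)
  bad <- which(!is.finite(out$value))
  if (length(bad) > 0) {
    stop(sprintf("non-finite feature '%s' in VOI %s",
                 out$name[bad[1]], out$voi[bad[1]]))
  }
  if (!is.null(subject_id)) {
    out <- dplyr::bind_cols(tibble::tibble(subject_id = subject_id), out)
  }
  out
}

#' Run the full per-knee feature pipeline on a phantom
#'
#' Convenience wrapper: VOI extraction on the mask followed by
#' [extract_all()].
#'
#' @inheritParams extract_all
#' @param ... passed to [extract_vois()].
#' @return tidy feature tibble.
#' @export
extract_knee_features <- function(volume, mask, config = feature_config(),
                                  subject_id = NULL, ...) {
  vois <- extract_vois(mask, ...)
  extract_all(volume, mask, vois, config, subject_id)
}

#' Pivot a tidy feature table to a wide per-knee matrix
#'
#' Column names are `<voi>.<feature>`; rows are knees.
#'
#' @param features tidy feature tibble with a `subject_id` column.
#' @return wide tibble, one row per subject.
#' @export
features_to_wide <- function(features) {
  stopifnot("subject_id" %in% names(features))
  features |>
    dplyr::mutate(col = paste(.data$voi, .data$name, sep = ".")) |>
    dplyr::select("subject_id", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")
}
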