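#' Multi-atlas label propagation and averaging
#'
#' Warps each atlas mask with its transform (nearest-neighbour label
#' interpolation) and averages the warped labels voxel-wise into a tibia
#' probability map on the target grid.
#'
#' @param atlas_masks list of logical/numeric 3-D arrays.
#' @param transforms list of `tibrad_transform`, one per mask.
#' @param target_grid integer length-3; must equal each transform's target grid.
#' @return numeric array in \[0, 1\].
#' @export
propagate_and_average <- function(atlas_masks, transforms, target_grid) {
  stopifnot(length(atlas_masks) == length(transforms), length(atlas_masks) >= 1)
  for (tf in transforms) {
    if (!identical(as.integer(tf$target_dim), as.integer(target_grid))) {
      stop("transform target grid does not match target_grid")
    }
  }
  acc <- array(0, target_grid)
  for (i in seq_along(atlas_masks)) {
    w <- apply_transform(array(as.numeric(atlas_masks[[i]]), dim(atlas_masks[[i]])),
                         transforms[[i]], interpolation = "nearest",
                         background = 0)
    acc <- acc + w
  }
  acc / length(atlas_masks)
}

#' Train the voxel-wise appearance classifier
#'
#' A random forest (via \pkg{ranger}) on the 49-channel Gaussian scale-space
#' stack, trained on a balanced subsample of tibia and background voxels
#' from each atlas.
#'
#' @param atlases list of `list(volume=, mask=)` pairs (e.g. phantoms).
#' @param scales_mm the three Gaussian scales.
#' @param n_per_class voxels sampled per class per atlas.
#' @param num_trees forest size.
#' @param seed integer seed (training is fully reproducible).
#' @return a `tibrad_voxel_classifier`.
#' @export
train_appearance_classifier <- function(atlases, scales_mm = c(0.5, 1, 2),
                                        n_per_class = 2000, num_trees = 100,
                                        seed = 1L) {
  stopifnot(length(atlases) >= 1)
  rows <- list()
  ys <- list()
  with_local_seed(seed, {
    for (i in seq_along(atlases)) {
      vol <- atlases[[i]]$volume
      msk <- as.logical(atlases[[i]]$mask)
      stack <- compute_scale_space_features(vol, scales_mm)
      fg <- which(msk)
      bg <- which(!msk)
      if (length(fg) == 0 || length(bg) == 0) {
        stop("atlas ", i, " has a single class of training voxels")
      }
      sf <- sample(fg, min(n_per_class, length(fg)))
      sb <- sample(bg, min(n_per_class, length(bg)))
      rows[[i]] <- stack[c(sf, sb), , drop = FALSE]
      ys[[i]] <- rep(c(1L, 0L), c(length(sf), length(sb)))
    }
    NULL
  })
  X <- do.call(rbind, rows)
  y <- factor(unlist(ys), levels = c(0L, 1L))
  df <- as.data.frame(X)
  df$.tibia <- y
  model <- ranger::ranger(dependent.variable.name = ".tibia", data = df,
                          probability = TRUE, num.trees = num_trees,
                          seed = seed, num.threads = 1)
  structure(list(model = model, scales_mm = scales_mm),
            class = "tibrad_voxel_classifier")
}

#' Per-voxel tibia probability from the appearance classifier
#'
#' @param classifier a `tibrad_voxel_classifier`.
#' @param image target image volume.
#' @param downsample integer resolution divisor for prediction; probabilities
#'   are computed on the reduced grid and trilinearly upsampled (1 = full
#'   resolution).
#' @return numeric array of tibia probabilities in \[0, 1\].
#' @export
predict_voxel_probabilities <- function(classifier, image, downsample = 1) {
  stopifnot(inherits(classifier, "tibrad_voxel_classifier"), downsample >= 1)
  d <- dim(image)
  work <- if (downsample > 1) {
    image_volume(downsample_volume(image, downsample),
                 voxel_spacing(image) * downsample)
  } else image
  stack <- compute_scale_space_features(work, classifier$scales_mm)
  pr <- predict(classifier$model, data = as.data.frame(stack),
                num.threads = 1)$predictions
  p <- array(pr[, "1"], dim(work))
  if (downsample == 1) return(p)
  g <- coord_grids(d)
  f <- downsample
  co <- lapply(list(g$x, g$z, g$y), function(v) (v + (f - 1) / 2) / f)
  dp <- dim(p)
  out <- sample_trilinear_cpp(as.numeric(p), dp,
                              pmin(pmax(co[[1]], 1), dp[1]),
                              pmin(pmax(co[[2]], 1), dp[2]),
                              pmin(pmax(co[[3]], 1), dp[3]), 0)
  array(out, d)
}

#' Fuse atlas and appearance probabilities into a segmentation
#'
#' Weighted arithmetic mean of the two probability maps thresholded at `t`,
#' keeping the largest 6-connected component.
#'
#' @param p_atlas,p_appearance probability arrays on the same grid.
#' @param w weight of the multi-atlas map in \[0, 1\].
#' @param t threshold in (0, 1).
#' @return logical mask array.
#' @export
fuse_and_threshold <- function(p_atlas, p_appearance, w = 0.5, t = 0.5) {
  if (!identical(dim(p_atlas), dim(p_appearance))) stop("grid mismatch")
  stopifnot(w >= 0, w <= 1, t > 0, t < 1)
  fused <- w * p_atlas + (1 - w) * p_appearance
  mask <- array(fused >= t, dim(p_atlas))
  largest_component(mask, 6)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; symmetric, in \[0, 1\]. Both masks empty is an
#' error (the ratio is undefined).
#'
#' @param a,b logical arrays on the same grid.
#' @return scalar Dice coefficient.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) stop("Dice undefined: both masks are empty")
  2 * sum(a & b) / (sa + sb)
}

#' Segment a tibia with the combined multi-atlas + appearance model
#'
#' Registers every atlas to the target (affine followed by non-rigid),
#' propagates and averages the atlas masks, predicts voxel-wise appearance
#' probabilities, and fuses the two maps. A QC flag marks cases whose fused
#' mask disagrees with the atlas consensus (Dice below `qc_dice`), the
#' package's stand-in for visual inspection.
#'
#' @param target target image volume.
#' @param atlases list of `list(volume=, mask=)` atlas pairs.
#' @param classifier optional pre-trained `tibrad_voxel_classifier`
#'   (trained on `atlases` if omitted).
#' @param config [registration_config()] list.
#' @param w,t fusion weight and threshold.
#' @param qc_dice QC threshold on Dice versus the thresholded atlas consensus.
#' @param seed seed for classifier training when `classifier` is `NULL`.
#' @param appearance_downsample resolution divisor for the appearance
#'   prediction (see [predict_voxel_probabilities()]).
#' @return list with `mask`, `p_atlas`, `p_appearance`, `transforms`,
#'   `qc_flag`.
#' @export
segment_tibia <- function(target, atlases, classifier = NULL,
                          config = registration_config(), w = 0.5, t = 0.5,
                          qc_dice = 0.8, seed = 1L,
                          appearance_downsample = 1) {
  transforms <- lapply(atlases, function(a)
    register_atlas(a$volume, target, config))
  p_atlas <- propagate_and_average(lapply(atlases, `[[`, "mask"),
                                   transforms, dim(target))
  if (is.null(classifier)) {
    classifier <- train_appearance_classifier(atlases, seed = seed)
  }
  p_app <- predict_voxel_probabilities(classifier, target,
                                       appearance_downsample)
  mask <- fuse_and_threshold(p_atlas, p_app, w, t)
  consensus <- array(p_atlas >= 0.5, dim(target))
  qc <- if (sum(consensus) + sum(mask) == 0) TRUE
        else dice(mask, consensus) < qc_dice
  list(mask = image_volume(mask, voxel_spacing(target)),
       p_atlas = p_atlas, p_appearance = p_app,
       transforms = transforms, qc_flag = qc)
}
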