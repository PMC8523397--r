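#' Image volumes and binary masks
#'
#' A `tibrad` image volume is a numeric 3-D array with a `"spacing"` attribute
#' giving the per-axis voxel size in millimetres, in the package's axis
#' convention (medial-lateral, inferior-superior, anterior-posterior). Binary
#' masks use the same representation with logical storage.
#'
#' @param data numeric or logical 3-D array.
#' @param spacing_mm numeric length-3, voxel size in mm per axis.
#' @return The array with its `spacing` attribute set.
#' @export
image_volume <- function(data, spacing_mm) {
  stopifnot(length(dim(data)) == 3, length(spacing_mm) == 3,
            all(is.finite(spacing_mm)), all(spacing_mm > 0))
  attr(data, "spacing") <- as.numeric(spacing_mm)
  data
}

#' Voxel spacing of a volume
#' @param vol a volume or mask created by [image_volume()] or read from NIfTI.
#' @return numeric length-3 spacing in mm (defaults to 1 mm isotropic if unset).
#' @export
voxel_spacing <- function(vol) {
  sp <- attr(vol, "spacing")
  if (is.null(sp)) rep(1, 3) else sp
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti} that keep the spacing attribute in sync
#' with the NIfTI header.
#'
#' @param vol volume or mask to write.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a numeric array with a `spacing` attribute.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- voxel_spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  image_volume(array(as.numeric(img), dim(img)[seq_len(3)]), sp)
}

#' Keep the largest connected component of a binary mask
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 or 26.
#' @return logical array of the same shape; all-`FALSE` input returned as is.
#' @export
largest_component <- function(mask, connectivity = 6) {
  stopifnot(connectivity %in% c(6, 26))
  if (!any(mask)) return(mask)
  lab <- label_components_cpp(as.logical(mask), dim(mask), as.integer(connectivity))
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  out <- array(lab == keep, dim(mask))
  attr(out, "spacing") <- attr(mask, "spacing")
  out
}

#' Count connected components of a binary mask
#' @inheritParams largest_component
#' @return integer component count.
#' @export
count_components <- function(mask, connectivity = 6) {
  if (!any(mask)) return(0L)
  lab <- label_components_cpp(as.logical(mask), dim(mask), as.integer(connectivity))
  max(lab)
}

# bounding box of a mask: list of per-axis index ranges
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  list(x = range(idx[, 1]), z = range(idx[, 2]), y = range(idx[, 3]))
}

# round half away from zero (mm -> voxel conversions)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
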