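#' Parameters for the synthetic knee phantom
#'
#' The phantom emulates the proximal tibia on a FIESTA-like isotropic grid: a
#' vertical shaft with an elliptical cross-section flaring into a plateau
#' whose top surface carries two spines (bumps) of distinct heights. Inside
#' the bone the intensity is a base level plus a correlated Gaussian texture
#' field plus i.i.d. noise. Disease (OA) is encoded in two directions known
#' from the osteoarthritis imaging literature: a longer texture correlation
#' length (more homogeneous trabecular texture) and a sinusoidal radial
#' perturbation of the plateau outline (lower slice-wise compactness).
#'
#' @param grid_shape voxels per axis (medial-lateral, vertical, antero-posterior).
#' @param spacing_mm voxel size in mm per axis.
#' @param shaft_radius_mm medial-lateral semi-axis of the shaft.
#' @param plateau_width_mm full medial-lateral width of the plateau.
#' @param spine_height_mm heights of the two tibial spines (mm); must differ.
#' @param texture_corr_len_mm named correlation lengths `c(control=, oa=)`;
#'   the OA value must exceed the control value (more homogeneous OA texture).
#' @param texture_sd named texture standard deviations `c(control=, oa=)`.
#' @param surface_irregularity_amp named relative amplitudes `c(control=, oa=)`
#'   of the sinusoidal plateau-outline perturbation.
#' @param noise_sd i.i.d. voxel noise standard deviation.
#' @param seed integer seed for the phantom's random fields.
#' @return a `tibrad_phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(96, 96, 64),
                           spacing_mm = c(0.5, 0.5, 0.5),
                           shaft_radius_mm = 12,
                           plateau_width_mm = 34,
                           spine_height_mm = c(4, 3),
                           texture_corr_len_mm = c(control = 0.8, oa = 2.0),
                           texture_sd = c(control = 20, oa = 20),
                           surface_irregularity_amp = c(control = 0.02, oa = 0.12),
                           noise_sd = 2,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 16),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            shaft_radius_mm > 0, plateau_width_mm > 0,
            length(spine_height_mm) == 2, all(spine_height_mm > 0),
            spine_height_mm[1] != spine_height_mm[2],
            all(texture_corr_len_mm > 0), all(texture_sd >= 0),
            all(surface_irregularity_amp >= 0), noise_sd >= 0)
  texture_corr_len_mm <- resolve_class_pair(texture_corr_len_mm)
  texture_sd <- resolve_class_pair(texture_sd)
  surface_irregularity_amp <- resolve_class_pair(surface_irregularity_amp)
  if (texture_corr_len_mm["oa"] <= texture_corr_len_mm["control"]) {
    stop("texture_corr_len_mm['oa'] must exceed the control value ",
         "(OA texture is more homogeneous)")
  }
  p <- list(grid_shape = as.integer(grid_shape),
            spacing_mm = as.numeric(spacing_mm),
            shaft_radius_mm = shaft_radius_mm,
            plateau_width_mm = plateau_width_mm,
            spine_height_mm = as.numeric(spine_height_mm),
            texture_corr_len_mm = texture_corr_len_mm,
            texture_sd = texture_sd,
            surface_irregularity_amp = surface_irregularity_amp,
            noise_sd = noise_sd, seed = as.integer(seed))
  class(p) <- "tibrad_phantom_params"
  # geometry must hold the plateau plus three stacked 10-mm VOI tiers
  geo <- phantom_geometry(p)
  tier <- round_half_away(10 / spacing_mm[2])
  # 2 = maximum downward interface jitter of the generator
  if (geo$z_top - 2 - 3 * tier < 1) {
    stop(sprintf(
      "grid too small: interface at voxel %d cannot hold 30 mm (%d voxels) of bone depth",
      geo$z_top, 3 * tier))
  }
  p
}

resolve_class_pair <- function(x) {
  if (length(x) == 1) x <- c(control = unname(x), oa = unname(x))
  if (is.null(names(x)) && length(x) == 2) names(x) <- c("control", "oa")
  stopifnot(all(c("control", "oa") %in% names(x)))
  x[c("control", "oa")]
}

# Derived voxel-space geometry shared by the generator and tests.
phantom_geometry <- function(params) {
  d <- params$grid_shape
  sp <- params$spacing_mm
  spine_vox <- ceiling(max(params$spine_height_mm) / sp[2])
  z_top <- d[2] - spine_vox - 4L        # plateau (cartilage-bone) interface
  a_shaft <- params$shaft_radius_mm / sp[1]
  a_plateau <- params$plateau_width_mm / 2 / sp[1]
  list(x0 = (d[1] + 1) / 2, y0 = (d[3] + 1) / 2,
       z_top = as.integer(z_top),
       flare = 12L,
       a_shaft = a_shaft, b_shaft = 0.75 * a_shaft * sp[1] / sp[3],
       a_plateau = a_plateau, b_plateau = 0.7 * a_plateau * sp[1] / sp[3],
       spine_offset_vox = round_half_away(0.30 * d[1] / 2),
       spine_sigma_vox = 4,
       spine_height_vox = params$spine_height_mm / sp[2])
}

# Evaluate the local RNG under a fixed seed without disturbing the caller's
# random stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic tibia phantom
#'
#' @param params a [phantom_params()] object.
#' @param oa_class logical; `TRUE` draws the OA texture/shape condition.
#' @return list with elements `volume` (numeric array) and `mask` (logical
#'   array), both carrying the voxel spacing; the ground-truth spine columns
#'   are attached to the mask as attribute `spine_cols`.
#' @export
generate_tibia_phantom <- function(params, oa_class = FALSE) {
  stopifnot(inherits(params, "tibrad_phantom_params"), is.logical(oa_class))
  cls <- if (oa_class) "oa" else "control"
  d <- params$grid_shape
  sp <- params$spacing_mm
  geo <- phantom_geometry(params)
  amp <- unname(params$surface_irregularity_amp[cls])

  # seeded anatomical variability (drawn first so the draw order is
  # identical for both classes at equal seeds)
  jit <- with_local_seed(params$seed, {
    list(cx0 = runif(1, -3, 3), cy0 = runif(1, -3, 3),
         scale = runif(1, 0.92, 1.08),
         z_off = sample(0:2, 1),
         spine_jit = round(runif(2, -2, 2)))
  })
  geo$x0 <- geo$x0 + jit$cx0
  geo$y0 <- geo$y0 + jit$cy0
  geo$a_shaft <- geo$a_shaft * jit$scale
  geo$b_shaft <- geo$b_shaft * jit$scale
  geo$a_plateau <- geo$a_plateau * jit$scale
  geo$b_plateau <- geo$b_plateau * jit$scale
  geo$z_top <- geo$z_top - jit$z_off

  x <- seq_len(d[1]); z <- seq_len(d[2]); y <- seq_len(d[3])
  dx <- outer(x - geo$x0, rep(1, d[3]))            # d1 x d3
  dy <- outer(rep(1, d[1]), y - geo$y0)
  theta <- atan2(dy, dx)
  pert <- 1 + amp * sin(6 * theta)                 # plateau outline irregularity

  # top surface: interface height plus two Gaussian spine bumps
  cx <- geo$x0 + c(-1, 1) * geo$spine_offset_vox + jit$spine_jit
  h <- geo$spine_height_vox
  bump <- h[1] * exp(-(((dx + geo$x0 - cx[1])^2) + dy^2) / (2 * geo$spine_sigma_vox^2)) +
    h[2] * exp(-(((dx + geo$x0 - cx[2])^2) + dy^2) / (2 * geo$spine_sigma_vox^2))
  z_surf <- geo$z_top + bump                       # d1 x d3

  # per-height semi-axes: shaft below, smooth flare into the plateau
  t <- (z - (geo$z_top - geo$flare)) / geo$flare
  t <- pmin(pmax(t, 0), 1)
  t <- t * t * (3 - 2 * t)                         # smoothstep
  a_z <- geo$a_shaft + t * (geo$a_plateau - geo$a_shaft)
  b_z <- geo$b_shaft + t * (geo$b_plateau - geo$b_shaft)
  # vertical radius ripple: the irregularity also waves the silhouette seen
  # in sagittal slices (period 3 mm), lowering slice-wise compactness
  rip <- 1 + amp * sin(2 * pi * z * sp[2] / 3)
  mask <- array(FALSE, d)
  for (k in seq_len(d[2])) {
    # outline perturbation only where the flare/plateau is active
    pk <- 1 + t[k] * (pert - 1)
    inside <- (dx / (a_z[k] * rip[k] * pk))^2 +
      (dy / (b_z[k] * rip[k] * pk))^2 <= 1
    mask[, k, ] <- inside & (k <= z_surf)
  }
  mask <- largest_component(mask, 6)

  vol <- with_local_seed(params$seed + 1L, {
    noise <- array(rnorm(prod(d)), d)
    corr <- unname(params$texture_corr_len_mm[cls]) / sp
    field <- gaussian_smooth(noise, corr)
    fsd <- sd(field)
    if (fsd > 0 && params$texture_sd[cls] > 0) {
      field <- field * (params$texture_sd[cls] / fsd)
    } else {
      field <- array(0, d)
    }
    iid <- if (params$noise_sd > 0) array(rnorm(prod(d), 0, params$noise_sd), d)
           else array(0, d)
    v <- array(10, d)            # background
    v[mask] <- 100 + field[mask] # base bone intensity + texture
    v + iid
  })

  vol <- image_volume(vol, sp)
  mask <- image_volume(mask, sp)
  attr(mask, "spine_cols") <- sort(round(cx))
  attr(mask, "geometry") <- geo
  list(volume = vol, mask = mask)
}
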