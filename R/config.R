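#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline with their defaults;
#' study-derived values (10 folds, 100 repetitions, the alpha/lambda grid
#' bounds, 10-mm VOI tiers via the extraction code) are set exactly as
#' reported.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "tibrad_run",
    stages = list(simulate = TRUE, segment = TRUE, voi = TRUE,
                  features = TRUE, train = TRUE, evaluate = TRUE),
    cohort = list(n = 60, prevalence = 76 / 665,
                  covariate_label_assoc = FALSE),
    phantom = list(grid_shape = c(96, 96, 64),
                   spacing_mm = c(0.5, 0.5, 0.5),
                   shaft_radius_mm = 12, plateau_width_mm = 34,
                   spine_height_mm = c(4, 3),
                   texture_corr_len_mm = c(control = 0.8, oa = 2.0),
                   texture_sd = c(control = 20, oa = 20),
                   surface_irregularity_amp = c(control = 0.02, oa = 0.12),
                   noise_sd = 2),
    segmentation = list(n_atlases = 5, w = 0.5, t = 0.5, qc_dice = 0.8,
                        n_per_class = 2000, num_trees = 100,
                        appearance_downsample = 2,
                        registration = list(nonrigid = TRUE,
                                            affine_dof = "affine",
                                            mi_bins = 32, coarse_range = 4,
                                            ctrl_spacing = 12, patch = 5,
                                            search = 3, maxit = 100)),
    voi = list(central_fraction = 0.8, min_separation = 8, right_knee = TRUE,
               mask_source = "segmentation"),
    features = list(n_levels = 16, lbp_radii = c(1, 2, 3),
                    gabor_frequencies = c(0.05, 0.08, 0.12, 0.18, 0.25,
                                          0.33, 0.42),
                    gabor_angles = seq(0, pi - pi / 12, by = pi / 12)),
    model = list(mode = "combined", voi_selection = "All",
                 label = "label_tfoa",
                 alpha = list(start = 0.1, end = 1, by = 0.05),
                 lambda = list(start = 0.001, end = 0.15, by = 0.009)),
    cv = list(folds = 10L, repetitions = 100L, stratified = TRUE,
              pooling = "averaged"),
    evaluate = list(bootstrap_B = 2000L, level = 0.95)
  )
}

# recursive merge of user values into defaults; unknown keys are collected
merge_config <- function(defaults, user, path = "") {
  bad <- character(0)
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      bad <- c(bad, full)
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        defaults[[key]] <- user[[key]]
      } else {
        sub <- merge_config(defaults[[key]], user[[key]], full)
        defaults[[key]] <- sub$config
        bad <- c(bad, sub$bad)
      }
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  list(config = defaults, bad = bad)
}

#' Validate a raw pipeline configuration
#'
#' Fills defaults, rejects unknown keys (all offending keys are listed in
#' the error), and checks value-level invariants before any stage runs.
#'
#' @param raw named list (e.g. parsed from YAML/JSON), possibly partial or
#'   `NULL` for all defaults.
#' @return a validated `tibrad_config` list.
#' @export
validate_config <- function(raw = NULL) {
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a named list")
  merged <- merge_config(default_config(), raw)
  if (length(merged$bad) > 0) {
    stop("unknown configuration key(s): ", paste(merged$bad, collapse = ", "))
  }
  cfg <- merged$config
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$cv$folds >= 2, "cv.folds must be >= 2")
  chk(cfg$cv$repetitions >= 1, "cv.repetitions must be >= 1")
  chk(cfg$cohort$n >= 10, "cohort.n must be >= 10")
  chk(cfg$cohort$prevalence > 0 && cfg$cohort$prevalence < 1,
      "cohort.prevalence must be in (0,1)")
  chk(cfg$segmentation$n_atlases >= 1, "segmentation.n_atlases must be >= 1")
  chk(cfg$segmentation$w >= 0 && cfg$segmentation$w <= 1,
      "segmentation.w must be in [0,1]")
  chk(cfg$segmentation$t > 0 && cfg$segmentation$t < 1,
      "segmentation.t must be in (0,1)")
  chk(cfg$voi$central_fraction > 0 && cfg$voi$central_fraction <= 1,
      "voi.central_fraction must be in (0,1]")
  chk(cfg$model$mode %in% c("covariates", "image", "combined"),
      "model.mode invalid")
  chk(all(cfg$features$gabor_frequencies < 0.5),
      "features.gabor_frequencies must be below Nyquist (0.5)")
  chk(cfg$model$alpha$start <= cfg$model$alpha$end && cfg$model$alpha$by > 0,
      "model.alpha grid invalid")
  chk(cfg$model$lambda$start <= cfg$model$lambda$end &&
        cfg$model$lambda$by > 0, "model.lambda grid invalid")
  if (length(errs) > 0) stop("invalid configuration: ",
                             paste(errs, collapse = "; "))
  class(cfg) <- c("tibrad_config", "list")
  cfg
}

#' Read a configuration file (YAML or JSON)
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return validated `tibrad_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    # keep bare "y"/"n" as strings so YAML 1.1 does not turn the key of
    # cohort.n into a boolean; true/false/yes/no still parse as logicals
    yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(v) if (tolower(v) == "y") v else TRUE,
      "bool#no" = function(v) if (tolower(v) == "n") v else FALSE))
  }
  validate_config(raw)
}
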