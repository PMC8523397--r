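#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order (simulate, segment, voi, features,
#' train, evaluate); every stage reads only the on-disk outputs of earlier
#' stages, so partial reruns are possible. A JSON run manifest records the
#' package version, configuration, per-stage seeds, output checksums and
#' timings. A disabled stage whose outputs a later stage needs produces an
#' error naming the gap.
#'
#' @param config a [validate_config()] result (or raw list, validated here).
#' @return the run manifest (list), invisibly; written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- if (inherits(config, "tibrad_config")) config
         else validate_config(config)
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("tibrad")),
                   seed = cfg$seed, config = cfg, stages = list())
  t_all <- Sys.time()

  run_stage <- function(name, fn) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    t0 <- Sys.time()
    files <- fn()
    manifest$stages[[name]] <<- list(
      completed = TRUE,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = as.list(tools::md5sum(files)))
    invisible(NULL)
  }
  need <- function(path, producer) {
    if (!file.exists(path)) {
      stop(sprintf("missing input '%s': enable or run the '%s' stage first",
                   path, producer))
    }
    path
  }
  params <- do.call(phantom_params, c(cfg$phantom, list(seed = cfg$seed)))
  fcfg <- do.call(feature_config, cfg$features)

  run_stage("simulate", function() {
    d <- file.path(out, "simulate")
    dir.create(file.path(d, "volumes"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(d, "atlases"), recursive = TRUE, showWarnings = FALSE)
    cohort <- generate_cohort(cfg$cohort$n, cfg$cohort$prevalence, params,
                              seed = cfg$seed,
                              covariate_label_assoc =
                                cfg$cohort$covariate_label_assoc)
    moaks <- generate_moaks_record(cohort, seed = cfg$seed + 1L)
    write.csv(cohort, file.path(d, "cohort.csv"), row.names = FALSE)
    write.csv(moaks, file.path(d, "moaks.csv"), row.names = FALSE)
    files <- c(file.path(d, "cohort.csv"), file.path(d, "moaks.csv"))
    for (i in seq_len(nrow(cohort))) {
      pi <- params; pi$seed <- cohort$phantom_seed[i]
      ph <- generate_tibia_phantom(pi, oa_class = cohort$label_tfoa[i])
      fv <- file.path(d, "volumes", paste0(cohort$subject_id[i], "_vol.nii.gz"))
      fm <- file.path(d, "volumes", paste0(cohort$subject_id[i], "_mask.nii.gz"))
      write_volume(ph$volume, fv)
      write_volume(ph$mask, fm)
      files <- c(files, fv, fm)
    }
    # atlas phantoms (controls, outside the cohort)
    for (a in seq_len(cfg$segmentation$n_atlases)) {
      pa <- params; pa$seed <- cfg$seed + 7000L + a
      ph <- generate_tibia_phantom(pa, oa_class = FALSE)
      fv <- file.path(d, "atlases", sprintf("atlas%02d_vol.nii.gz", a))
      fm <- file.path(d, "atlases", sprintf("atlas%02d_mask.nii.gz", a))
      write_volume(ph$volume, fv)
      write_volume(ph$mask, fm)
      files <- c(files, fv, fm)
    }
    files
  })

  run_stage("segment", function() {
    d <- file.path(out, "segment")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    sd <- file.path(out, "simulate")
    cohort <- read.csv(need(file.path(sd, "cohort.csv"), "simulate"))
    atl_files <- list.files(file.path(sd, "atlases"), "_vol\\.nii\\.gz$",
                            full.names = TRUE)
    atlases <- lapply(atl_files, function(fv) {
      v <- read_volume(fv)
      m <- read_volume(sub("_vol", "_mask", fv))
      list(volume = v, mask = array(m > 0.5, dim(v)))
    })
    rc <- do.call(registration_config, cfg$segmentation$registration)
    clf <- train_appearance_classifier(atlases, fcfg$scales_mm,
                                       cfg$segmentation$n_per_class,
                                       cfg$segmentation$num_trees,
                                       seed = cfg$seed)
    qc <- list()
    files <- character(0)
    for (i in seq_len(nrow(cohort))) {
      sid <- cohort$subject_id[i]
      vol <- read_volume(need(
        file.path(sd, "volumes", paste0(sid, "_vol.nii.gz")), "simulate"))
      seg <- segment_tibia(vol, atlases, classifier = clf, config = rc,
                           w = cfg$segmentation$w, t = cfg$segmentation$t,
                           qc_dice = cfg$segmentation$qc_dice,
                           appearance_downsample =
                             cfg$segmentation$appearance_downsample)
      fm <- file.path(d, paste0(sid, "_seg.nii.gz"))
      write_volume(seg$mask, fm)
      truth <- array(read_volume(
        file.path(sd, "volumes", paste0(sid, "_mask.nii.gz"))) > 0.5,
        dim(vol))
      qc[[i]] <- tibble::tibble(subject_id = sid,
                                dice_vs_truth = dice(seg$mask, truth),
                                qc_flag = seg$qc_flag)
      files <- c(files, fm)
    }
    fq <- file.path(d, "dice_qc.csv")
    write.csv(dplyr::bind_rows(qc), fq, row.names = FALSE)
    c(files, fq)
  })

  run_stage("voi", function() {
    d <- file.path(out, "voi")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    sd <- file.path(out, "simulate")
    cohort <- read.csv(need(file.path(sd, "cohort.csv"), "simulate"))
    files <- character(0)
    for (i in seq_len(nrow(cohort))) {
      sid <- cohort$subject_id[i]
      mask_path <- if (identical(cfg$voi$mask_source, "segmentation")) {
        need(file.path(out, "segment", paste0(sid, "_seg.nii.gz")), "segment")
      } else {
        need(file.path(sd, "volumes", paste0(sid, "_mask.nii.gz")), "simulate")
      }
      m <- read_volume(mask_path)
      mask <- image_volume(array(m > 0.5, dim(m)), voxel_spacing(m))
      vois <- extract_vois(mask,
                           central_fraction = cfg$voi$central_fraction,
                           min_separation = cfg$voi$min_separation,
                           right_knee = cfg$voi$right_knee)
      fj <- file.path(d, paste0(sid, "_vois.json"))
      write_voiset(vois, fj)
      files <- c(files, fj)
    }
    files
  })

  run_stage("features", function() {
    d <- file.path(out, "features")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    sd <- file.path(out, "simulate")
    cohort <- read.csv(need(file.path(sd, "cohort.csv"), "simulate"))
    rows <- list()
    for (i in seq_len(nrow(cohort))) {
      sid <- cohort$subject_id[i]
      vol <- read_volume(need(
        file.path(sd, "volumes", paste0(sid, "_vol.nii.gz")), "simulate"))
      mask_path <- if (identical(cfg$voi$mask_source, "segmentation")) {
        need(file.path(out, "segment", paste0(sid, "_seg.nii.gz")), "segment")
      } else {
        file.path(sd, "volumes", paste0(sid, "_mask.nii.gz"))
      }
      m <- read_volume(mask_path)
      mask <- image_volume(array(m > 0.5, dim(m)), voxel_spacing(m))
      vois <- read_voiset(need(
        file.path(out, "voi", paste0(sid, "_vois.json")), "voi"))
      rows[[i]] <- extract_all(vol, mask, vois, fcfg, subject_id = sid)
    }
    ff <- file.path(d, "features.csv")
    write.csv(dplyr::bind_rows(rows), ff, row.names = FALSE)
    ff
  })

  run_stage("train", function() {
    d <- file.path(out, "train")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    cohort <- read.csv(need(file.path(out, "simulate", "cohort.csv"),
                            "simulate"))
    features <- tibble::as_tibble(read.csv(
      need(file.path(out, "features", "features.csv"), "features")))
    spec <- model_spec(cfg$model$mode, cfg$model$voi_selection,
                       build_grid(cfg$model$alpha$start, cfg$model$alpha$end,
                                  cfg$model$alpha$by),
                       build_grid(cfg$model$lambda$start,
                                  cfg$model$lambda$end, cfg$model$lambda$by))
    dm <- build_design_matrix(cohort, features, spec,
                              label = cfg$model$label,
                              drop_zero_variance = TRUE)
    prot <- cv_protocol(cfg$cv$folds, cfg$cv$repetitions,
                        seed = cfg$seed + 2L,
                        stratified = cfg$cv$stratified,
                        pooling = cfg$cv$pooling)
    fit <- grid_search_cv(dm$X, dm$y, spec, prot)
    top <- head(tidy(fit), 5)
    jsonlite::write_json(
      list(alpha = fit$alpha, lambda = fit$lambda,
           mean_roc_auc = mean(fit$repetition_auc$roc_auc),
           mean_pr_auc = mean(fit$repetition_auc$pr_auc),
           top_coefficients = top),
      file.path(d, "fit.json"), auto_unbox = TRUE, digits = NA)
    oof <- as.data.frame(fit$oof_scores)
    names(oof) <- paste0("rep", seq_len(ncol(oof)))
    oof <- cbind(subject_id = dm$subject_id, label = dm$y, oof)
    write.csv(oof, file.path(d, "oof_scores.csv"), row.names = FALSE)
    saveRDS(fit, file.path(d, "fit.rds"))
    c(file.path(d, "fit.json"), file.path(d, "oof_scores.csv"))
  })

  run_stage("evaluate", function() {
    d <- file.path(out, "evaluate")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    oof <- read.csv(need(file.path(out, "train", "oof_scores.csv"), "train"))
    scores <- rowMeans(oof[, grep("^rep", names(oof)), drop = FALSE])
    y <- oof$label
    roc <- bootstrap_ci(roc_auc, scores, y, B = cfg$evaluate$bootstrap_B,
                        level = cfg$evaluate$level, seed = cfg$seed + 3L)
    pr <- bootstrap_ci(pr_auc, scores, y, B = cfg$evaluate$bootstrap_B,
                       level = cfg$evaluate$level, seed = cfg$seed + 4L)
    res <- dplyr::bind_rows(
      dplyr::mutate(roc, metric = "roc_auc"),
      dplyr::mutate(pr, metric = "pr_auc")) |>
      dplyr::mutate(voi_selection = cfg$model$voi_selection,
                    mode = cfg$model$mode)
    write.csv(res, file.path(d, "metrics.csv"), row.names = FALSE)
    rep <- report_table(res)
    write_report(rep, file.path(d, "report.csv"), file.path(d, "report.json"))
    curves <- performance_curve(scores, y)
    write.csv(curves, file.path(d, "curves.csv"), row.names = FALSE)
    c(file.path(d, "metrics.csv"), file.path(d, "report.csv"),
      file.path(d, "report.json"), file.path(d, "curves.csv"))
  })

  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all,
                                                units = "secs"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(manifest)
}
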