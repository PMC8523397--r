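#' Model specification for the osteoarthritis classifier
#'
#' @param mode `"covariates"` (age + BMI), `"image"` (radiomic features of
#'   the selected VOIs), or `"combined"`.
#' @param voi_selection `"All"` (six VOIs + whole-bone shape), `"AllMedial"`
#'   (SBM, MidM, TBM), or a single VOI name.
#' @param alpha_grid,lambda_grid hyperparameter grids (defaults reproduce
#'   the study grid).
#' @return a `tibrad_model_spec` list.
#' @export
model_spec <- function(mode = c("combined", "covariates", "image"),
                       voi_selection = "All",
                       alpha_grid = default_grids()$alpha,
                       lambda_grid = default_grids()$lambda) {
  mode <- match.arg(mode)
  valid <- c("All", "AllMedial", "SBM", "MidM", "TBM", "SBL", "MidL", "TBL")
  stopifnot(all(voi_selection %in% valid), length(alpha_grid) >= 1,
            length(lambda_grid) >= 1, all(alpha_grid >= 0 & alpha_grid <= 1),
            all(lambda_grid > 0))
  structure(list(mode = mode, voi_selection = voi_selection,
                 alpha_grid = alpha_grid, lambda_grid = lambda_grid),
            class = "tibrad_model_spec")
}

#' Cross-validation protocol
#'
#' @param folds number of folds (>= 2).
#' @param repetitions number of repeated CV rounds (study default 100).
#' @param seed integer seed.
#' @param stratified keep the class ratio in every fold.
#' @param pooling `"averaged"` (AUC per repetition on that repetition's
#'   pooled out-of-fold scores, then averaged) or `"pooled"` (single AUC on
#'   all out-of-fold scores).
#' @return a `tibrad_cv_protocol` list.
#' @export
cv_protocol <- function(folds = 10, repetitions = 100, seed = 1L,
                        stratified = TRUE,
                        pooling = c("averaged", "pooled")) {
  stopifnot(folds >= 2, repetitions >= 1)
  structure(list(folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), stratified = stratified,
                 pooling = match.arg(pooling)),
            class = "tibrad_cv_protocol")
}

voi_columns_for <- function(selection) {
  if (identical(selection, "All")) {
    list(vois = c("SBM", "MidM", "TBM", "SBL", "MidL", "TBL"), shape = TRUE)
  } else if (identical(selection, "AllMedial")) {
    list(vois = c("SBM", "MidM", "TBM"), shape = FALSE)
  } else {
    list(vois = selection, shape = FALSE)
  }
}

#' Build the design matrix and response for a model specification
#'
#' Covariate mode uses age and BMI only; image mode uses the features of the
#' selected VOIs (plus whole-bone shape features when the selection is
#' `"All"`); combined mode is their union. Columns are returned
#' unstandardized; [grid_search_cv()] standardizes inside training folds
#' only.
#'
#' @param cohort a [generate_cohort()] tibble (or any table with
#'   `subject_id`, `age`, `bmi` and the label column).
#' @param features tidy feature table with `subject_id` (may be `NULL` for
#'   covariate-only models).
#' @param spec a [model_spec()].
#' @param label name of the logical label column (default `label_tfoa`).
#' @param drop_zero_variance drop constant columns instead of erroring.
#' @return list with `X` (matrix), `y` (0/1 vector), `subject_id`.
#' @export
build_design_matrix <- function(cohort, features = NULL,
                                spec = model_spec(), label = "label_tfoa",
                                drop_zero_variance = FALSE) {
  stopifnot(inherits(spec, "tibrad_model_spec"),
            label %in% names(cohort))
  cov_mat <- as.matrix(cohort[, c("age", "bmi")])
  rownames(cov_mat) <- cohort$subject_id
  if (spec$mode == "covariates") {
    X <- cov_mat
  } else {
    if (is.null(features)) stop("image/combined mode needs a feature table")
    sel <- voi_columns_for(spec$voi_selection)
    keep_vois <- c(sel$vois, if (sel$shape) "whole")
    wide <- features_to_wide(dplyr::filter(features, .data$voi %in% keep_vois))
    missing <- setdiff(cohort$subject_id, wide$subject_id)
    if (length(missing) > 0) {
      stop("features missing for subjects: ",
           paste(head(missing, 5), collapse = ", "))
    }
    wide <- wide[match(cohort$subject_id, wide$subject_id), ]
    fmat <- as.matrix(wide[, setdiff(names(wide), "subject_id")])
    rownames(fmat) <- cohort$subject_id
    X <- if (spec$mode == "image") fmat else cbind(fmat, cov_mat)
  }
  sds <- apply(X, 2, sd)
  zv <- which(sds == 0 | !is.finite(sds))
  if (length(zv) > 0) {
    if (drop_zero_variance) {
      X <- X[, -zv, drop = FALSE]
    } else {
      stop("zero-variance column(s): ",
           paste(head(colnames(X)[zv], 5), collapse = ", "))
    }
  }
  list(X = X, y = as.numeric(cohort[[label]]), subject_id = cohort$subject_id)
}

# stratified fold assignment; returns integer fold id per observation
make_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

# standardize columns with training-fold statistics; zero-SD columns are
# centred and left unscaled
fold_standardizer <- function(Xtr) {
  mu <- colMeans(Xtr)
  sdev <- apply(Xtr, 2, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  list(mu = mu, sd = sdev,
       apply = function(X) sweep(sweep(X, 2, mu), 2, sdev, "/"))
}

#' Repeated stratified k-fold grid-search cross-validation
#'
#' For every (alpha, lambda) pair, runs `repetitions` rounds of stratified
#' k-fold CV of the elastic-net logistic model (standardizing predictors on
#' training folds only, warm starts along the lambda path), scores
#' out-of-fold predictions by ROC AUC, selects the pair with the highest
#' mean AUC (ties broken toward larger lambda, then larger alpha), and
#' refits on all data.
#'
#' @param X design matrix.
#' @param y binary response.
#' @param spec a [model_spec()] (grids are taken from it).
#' @param protocol a [cv_protocol()].
#' @return a `tibrad_fit`: final coefficients (original scale), selected
#'   hyperparameters, the CV grid with mean AUCs, per-repetition out-of-fold
#'   scores of the selected pair, and per-repetition ROC/PR AUCs.
#' @export
grid_search_cv <- function(X, y, spec = model_spec(),
                           protocol = cv_protocol()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  k <- protocol$folds
  R <- protocol$repetitions
  stopifnot(nrow(X) >= 5 * k)
  if (min(table(y)) < k && protocol$stratified) {
    stop("a fold would lack positives: use fewer folds or more data")
  }
  alphas <- spec$alpha_grid
  lambdas <- sort(spec$lambda_grid, decreasing = TRUE)  # warm-start path
  n <- nrow(X)
  nl <- length(lambdas)
  na <- length(alphas)
  # oof_scores[obs, lambda, alpha, rep]
  oof <- array(NA_real_, c(n, nl, na, R))
  with_local_seed(protocol$seed, {
    for (r in seq_len(R)) {
      fold <- make_folds(y, k, protocol$stratified)
      if (protocol$stratified && any(tapply(y, fold, function(v)
        length(unique(v))) < 2)) {
        stop("a fold lacks one class; reduce folds or check stratification")
      }
      for (f in seq_len(k)) {
        tr <- fold != f
        std <- fold_standardizer(X[tr, , drop = FALSE])
        Xtr <- std$apply(X[tr, , drop = FALSE])
        Xte <- std$apply(X[!tr, , drop = FALSE])
        ytr <- y[tr]
        for (a in seq_len(na)) {
          beta <- rep(0, ncol(X))
          b0 <- qlogis(mean(ytr))
          for (l in seq_len(nl)) {
            lam_prev <- if (l == 1) lambdas[1] else lambdas[l - 1]
            fit <- enet_fit_cpp(Xtr, ytr, alphas[a], lambdas[l],
                                beta, b0, 2e-4, 60L, lam_prev)
            beta <- as.numeric(fit$beta)
            b0 <- fit$intercept
            oof[!tr, l, a, r] <- plogis(as.numeric(
              Xte %*% beta + b0))
          }
        }
      }
    }
    NULL
  })
  # score the grid
  grid <- tidyr::expand_grid(alpha = alphas, lambda = lambdas)
  grid$mean_auc <- purrr::pmap_dbl(grid, function(alpha, lambda) {
    a <- match(alpha, alphas); l <- match(lambda, lambdas)
    if (protocol$pooling == "averaged") {
      mean(vapply(seq_len(R), function(r) roc_auc(oof[, l, a, r], y),
                  numeric(1)))
    } else {
      roc_auc(as.numeric(oof[, l, a, ]), rep(y, R))
    }
  })
  best <- grid |>
    dplyr::arrange(dplyr::desc(.data$mean_auc), dplyr::desc(.data$lambda),
                   dplyr::desc(.data$alpha)) |>
    dplyr::slice(1)
  ai <- match(best$alpha, alphas); li <- match(best$lambda, lambdas)
  best_oof <- oof[, li, ai, , drop = TRUE]
  best_oof <- matrix(best_oof, n, R)

  # final refit on all data (standardized internally, coefficients mapped
  # back to the original scale)
  std <- fold_standardizer(X)
  final <- fit_elastic_net(std$apply(X), y, best$alpha, best$lambda,
                           tol = 1e-6, maxit = 200, screen = TRUE)
  beta_orig <- final$beta / std$sd
  intercept_orig <- final$intercept - sum(final$beta * std$mu / std$sd)
  rep_auc <- tibble::tibble(
    repetition = seq_len(R),
    roc_auc = vapply(seq_len(R), function(r) roc_auc(best_oof[, r], y),
                     numeric(1)),
    pr_auc = vapply(seq_len(R), function(r) pr_auc(best_oof[, r], y),
                    numeric(1)))
  structure(list(coefficients = setNames(beta_orig, colnames(X)),
                 intercept = intercept_orig,
                 alpha = best$alpha, lambda = best$lambda,
                 cv_grid = grid, oof_scores = best_oof, y = y,
                 repetition_auc = rep_auc,
                 protocol = protocol, spec = spec,
                 n = n, p = ncol(X)),
            class = "tibrad_fit")
}

#' @export
print.tibrad_fit <- function(x, ...) {
  cat(sprintf("Elastic-net CV fit: n=%d, p=%d, mode=%s\n", x$n, x$p,
              x$spec$mode))
  cat(sprintf("  selected alpha=%.3g lambda=%.4g\n", x$alpha, x$lambda))
  cat(sprintf("  mean out-of-fold ROC AUC=%.3f, PR AUC=%.3f (%d repetitions)\n",
              mean(x$repetition_auc$roc_auc), mean(x$repetition_auc$pr_auc),
              nrow(x$repetition_auc)))
  nz <- sum(x$coefficients != 0)
  cat(sprintf("  %d nonzero coefficients\n", nz))
  invisible(x)
}

#' Tidy an elastic-net CV fit (broom-style)
#'
#' @param x a `tibrad_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, sorted by |estimate|.
#' @export
tidy.tibrad_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients)) |>
    dplyr::arrange(dplyr::desc(abs(.data$estimate)))
}

#' One-row summary of an elastic-net CV fit
#'
#' @param x a `tibrad_fit`.
#' @param ... unused.
#' @return one-row tibble with the selected hyperparameters, mean ROC/PR AUC
#'   and the nonzero coefficient count.
#' @export
glance.tibrad_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda,
                 roc_auc = mean(x$repetition_auc$roc_auc),
                 pr_auc = mean(x$repetition_auc$pr_auc),
                 n = x$n, p = x$p,
                 n_nonzero = sum(x$coefficients != 0))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
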