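make_toy_problem <- function(n = 120, p = 8, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  y <- rbinom(n, 1, plogis(1.2 * X[, 1] - X[, 2] - 0.5))
  list(X = X, y = y)
}

test_that("design matrices have the documented shapes", {
  co <- generate_cohort(20, 0.3, small_params(), seed = 2L)
  ph <- small_phantom(seed = 61L)
  vois <- extract_vois(ph$mask)
  feats <- dplyr::bind_rows(lapply(co$subject_id, function(sid) {
    f <- fixture("features_one", function()
      extract_all(ph$volume, ph$mask, vois))
    dplyr::bind_cols(tibble::tibble(subject_id = sid), f)
  }))
  # per-subject jitter so the image columns are not constant
  set.seed(4)
  feats$value <- feats$value * (1 + rnorm(nrow(feats), 0, 0.02)) +
    rnorm(nrow(feats), 0, 1e-6)
  dm_cov <- build_design_matrix(co, NULL, model_spec("covariates"))
  expect_equal(colnames(dm_cov$X), c("age", "bmi"))
  dm_img <- build_design_matrix(co, feats, model_spec("image", "SBM"),
                                drop_zero_variance = FALSE)
  expect_equal(ncol(dm_img$X), 3 + 12 + 271)
  dm_comb <- build_design_matrix(co, feats, model_spec("combined", "SBM"))
  expect_equal(ncol(dm_comb$X), ncol(dm_img$X) + 2)
  # whole-bone shape features enter only for the All selection
  dm_all <- build_design_matrix(co, feats, model_spec("image", "All"))
  expect_equal(ncol(dm_all$X), 6 * 286 + 17)
  # missing subjects are a named error
  expect_error(build_design_matrix(co, feats[feats$subject_id != "S0003", ],
                                   model_spec("image", "SBM")),
               "S0003")
  # zero-variance columns error unless dropped
  feats0 <- feats
  feats0$value[feats0$name == feats0$name[1]] <- 1
  expect_error(build_design_matrix(co, feats0, model_spec("image", "SBM")),
               "zero-variance")
})

test_that("a single grid point reduces to plain repeated CV and is seeded", {
  toy <- make_toy_problem()
  spec <- model_spec("image", "SBM", alpha_grid = 0.5, lambda_grid = 0.05)
  prot <- cv_protocol(folds = 4, repetitions = 2, seed = 31L)
  fit1 <- grid_search_cv(toy$X, toy$y, spec, prot)
  fit2 <- grid_search_cv(toy$X, toy$y, spec, prot)
  expect_equal(fit1$oof_scores, fit2$oof_scores)
  expect_equal(nrow(fit1$cv_grid), 1)
  expect_equal(fit1$alpha, 0.5)
  expect_equal(fit1$lambda, 0.05)
  expect_gt(mean(fit1$repetition_auc$roc_auc), 0.7)  # planted signal found
  expect_true(all(fit1$oof_scores > 0 & fit1$oof_scores < 1))
})

test_that("test-fold subjects do not leak into training-fold scalers", {
  toy <- make_toy_problem(n = 80, p = 4, seed = 9)
  spec <- model_spec("image", "SBM", alpha_grid = 0.5, lambda_grid = 0.05)
  prot <- cv_protocol(folds = 4, repetitions = 1, seed = 13L)
  fit1 <- grid_search_cv(toy$X, toy$y, spec, prot)
  # corrupt one subject grossly; fold assignment depends only on y and seed
  X2 <- toy$X
  X2[7, ] <- X2[7, ] + 1000
  fit2 <- grid_search_cv(X2, toy$y, spec, prot)
  fold_of <- local({
    set.seed(13L)
    tibrad:::make_folds(toy$y, 4, TRUE)
  })
  same_fold <- which(fold_of == fold_of[7] & seq_along(toy$y) != 7)
  # subjects sharing subject 7's test fold are scored by a model and scalers
  # fit without it: their out-of-fold scores must be unchanged
  expect_equal(fit1$oof_scores[same_fold, 1], fit2$oof_scores[same_fold, 1])
  # sanity: subjects in other folds are affected (7 entered their training)
  other <- which(fold_of != fold_of[7])
  expect_false(isTRUE(all.equal(fit1$oof_scores[other, 1],
                                fit2$oof_scores[other, 1])))
})

test_that("tidy and glance summarize fits in broom style", {
  toy <- make_toy_problem()
  fit <- grid_search_cv(toy$X, toy$y,
                        model_spec("image", "SBM", alpha_grid = c(0.5, 1),
                                   lambda_grid = c(0.02, 0.08)),
                        cv_protocol(4, 2, seed = 3L))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate"))
  expect_true(all(diff(abs(td$estimate)) <= 1e-12))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$roc_auc > 0 && gl$roc_auc < 1)
  expect_equal(gl$n, 120)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("unstratifiable folds are rejected with guidance", {
  toy <- make_toy_problem(n = 60)
  y <- c(rep(1, 3), rep(0, 57))
  expect_error(grid_search_cv(toy$X, y,
                              model_spec("image", "SBM", alpha_grid = 0.5,
                                         lambda_grid = 0.05),
                              cv_protocol(10, 1, seed = 1L)),
               "fewer folds|fold")
})
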