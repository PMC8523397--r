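test_that("ROC AUC matches pair counting, ties and limits", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(8)
  for (i in 1:10) {
    s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # with ties
    l <- rbinom(30, 1, 0.4)
    if (sum(l) %in% c(0, 30)) next
    expect_equal(roc_auc(s, l), roc_auc_bf(s, l))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("ROC AUC flips under score negation and resists monotone maps", {
  set.seed(10)
  s <- runif(40)  # tie-free almost surely
  l <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
  expect_equal(roc_auc(plogis(5 * s - 2), l), roc_auc(s, l))
  expect_equal(pr_auc(plogis(5 * s - 2), l), pr_auc(s, l))
})

test_that("PR AUC is average precision with the constant-score baseline", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # constant scores: precision equals prevalence at the single threshold
  l <- c(rep(1, 76), rep(0, 665 - 76))
  expect_equal(pr_auc(rep(0.5, 665), l), 76 / 665)
  # four-point hand example against the threshold sweep oracle
  s4 <- c(0.9, 0.7, 0.6, 0.2); l4 <- c(1, 0, 1, 0)
  expect_equal(pr_auc(s4, l4), pr_auc_bf(s4, l4))
  expect_equal(pr_auc(s4, l4), 0.5 * 1 + 0.5 * (2 / 3))
  set.seed(12)
  for (i in 1:10) {
    s <- sample(seq(0, 1, by = 0.2), 25, replace = TRUE)
    l <- rbinom(25, 1, 0.3)
    if (sum(l) == 0) next
    expect_equal(pr_auc(s, l), pr_auc_bf(s, l))
  }
})

test_that("bootstrap CIs are seeded, ordered and cover the null", {
  set.seed(14)
  s <- runif(120)
  l <- rbinom(120, 1, 0.3)
  ci1 <- bootstrap_ci(roc_auc, s, l, B = 400, seed = 5L)
  ci2 <- bootstrap_ci(roc_auc, s, l, B = 400, seed = 5L)
  expect_equal(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$estimate)
  expect_gte(ci1$ci_high, ci1$estimate)
  # perfect classifier: upper bound 1
  sp <- c(rep(1, 10), rep(0, 30))
  lp <- c(rep(1, 10), rep(0, 30))
  cip <- bootstrap_ci(roc_auc, sp, lp, B = 200, seed = 2L)
  expect_equal(cip$ci_high, 1.0)
  # coverage on a label-free null: most intervals contain 0.5
  cover <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    sn <- runif(100)
    ln <- rbinom(100, 1, 0.3)
    ci <- bootstrap_ci(roc_auc, sn, ln, B = 200, seed = i)
    ci$ci_low <= 0.5 && ci$ci_high >= 0.5
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("the report table has the study layout and round-trips", {
  res <- tidyr::expand_grid(
    voi_selection = c("All", "SBM", "MidM", "TBM", "SBL", "MidL", "TBL"),
    mode = c("covariates", "image", "combined"),
    metric = c("roc_auc", "pr_auc"))
  set.seed(3)
  res$estimate <- round(runif(nrow(res), 0.5, 0.9), 2)
  res$ci_low <- res$estimate - 0.07
  res$ci_high <- res$estimate + 0.07
  # the covariate model is the same model in every VOI row
  cov_rows <- res$mode == "covariates"
  for (mt in c("roc_auc", "pr_auc")) {
    sel <- cov_rows & res$metric == mt
    res$estimate[sel] <- res$estimate[sel][1]
    res$ci_low[sel] <- res$ci_low[sel][1]
    res$ci_high[sel] <- res$ci_high[sel][1]
  }
  rep <- report_table(res)
  expect_equal(nrow(rep), 7)
  expect_equal(length(unique(rep$covariates_roc_auc)), 1)
  expect_true(all(c("image_roc_auc", "combined_pr_auc") %in% names(rep)))
  # missing cells are explicit NA
  rep2 <- report_table(dplyr::filter(res, voi_selection != "TBL"))
  expect_true(all(is.na(rep2[rep2$voi_selection == "TBL",
                             "image_roc_auc"])))
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  write_report(rep, path_csv = path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$covariates_roc_auc_value, rep$covariates_roc_auc_value)
  expect_equal(back$voi_selection, rep$voi_selection)
})

test_that("evaluate_fit produces report-ready rows", {
  toy_X <- matrix(rnorm(120 * 4), 120, 4)
  colnames(toy_X) <- paste0("f", 1:4)
  set.seed(2)
  toy_y <- rbinom(120, 1, plogis(toy_X[, 1]))
  fit <- grid_search_cv(toy_X, toy_y,
                        model_spec("image", "SBM", alpha_grid = 1,
                                   lambda_grid = 0.05),
                        cv_protocol(4, 2, seed = 8L))
  ev <- evaluate_fit(fit, B = 200, seed = 3L)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$ci_low <= ev$estimate & ev$estimate <= ev$ci_high))
  expect_true(all(ev$estimate >= 0 & ev$estimate <= 1))
})
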