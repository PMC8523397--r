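#' Evaluate a CV fit with bootstrap confidence intervals
#'
#' Summarizes a `tibrad_fit` by the ROC AUC and PR AUC of its per-subject
#' mean out-of-fold score (averaged across repetitions), each with a
#' stratified percentile-bootstrap confidence interval, shaped for
#' [report_table()].
#'
#' @param fit a `tibrad_fit`.
#' @param B bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return tibble with `voi_selection`, `mode`, `metric`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
evaluate_fit <- function(fit, B = 2000, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "tibrad_fit"))
  scores <- rowMeans(fit$oof_scores)
  y <- fit$y
  roc <- bootstrap_ci(roc_auc, scores, y, B, level, seed)
  pr <- bootstrap_ci(pr_auc, scores, y, B, level, seed + 1L)
  dplyr::bind_rows(
    dplyr::mutate(roc, metric = "roc_auc"),
    dplyr::mutate(pr, metric = "pr_auc")) |>
    dplyr::mutate(voi_selection = paste(fit$spec$voi_selection,
                                        collapse = "+"),
                  mode = fit$spec$mode) |>
    dplyr::select("voi_selection", "mode", "metric", "estimate",
                  "ci_low", "ci_high")
}
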