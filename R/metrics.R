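#' Area under the ROC curve
#'
#' Mann-Whitney formulation via mid-ranks: ties between a positive and a
#' negative score count 0.5.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1 or logical).
#' @return scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Non-interpolated average precision over the threshold sweep of distinct
#' score values (tied scores enter as one group). A constant score gives
#' exactly the prevalence.
#'
#' @inheritParams roc_auc
#' @return scalar PR AUC in (0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1)
  if (npos == 0) stop("at least one positive required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores into single thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  d_rec <- diff(c(0, rec))
  sum(prec * d_rec)
}

#' Percentile bootstrap confidence interval for a ranking metric
#'
#' Stratified bootstrap (resampling positives and negatives separately) of
#' subjects; degenerate resamples with a single class are redrawn (counted
#' and capped). Under stratified resampling this does not occur, but the
#' guard also covers non-stratified use.
#'
#' @param metric function `(scores, labels) -> scalar`, e.g. [roc_auc()].
#' @param scores,labels data.
#' @param B number of bootstrap resamples (>= 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @return a `tibrad_metric_ci` tibble row: `estimate`, `ci_low`, `ci_high`,
#'   `method`, `B`, `seed`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 2000, level = 0.95,
                         seed = 1L) {
  labels <- as.numeric(labels)
  stopifnot(B >= 100, level > 0, level < 1)
  est <- metric(scores, labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  stat <- numeric(B)
  with_local_seed(seed, {
    redraws <- 0
    for (b in seq_len(B)) {
      for (attempt in 1:100) {
        idx <- c(sample(pos, length(pos), replace = TRUE),
                 sample(neg, length(neg), replace = TRUE))
        if (length(unique(labels[idx])) == 2) break
        redraws <- redraws + 1
      }
      stat[b] <- metric(scores[idx], labels[idx])
    }
    NULL
  })
  qs <- quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble::tibble(estimate = est, ci_low = qs[1], ci_high = qs[2],
                 method = "stratified percentile bootstrap",
                 B = as.integer(B), seed = as.integer(seed))
}

#' ROC and PR curve points for plotting
#'
#' @inheritParams roc_auc
#' @return tibble with `threshold`, `fpr`, `tpr`, `precision`, `recall`.
#' @export
performance_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  npos <- sum(l); nneg <- sum(1 - l)
  tibble::tibble(threshold = s[last],
                 fpr = fp[last] / nneg, tpr = tp[last] / npos,
                 precision = tp[last] / (tp[last] + fp[last]),
                 recall = tp[last] / npos)
}

#' Result table in the study's layout
#'
#' Rows are VOI selections, columns the three model modes crossed with
#' ROC/PR AUC and their confidence intervals; missing cells are explicit
#' `NA`.
#'
#' @param results tibble with columns `voi_selection`, `mode`, `metric`
#'   (`"roc_auc"` / `"pr_auc"`), `estimate`, `ci_low`, `ci_high`.
#' @param voi_order row order (defaults to the study's).
#' @return wide tibble with one row per VOI selection and formatted
#'   `"<est> (<lo>-<hi>)"` cells alongside the numeric columns.
#' @export
report_table <- function(results,
                         voi_order = c("All", "SBM", "MidM", "TBM", "SBL",
                                       "MidL", "TBL")) {
  need <- c("voi_selection", "mode", "metric", "estimate", "ci_low", "ci_high")
  stopifnot(all(need %in% names(results)))
  fmt <- function(e, lo, hi) {
    ifelse(is.na(e), NA_character_,
           sprintf("%.2f (%.2f-%.2f)", e, lo, hi))
  }
  full <- tidyr::expand_grid(
    voi_selection = voi_order,
    mode = c("covariates", "image", "combined"),
    metric = c("roc_auc", "pr_auc")) |>
    dplyr::left_join(results, by = c("voi_selection", "mode", "metric")) |>
    dplyr::mutate(cell = fmt(.data$estimate, .data$ci_low, .data$ci_high),
                  col = paste(.data$mode, .data$metric, sep = "_"))
  wide_txt <- full |>
    dplyr::select("voi_selection", "col", "cell") |>
    tidyr::pivot_wider(names_from = "col", values_from = "cell")
  wide_num <- full |>
    dplyr::select("voi_selection", "col", "estimate") |>
    tidyr::pivot_wider(names_from = "col", values_from = "estimate",
                       names_glue = "{col}_value")
  dplyr::left_join(wide_txt, wide_num, by = "voi_selection")
}

#' Write / read a report table (CSV and JSON round-trip)
#' @param report a [report_table()] tibble.
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) write.csv(report, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(report, path_json, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(report)
}
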