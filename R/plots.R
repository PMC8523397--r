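#' Coefficient plot for an elastic-net CV fit
#'
#' Horizontal bar chart of the largest-magnitude nonzero coefficients,
#' mirroring the "largest coefficients in the best performing model" style
#' of reporting.
#'
#' @param object a `tibrad_fit`.
#' @param top_n number of coefficients shown.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tibrad_fit <- function(object, top_n = 10, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$estimate != 0) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "coefficient (original scale)", y = NULL,
                  title = sprintf("Elastic net (alpha=%.2g, lambda=%.3g)",
                                  object$alpha, object$lambda)) +
    ggplot2::theme_minimal()
}

#' ROC and PR curves for classifier scores
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return a ggplot object with ROC and PR panels.
#' @export
plot_performance_curves <- function(scores, labels) {
  cv <- performance_curve(scores, labels)
  prev <- mean(as.numeric(labels))
  df <- dplyr::bind_rows(
    tibble::tibble(panel = "ROC", x = c(0, cv$fpr, 1), y = c(0, cv$tpr, 1)),
    tibble::tibble(panel = "Precision-recall", x = c(0, cv$recall),
                   y = c(cv$precision[1], cv$precision)))
  ref <- tibble::tibble(panel = c("ROC", "Precision-recall"),
                        slope = c(1, 0), intercept = c(0, prev))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_abline(data = ref,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept),
                         linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Sagittal slice with VOI overlay
#'
#' Shows one sagittal slice of a volume with the intersecting VOI boxes
#' outlined, for quick visual QC of the VOI placement.
#'
#' @param volume image volume.
#' @param vois a `tibrad_voiset`.
#' @param slice sagittal (medial-lateral) slice index; defaults to the
#'   middle of the first VOI.
#' @return a ggplot object.
#' @export
plot_voi_slice <- function(volume, vois, slice = NULL) {
  if (is.null(slice)) {
    b1 <- vois$boxes[[1]]
    slice <- round(mean(b1$x))
  }
  sl <- volume[slice, , ]
  df <- tibble::tibble(z = rep(seq_len(nrow(sl)), ncol(sl)),
                       y = rep(seq_len(ncol(sl)), each = nrow(sl)),
                       intensity = as.numeric(sl))
  rects <- purrr::imap_dfr(vois$boxes, function(b, nm) {
    if (slice < b$x[1] || slice > b$x[2]) return(NULL)
    tibble::tibble(voi = nm, zmin = b$z[1], zmax = b$z[2],
                   ymin = b$y[1], ymax = b$y[2])
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$z)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "anterior-posterior", y = "inferior-superior") +
    ggplot2::theme_minimal()
  if (nrow(rects) > 0) {
    p <- p + ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$ymin, xmax = .data$ymax,
                   ymin = .data$zmin, ymax = .data$zmax,
                   colour = .data$voi),
      fill = NA, inherit.aes = FALSE)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
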