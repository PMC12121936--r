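#' Plot stacked ROI traces
#'
#' @param object A [trace_matrix()].
#' @param rois ROI ids (or indices) to show; defaults to the first 10.
#' @param offset Vertical offset between traces, in units of the median
#'   per-trace sd.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trace_matrix <- function(object, rois = NULL, offset = 4, ...) {
  if (is.null(rois)) rois <- head(roi_ids(object), 10)
  if (is.numeric(rois)) rois <- roi_ids(object)[rois]
  v <- unclass(object)[rois, , drop = FALSE]
  step <- offset * median(apply(v, 1, sd))
  df <- tibble(
    roi_id = rep(rois, each = ncol(v)),
    time_s = rep((seq_len(ncol(v)) - 1) / frame_rate(object), length(rois)),
    value = as.vector(t(v)) +
      rep((seq_along(rois) - 1) * step, each = ncol(v))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value,
                                   group = .data$roi_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (offset per ROI)") +
    ggplot2::theme_minimal()
}

#' Histogram of normalized band power with the selection threshold
#'
#' @param object A `subprep_selection` from [select_rois()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subprep_selection <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$normalized_power, fill = .data$selected)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "normalized band power", y = "ROI count",
      title = sprintf("ROI selection at threshold %.2f", thr)
    ) +
    ggplot2::theme_minimal()
}

#' First principal component with flagged artifact intervals
#'
#' @param object A `subprep_artifacts` from [detect_artifacts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subprep_artifacts <- function(object, ...) {
  pc1 <- attr(object, "pc1")
  fs <- attr(object, "frame_rate_hz")
  if (is.null(pc1)) abort("This intervals object carries no pc1 diagnostic.")
  df <- tibble(time_s = (seq_along(pc1) - 1) / fs, pc1 = pc1)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$pc1)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "PC1 of z-scored traces") +
    ggplot2::theme_minimal()
  if (nrow(object) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(object),
      ggplot2::aes(
        xmin = .data$start_s, xmax = .data$end_s,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "red", alpha = 0.25
    )
  }
  p
}

#' dF/F trace with detected transients highlighted
#'
#' @param object A `subprep_transients` from [extract_transients()].
#' @param roi ROI id (or index) to show; defaults to the ROI with most peaks.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subprep_transients <- function(object, roi = NULL, ...) {
  if (is.null(roi)) {
    roi <- if (nrow(object$peaks)) {
      names(sort(table(object$peaks$roi_id), decreasing = TRUE))[1]
    } else {
      roi_ids(object$dff)[1]
    }
  }
  if (is.numeric(roi)) roi <- roi_ids(object$dff)[roi]
  fs <- frame_rate(object$dff)
  df <- tibble(
    time_s = (seq_len(n_frames(object$dff)) - 1) / fs,
    dff = unclass(object$dff)[roi, ],
    masked = unclass(object$masked_dff)[roi, ]
  )
  pk <- dplyr::filter(object$peaks, .data$roi_id == roi)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$dff)) +
    ggplot2::geom_line(colour = "darkgreen", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$masked), colour = "black",
                       linewidth = 0.4) +
    ggplot2::geom_point(
      data = pk, ggplot2::aes(.data$time_s, .data$amplitude),
      colour = "red", size = 1.5
    ) +
    ggplot2::labs(
      x = "time (s)", y = expression(Delta * F / F),
      title = sprintf("%s: %d transients", roi, nrow(pk))
    ) +
    ggplot2::theme_minimal()
}

#' K-scan diagnostics: silhouette (and AMI) against k
#'
#' @param object A `subprep_kscan` from [scan_k()] or the `kscan` element of
#'   [cluster_rois()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subprep_kscan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$scores, c("silhouette", "ami"),
    names_to = "metric", values_to = "score"
  )
  long <- dplyr::filter(long, !is.na(.data$score))
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$score,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(
      data = object$best,
      ggplot2::aes(xintercept = .data$k), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "number of clusters k", y = "score") +
    ggplot2::theme_minimal()
}
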