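#' Construct a trace matrix
#'
#' A `trace_matrix` holds fluorescence traces for one imaging channel as an
#' ROIs-by-frames numeric matrix, together with the frame rate and stable ROI
#' identifiers. It is the common currency of every pipeline stage: raw
#' fluorescence goes in, smoothed traces, z-scored traces and transient-masked
#' dF/F come out, all in the same container.
#'
#' Frame indices are 1-based throughout the package and frame intervals are
#' half-open `[start, end)`, so the length of an interval is `end - start` and
#' abutting intervals concatenate without overlap.
#'
#' @param values Numeric matrix, one row per ROI, one column per frame. All
#'   values must be finite.
#' @param frame_rate_hz Acquisition frame rate in Hz (e.g. 15.49 for a
#'   resonant-scanned two-photon FOV).
#' @param roi_ids Character vector of ROI identifiers, one per row. Defaults to
#'   `"roi_1" ... "roi_n"`. Identifiers are opaque and preserved end-to-end so
#'   outputs can be joined back to the upstream segmentation.
#' @param channel `"activity"` (calcium-sensitive fluorophore) or `"static"`
#'   (activity-independent fluorophore such as mRuby, used for motion
#'   verification).
#'
#' @return An object of class `trace_matrix`.
#' @export
#' @examples
#' tm <- trace_matrix(matrix(rnorm(300), nrow = 3), frame_rate_hz = 15.49)
#' n_rois(tm)
#' n_frames(tm)
trace_matrix <- function(values, frame_rate_hz, roi_ids = NULL,
                         channel = c("activity", "static")) {
  channel <- match.arg(channel)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (ROIs x frames).")
  }
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1 ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    abort("`frame_rate_hz` must be a single positive number.")
  }
  if (nrow(values) < 1) abort("A trace matrix needs at least one ROI.")
  if (ncol(values) < 2) abort("A trace matrix needs at least two frames.")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Non-finite value at ROI row %d, frame %d (and possibly others). Use `repair = TRUE` in the reader or clean the input.",
      bad[1, 1], bad[1, 2]
    ))
  }
  if (is.null(roi_ids)) roi_ids <- paste0("roi_", seq_len(nrow(values)))
  roi_ids <- as.character(roi_ids)
  if (length(roi_ids) != nrow(values)) {
    abort("`roi_ids` must have one entry per ROI row.")
  }
  if (anyDuplicated(roi_ids)) abort("ROI ids must be unique.")
  dimnames(values) <- list(roi_ids, NULL)
  structure(values,
    frame_rate_hz = frame_rate_hz, channel = channel,
    class = c("trace_matrix", "matrix", "array")
  )
}

#' Trace matrix accessors
#'
#' @param x A [trace_matrix()].
#' @return `n_rois()` and `n_frames()` return integer counts, `frame_rate()`
#'   the sampling rate in Hz, `roi_ids()` the character ROI identifiers and
#'   `nyquist()` half the frame rate.
#' @export
n_rois <- function(x) nrow(x)

#' @rdname n_rois
#' @export
n_frames <- function(x) ncol(x)

#' @rdname n_rois
#' @export
frame_rate <- function(x) attr(x, "frame_rate_hz")

#' @rdname n_rois
#' @export
roi_ids <- function(x) rownames(x)

#' @rdname n_rois
#' @export
nyquist <- function(x) {
  fs <- if (inherits(x, "trace_matrix")) frame_rate(x) else x
  fs / 2
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf(
    "<trace_matrix> %d ROIs x %d frames @ %.4g Hz (%s channel, %.1f s)\n",
    n_rois(x), n_frames(x), frame_rate(x), attr(x, "channel"),
    n_frames(x) / frame_rate(x)
  ))
  invisible(x)
}

# rebuild a trace_matrix with new values but the same metadata
tm_like <- function(values, template, ids = roi_ids(template)) {
  trace_matrix(values, frame_rate(template),
    roi_ids = ids,
    channel = attr(template, "channel")
  )
}

# subset of rows keeping metadata
tm_rows <- function(x, idx) {
  tm_like(unclass(x)[idx, , drop = FALSE], x, ids = roi_ids(x)[idx])
}

#' Validate a frequency band against a sampling rate
#'
#' @param low_hz,high_hz Band edges in Hz.
#' @param frame_rate_hz Sampling rate in Hz; the band must sit strictly below
#'   the Nyquist frequency.
#' @return A named numeric vector `c(low_hz, high_hz)`.
#' @export
frequency_band <- function(low_hz, high_hz, frame_rate_hz) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < frame_rate_hz / 2)) {
    abort(sprintf(
      "Band [%g, %g] Hz is invalid: need 0 < low < high < Nyquist (%g Hz).",
      low_hz, high_hz, frame_rate_hz / 2
    ))
  }
  c(low_hz = low_hz, high_hz = high_hz)
}

#' Read a trace matrix from CSV
#'
#' Accepts either a headerless numeric matrix (one row per ROI) or the format
#' written by [write_trace_csv()]: a header line starting with `roi_id`
#' followed by one row per ROI whose first field is the ROI identifier.
#'
#' @param path Path to a CSV file.
#' @param frame_rate_hz Frame rate in Hz.
#' @param channel Channel label, `"activity"` or `"static"`.
#' @param repair If `TRUE`, non-finite cells are repaired by per-ROI linear
#'   interpolation (constant extension at the ends) instead of raising an
#'   error. Off by default: silent imputation hides upstream problems.
#' @return A [trace_matrix()]. Row order of the file is preserved.
#' @export
read_trace_csv <- function(path, frame_rate_hz,
                           channel = c("activity", "static"),
                           repair = FALSE) {
  channel <- match.arg(channel)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  nf <- count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1) {
    abort(sprintf(
      "Ragged CSV: rows have differing field counts (%s) in %s.",
      paste(unique(nf), collapse = ", "), path
    ))
  }
  first <- readLines(path, n = 1)
  has_header <- grepl("^\"?roi_id\"?,", first)
  df <- suppressWarnings(readr::read_csv(
    path,
    col_names = has_header, col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE
  ))
  first_col <- df[[1]]
  id_col <- has_header || anyNA(suppressWarnings(as.numeric(first_col)))
  if (id_col) {
    ids <- as.character(first_col)
    num <- df[, -1, drop = FALSE]
  } else {
    ids <- NULL
    num <- df
  }
  values <- matrix(suppressWarnings(as.numeric(as.matrix(num))),
    nrow = nrow(df)
  )
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    if (repair) {
      values <- t(apply(values, 1, interpolate_nonfinite))
    } else {
      abort(sprintf(
        "Non-finite value at row %d, frame column %d of %s (and possibly others).",
        bad[1, 1], bad[1, 2], path
      ))
    }
  }
  trace_matrix(values, frame_rate_hz, roi_ids = ids, channel = channel)
}

#' Write a trace matrix to CSV
#'
#' Writes a header `roi_id,f1,...,fN` followed by one row per ROI. Values are
#' written with full double precision so that
#' `read_trace_csv(write_trace_csv(x))` round-trips bit-identically.
#'
#' @param traces A [trace_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  df <- tibble::as_tibble(unclass(traces)[, , drop = FALSE],
    .name_repair = ~ paste0("f", seq_along(.x))
  )
  df <- dplyr::bind_cols(tibble(roi_id = roi_ids(traces)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# linear interpolation over non-finite cells; constant extension at ends
interpolate_nonfinite <- function(x) {
  ok <- is.finite(x)
  if (all(ok)) return(x)
  if (sum(ok) < 2) abort("Cannot repair a trace with fewer than 2 finite values.")
  approx(which(ok), x[ok], xout = seq_along(x), rule = 2)$y
}
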