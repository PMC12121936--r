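#' Rolling-percentile baseline of a fluorescence trace
#'
#' Estimates the slowly varying baseline F0 as a low percentile (default the
#' 8th) of the fluorescence distribution in a centred ~20 s window around
#' each sample. Calcium transients are sparse and positive, so a low
#' percentile tracks bleaching and slow drift while ignoring the transients
#' themselves. Windows are truncated (not reflected) at the session edges:
#' reflection would fabricate data at the boundaries.
#'
#' @param trace Numeric vector.
#' @param frame_rate_hz Sampling rate in Hz.
#' @param window_s Window length in seconds (default 20).
#' @param percentile Percentile in (0, 100) (default 8).
#' @return Numeric baseline, same length as `trace`.
#' @export
rolling_percentile_baseline <- function(trace, frame_rate_hz, window_s = 20,
                                        percentile = 8) {
  if (!(window_s > 0) || !(percentile > 0 && percentile < 100)) {
    abort("Need window_s > 0 and 0 < percentile < 100.")
  }
  wf <- max(3L, as.integer(round(window_s * frame_rate_hz)))
  if (wf > length(trace)) {
    abort(sprintf(
      "Baseline window (%d frames) exceeds trace length (%d frames).",
      wf, length(trace)
    ))
  }
  half <- wf %/% 2L
  .roll_quantile_cpp(as.double(trace), half, percentile / 100)
}

#' Baseline-corrected dF/F
#'
#' `dff[t] = (F[t] - F0[t]) / max(F0[t], eps)`. The small floor `eps`
#' (default 1% of the trace's global median, never below 1e-6) guards
#' against division by a near-zero baseline in dim ROIs. With
#' `subtract_only = TRUE` the numerator is returned unscaled.
#'
#' @param trace Numeric fluorescence vector.
#' @param baseline Baseline from [rolling_percentile_baseline()], same length.
#' @param eps Baseline floor; `NULL` for the default rule.
#' @param subtract_only If `TRUE`, return `F - F0` without dividing.
#' @return Numeric dF/F vector.
#' @export
compute_dff <- function(trace, baseline, eps = NULL, subtract_only = FALSE) {
  if (length(trace) != length(baseline)) {
    abort("`trace` and `baseline` must have the same length.")
  }
  if (subtract_only) return(trace - baseline)
  if (is.null(eps)) eps <- max(0.01 * abs(median(trace)), 1e-6)
  if (all(baseline <= 0)) {
    abort("Baseline is non-positive everywhere; dF/F is undefined.")
  }
  (trace - baseline) / pmax(baseline, eps)
}

#' Detect significant calcium transients in a dF/F trace
#'
#' Finds local maxima and keeps those passing all three gates: amplitude
#' (height) at least `min_amplitude`, prominence at least `min_prominence`,
#' and width at half-prominence of at least `ceiling(min_duration_s *
#' frame_rate_hz)` frames. Prominence — the height of a peak above the higher
#' of its two flanking valleys — and the duration gate together reject brief
#' noise excursions that clear the raw amplitude bar. Each surviving peak is
#' annotated with its extent: the prominence base interval, clipped on each
#' side at the first frame where dF/F drops below 0 so that long shallow
#' shoulders are not swept into the transient.
#'
#' @param dff Numeric dF/F vector.
#' @param frame_rate_hz Sampling rate in Hz.
#' @param min_amplitude Minimum peak height in dF/F units (default 0.12).
#' @param min_duration_s Minimum width at half-prominence in seconds
#'   (default 0.5).
#' @param min_prominence Minimum prominence in dF/F units (default 0.1).
#' @return A tibble with one row per accepted peak: `peak_frame`, `time_s`,
#'   `amplitude`, `prominence`, `width_s`, `extent_start`, `extent_end`
#'   (1-based, half-open).
#' @export
detect_peaks <- function(dff, frame_rate_hz, min_amplitude = 0.12,
                         min_duration_s = 0.5, min_prominence = 0.1) {
  if (!all(is.finite(dff))) abort("`dff` contains non-finite values.")
  stopifnot(min_amplitude > 0, min_duration_s > 0, min_prominence > 0)
  cand <- local_maxima(dff)
  empty <- tibble(
    peak_frame = integer(0), time_s = numeric(0), amplitude = numeric(0),
    prominence = numeric(0), width_s = numeric(0),
    extent_start = integer(0), extent_end = integer(0)
  )
  if (length(cand) == 0) return(empty)
  pr <- peak_prominences(dff, cand)
  wd <- peak_widths(dff, cand, pr, rel_height = 0.5)
  min_w_frames <- ceiling(min_duration_s * frame_rate_hz)
  keep <- dff[cand] >= min_amplitude &
    pr$prominence >= min_prominence &
    wd$width_frames >= min_w_frames
  if (!any(keep)) return(empty)
  cand <- cand[keep]
  prom <- pr$prominence[keep]
  lb <- pr$left_base[keep]
  rb <- pr$right_base[keep]
  wds <- wd$width_frames[keep]
  ext <- vapply(seq_along(cand), function(i) {
    clip_extent(dff, cand[i], lb[i], rb[i])
  }, numeric(2))
  tibble(
    peak_frame = as.integer(cand),
    time_s = (cand - 1) / frame_rate_hz,
    amplitude = dff[cand],
    prominence = prom,
    width_s = wds / frame_rate_hz,
    extent_start = as.integer(ext[1, ]),
    extent_end = as.integer(ext[2, ])
  )
}

# Strict local maxima; flat-topped peaks report their midpoint.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i - 1] < x[i]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1L
      if (j < n && x[j + 1] < x[i]) peaks <- c(peaks, (i + j) %/% 2L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# Prominence of each peak: height above the higher of the two valley minima
# between the peak and the nearest higher point (or signal border) on each
# side. Bases are the positions of those minima.
peak_prominences <- function(x, peaks) {
  n <- length(x)
  prom <- numeric(length(peaks))
  lbase <- integer(length(peaks))
  rbase <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    i <- p
    lmin <- x[p]
    lpos <- p
    while (i > 1 && x[i - 1] <= x[p]) {
      i <- i - 1L
      if (x[i] < lmin) {
        lmin <- x[i]
        lpos <- i
      }
    }
    i <- p
    rmin <- x[p]
    rpos <- p
    while (i < n && x[i + 1] <= x[p]) {
      i <- i + 1L
      if (x[i] < rmin) {
        rmin <- x[i]
        rpos <- i
      }
    }
    prom[k] <- x[p] - max(lmin, rmin)
    lbase[k] <- lpos
    rbase[k] <- rpos
  }
  list(prominence = prom, left_base = lbase, right_base = rbase)
}

# Width (in frames, interpolated) at a reference height of
# peak - rel_height * prominence, searched within the base interval.
peak_widths <- function(x, peaks, pr, rel_height = 0.5) {
  w <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    ref <- x[p] - rel_height * pr$prominence[k]
    i <- p
    while (i > pr$left_base[k] && x[i - 1] >= ref) i <- i - 1L
    left_ip <- as.numeric(i)
    if (i > pr$left_base[k]) { # x[i-1] < ref <= x[i]: interpolate the crossing
      left_ip <- i - (x[i] - ref) / (x[i] - x[i - 1])
    }
    j <- p
    while (j < pr$right_base[k] && x[j + 1] >= ref) j <- j + 1L
    right_ip <- as.numeric(j)
    if (j < pr$right_base[k]) {
      right_ip <- j + (x[j] - ref) / (x[j] - x[j + 1])
    }
    w[k] <- right_ip - left_ip
  }
  list(width_frames = w)
}

# Extent: prominence bases clipped at the first sub-zero frame on each side.
clip_extent <- function(x, p, lb, rb) {
  s <- lb
  i <- p
  while (i > lb) {
    if (x[i - 1] < 0) {
      s <- i
      break
    }
    i <- i - 1L
    s <- i
  }
  e <- rb
  j <- p
  while (j < rb) {
    if (x[j + 1] < 0) {
      e <- j
      break
    }
    j <- j + 1L
    e <- j
  }
  c(s, e + 1) # half-open
}

#' Zero a dF/F trace outside detected transients
#'
#' Samples inside the union of peak extents keep their dF/F values; all other
#' samples are set exactly to 0, so downstream correlations see only
#' significant transients.
#'
#' @param dff Numeric dF/F vector.
#' @param peaks Peak tibble from [detect_peaks()] on the same trace.
#' @return Numeric vector of the same length.
#' @export
mask_to_transients <- function(dff, peaks) {
  keep <- rep(FALSE, length(dff))
  for (i in seq_len(nrow(peaks))) {
    keep[peaks$extent_start[i]:(peaks$extent_end[i] - 1)] <- TRUE
  }
  out <- numeric(length(dff))
  out[keep] <- dff[keep]
  out
}

#' Extract significant transients from every ROI
#'
#' Runs baseline correction ([rolling_percentile_baseline()],
#' [compute_dff()]), peak detection ([detect_peaks()]) and transient masking
#' ([mask_to_transients()]) over a whole [trace_matrix()].
#'
#' @param traces A [trace_matrix()] of raw or artifact-cleaned fluorescence.
#' @inheritParams rolling_percentile_baseline
#' @inheritParams detect_peaks
#' @inheritParams compute_dff
#' @return A `subprep_transients` object: a list with `peaks` (tibble over
#'   all ROIs, with `roi_id`), `dff` and `masked_dff` (both [trace_matrix()]).
#' @export
extract_transients <- function(traces, window_s = 20, percentile = 8,
                               min_amplitude = 0.12, min_duration_s = 0.5,
                               min_prominence = 0.1, subtract_only = FALSE) {
  stopifnot(inherits(traces, "trace_matrix"))
  fs <- frame_rate(traces)
  v <- unclass(traces)
  dff <- matrix(0, nrow(v), ncol(v))
  masked <- matrix(0, nrow(v), ncol(v))
  pk_list <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    f0 <- rolling_percentile_baseline(v[i, ], fs, window_s, percentile)
    d <- compute_dff(v[i, ], f0, subtract_only = subtract_only)
    pk <- detect_peaks(d, fs, min_amplitude, min_duration_s, min_prominence)
    dff[i, ] <- d
    masked[i, ] <- mask_to_transients(d, pk)
    pk_list[[i]] <- dplyr::bind_cols(
      tibble(roi_id = rep(roi_ids(traces)[i], nrow(pk))), pk
    )
  }
  structure(
    list(
      peaks = dplyr::bind_rows(pk_list),
      dff = tm_like(dff, traces),
      masked_dff = tm_like(masked, traces)
    ),
    class = "subprep_transients"
  )
}

#' @export
print.subprep_transients <- function(x, ...) {
  cat(sprintf(
    "<subprep_transients> %d peaks across %d ROIs (%d ROIs with >= 1 peak)\n",
    nrow(x$peaks), n_rois(x$dff), length(unique(x$peaks$roi_id))
  ))
  invisible(x)
}

#' @export
tidy.subprep_transients <- function(x, ...) x$peaks

#' @export
glance.subprep_transients <- function(x, ...) {
  mins <- n_frames(x$dff) / frame_rate(x$dff) / 60
  tibble(
    n_rois = n_rois(x$dff),
    n_peaks = nrow(x$peaks),
    n_rois_with_peaks = length(unique(x$peaks$roi_id)),
    peaks_per_min = nrow(x$peaks) / (mins * n_rois(x$dff)),
    mean_amplitude = mean(x$peaks$amplitude)
  )
}
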