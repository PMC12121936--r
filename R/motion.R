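#' Z-score traces per ROI
#'
#' Standardizes each ROI trace to zero mean and unit standard deviation
#' (population sd, i.e. dividing by `sqrt(mean((x - mean(x))^2))`), making
#' traces of very different brightness comparable before PCA. A z-plane shift
#' moves many ROIs at once — in different directions but at the same frames —
#' so after z-scoring it dominates the shared variance.
#'
#' @param traces A [trace_matrix()].
#' @return A [trace_matrix()] of z-scored traces.
#' @export
zscore_traces <- function(traces) {
  stopifnot(inherits(traces, "trace_matrix"))
  v <- unclass(traces)
  mu <- rowMeans(v)
  s <- sqrt(rowMeans((v - mu)^2))
  zero <- which(s == 0)
  if (length(zero) > 0) {
    abort(sprintf(
      "Zero-variance ROI(s) cannot be z-scored: %s",
      paste(roi_ids(traces)[zero], collapse = ", ")
    ))
  }
  tm_like((v - mu) / s, traces)
}

#' First principal component of the ROI population
#'
#' Treats frames as observations and ROIs as variables, so the leading
#' principal component is itself a time series: the single temporal pattern
#' that explains the most shared variance across ROIs. For a synchronous
#' z-shift this component shows a level change confined to the shift period.
#' The sign is fixed so the frame of maximum magnitude is positive.
#'
#' @param zscored A [trace_matrix()], normally from [zscore_traces()].
#' @return A list with `pc1` (numeric, length `n_frames`) and
#'   `explained_variance_ratio` (fraction in \[0, 1\]).
#' @export
first_principal_component <- function(zscored) {
  stopifnot(inherits(zscored, "trace_matrix"))
  v <- unclass(zscored)
  if (nrow(v) == 1) {
    pc1 <- as.numeric(v[1, ] - mean(v[1, ]))
    evr <- 1.0
  } else {
    pr <- prcomp(t(v), center = TRUE, scale. = FALSE)
    pc1 <- as.numeric(pr$x[, 1])
    evr <- pr$sdev[1]^2 / sum(pr$sdev^2)
  }
  if (pc1[which.max(abs(pc1))] < 0) pc1 <- -pc1
  list(pc1 = pc1, explained_variance_ratio = evr)
}

#' Bottom-up change-point segmentation
#'
#' Splits the series into many tiny equal-length segments (2-frame atoms) and
#' greedily merges the adjacent pair whose merge increases the total
#' within-segment sum of squared deviations the least, until exactly
#' `n_change_points` interior breakpoints remain. This bottom-up strategy is
#' robust to outliers and handles multiple level shifts; the number of change
#' points is a user input — over-specify and let
#' [classify_artifact_segments()] reject spurious ones.
#'
#' @param series Numeric vector (typically `pc1`).
#' @param n_change_points Number of interior breakpoints to return.
#' @param atom_frames Initial segment size in frames (default 2).
#' @return Sorted integer breakpoints: each is the 1-based index of the first
#'   frame of the segment to its right, so segments are
#'   `[1, b1), [b1, b2), ..., [bk, n+1)` in half-open convention.
#' @export
bottomup_segment <- function(series, n_change_points, atom_frames = 2) {
  n <- length(series)
  if (n < atom_frames * 4) {
    abort(sprintf("Series too short: need at least %d frames.", atom_frames * 4))
  }
  if (n_change_points < 1) abort("`n_change_points` must be >= 1.")
  # atom boundaries: starts of each atom (1-based), last atom absorbs remainder
  starts <- seq(1, n - atom_frames + 1, by = atom_frames)
  m <- length(starts)
  if (n_change_points >= m) {
    abort("`n_change_points` too large for this series length.")
  }
  ends <- c(starts[-1], n + 1) # half-open ends
  # per-segment sufficient statistics
  csum <- c(0, cumsum(series))
  csum2 <- c(0, cumsum(series^2))
  seg_n <- as.numeric(ends - starts)
  seg_s <- csum[ends] - csum[starts]
  seg_s2 <- csum2[ends] - csum2[starts]
  sse <- function(nn, ss, ss2) ss2 - ss^2 / nn
  cost <- sse(seg_n, seg_s, seg_s2)
  # merge cost of joining segment i with i+1
  merge_delta <- function(i, j) {
    sse(seg_n[i] + seg_n[j], seg_s[i] + seg_s[j], seg_s2[i] + seg_s2[j]) -
      cost[i] - cost[j]
  }
  alive <- rep(TRUE, m)
  nxt <- c(seq_len(m)[-1], NA_integer_)
  prv <- c(NA_integer_, seq_len(m)[-m])
  delta <- rep(NA_real_, m) # delta[i] = cost of merging i with nxt[i]
  idx <- seq_len(m - 1)
  delta[idx] <- merge_delta(idx, idx + 1)
  n_bkps <- m - 1
  while (n_bkps > n_change_points) {
    i <- which.min(delta) # leftmost minimum on ties
    j <- nxt[i]
    # merge j into i
    seg_n[i] <- seg_n[i] + seg_n[j]
    seg_s[i] <- seg_s[i] + seg_s[j]
    seg_s2[i] <- seg_s2[i] + seg_s2[j]
    ends[i] <- ends[j]
    cost[i] <- sse(seg_n[i], seg_s[i], seg_s2[i])
    alive[j] <- FALSE
    nxt[i] <- nxt[j]
    if (!is.na(nxt[i])) prv[nxt[i]] <- i
    delta[j] <- NA_real_
    delta[i] <- if (is.na(nxt[i])) NA_real_ else merge_delta(i, nxt[i])
    p <- prv[i]
    if (!is.na(p)) delta[p] <- merge_delta(p, i)
    n_bkps <- n_bkps - 1
  }
  sort(starts[alive][-1])
}

#' Classify segments as z-shift artifacts
#'
#' Replaces the by-eye validation of candidate change points with an explicit
#' rule: a segment is flagged iff its median level deviates from the global
#' baseline median by more than `deviation_k` robust scale units AND it lasts
#' at least `min_artifact_duration_s`. The baseline median and robust scale
#' (1.4826 x MAD) are estimated in two passes: first over all frames, then
#' over unflagged segments only, so a large artifact cannot inflate its own
#' baseline. Adjacent flagged segments are merged. The duration gate reflects
#' that genuine population coactivity is transient (a second or two) while a
#' z-plane shift persists.
#'
#' @param pc1 Numeric series (from [first_principal_component()]).
#' @param breakpoints Integer breakpoints from [bottomup_segment()].
#' @param frame_rate_hz Sampling rate in Hz.
#' @param min_artifact_duration_s Minimum artifact duration in seconds
#'   (default 2).
#' @param deviation_k Robust deviation multiplier (default 3).
#' @param source Channel label stored on the result (default
#'   `"activity_channel"`).
#' @return A `subprep_artifacts` tibble with columns `start_frame`,
#'   `end_frame` (1-based, half-open), `start_s`, `end_s`; attribute `source`.
#' @export
classify_artifact_segments <- function(pc1, breakpoints, frame_rate_hz,
                                       min_artifact_duration_s = 2,
                                       deviation_k = 3,
                                       source = "activity_channel") {
  n <- length(pc1)
  if (length(breakpoints) > 0 &&
      (min(breakpoints) < 2 || max(breakpoints) > n)) {
    abort("Breakpoints out of range for this series.")
  }
  bounds <- c(1, sort(breakpoints), n + 1)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  meds <- vapply(seq_along(starts), function(i) {
    median(pc1[starts[i]:(ends[i] - 1)])
  }, numeric(1))
  durs <- (ends - starts) / frame_rate_hz
  flag_pass <- function(baseline_frames) {
    base_med <- median(pc1[baseline_frames])
    scale <- 1.4826 * median(abs(pc1[baseline_frames] - base_med))
    if (scale == 0) scale <- 1e-12
    abs(meds - base_med) > deviation_k * scale & durs >= min_artifact_duration_s
  }
  flagged <- flag_pass(seq_len(n))
  if (any(flagged) && !all(flagged)) {
    keep <- unlist(lapply(which(!flagged), function(i) starts[i]:(ends[i] - 1)))
    flagged <- flag_pass(keep)
  }
  iv <- merge_flagged(starts, ends, flagged)
  artifact_intervals(iv, frame_rate_hz, source = source)
}

merge_flagged <- function(starts, ends, flagged) {
  if (!any(flagged)) {
    return(tibble(start_frame = integer(0), end_frame = integer(0)))
  }
  r <- rle(flagged)
  re <- cumsum(r$lengths)
  rs <- re - r$lengths + 1
  on <- which(r$values)
  tibble(
    start_frame = as.integer(starts[rs[on]]),
    end_frame = as.integer(ends[re[on]])
  )
}

artifact_intervals <- function(iv, frame_rate_hz, source = "activity_channel") {
  iv <- dplyr::mutate(iv,
    start_s = (.data$start_frame - 1) / frame_rate_hz,
    end_s = (.data$end_frame - 1) / frame_rate_hz
  )
  structure(iv,
    source = source, frame_rate_hz = frame_rate_hz,
    class = c("subprep_artifacts", class(tibble()))
  )
}

#' Validate candidate artifact intervals by population synchrony
#'
#' A z-plane shift moves many, if not all, ROIs in the FOV at once, whereas a
#' large calcium transient — which can also drive a sustained excursion of
#' PC1 when it belongs to a dominant ROI or axon group — moves only a few.
#' For each candidate interval this check asks what fraction of ROIs
#' individually show a sustained level shift there: ROI `i` counts as
#' affected when the median of its (detrended, z-scored) trace inside the
#' interval deviates from its outside-interval median by more than
#' `deviation_k` times its own robust scale (1.4826 x MAD, computed outside
#' all candidate intervals). Intervals with fewer than
#' `min_affected_fraction` of ROIs affected are discarded as activity-driven.
#'
#' @param traces The [trace_matrix()] the candidates were detected on.
#' @param intervals A `subprep_artifacts` tibble of candidate intervals.
#' @param deviation_k Per-ROI robust deviation multiplier (default 3).
#' @param min_affected_fraction Minimum fraction of ROIs that must shift
#'   (default 0.25).
#' @param detrend Detrend each trace first, as in [detect_artifacts()].
#' @return The intervals that pass, with a column `affected_fraction`.
#' @export
validate_synchrony <- function(traces, intervals, deviation_k = 3,
                               min_affected_fraction = 0.25, detrend = TRUE) {
  if (nrow(intervals) == 0) {
    return(dplyr::mutate(intervals, affected_fraction = numeric(0)))
  }
  v <- unclass(traces)
  if (detrend) v <- t(apply(v, 1, detrend_series))
  mu <- rowMeans(v)
  s <- sqrt(rowMeans((v - mu)^2))
  s[s == 0] <- 1
  v <- (v - mu) / s
  inside_any <- rep(FALSE, ncol(v))
  for (i in seq_len(nrow(intervals))) {
    inside_any[intervals$start_frame[i]:(intervals$end_frame[i] - 1)] <- TRUE
  }
  out_idx <- which(!inside_any)
  base <- apply(v[, out_idx, drop = FALSE], 1, median)
  scale <- 1.4826 * apply(
    abs(v[, out_idx, drop = FALSE] - base), 1, median
  )
  scale[scale == 0] <- 1e-12
  frac <- vapply(seq_len(nrow(intervals)), function(i) {
    idx <- intervals$start_frame[i]:(intervals$end_frame[i] - 1)
    seg_med <- apply(v[, idx, drop = FALSE], 1, median)
    mean(abs(seg_med - base) > deviation_k * scale)
  }, numeric(1))
  out <- dplyr::mutate(intervals, affected_fraction = frac)
  keep <- frac >= min_affected_fraction
  att <- attributes(intervals)
  out <- out[keep, , drop = FALSE]
  attr(out, "source") <- att$source
  attr(out, "frame_rate_hz") <- att$frame_rate_hz
  out
}

#' Detect z-shift artifact intervals in one call
#'
#' Runs z-scoring, PCA, bottom-up segmentation, segment classification and
#' population-synchrony validation.
#'
#' @param traces A [trace_matrix()].
#' @param n_change_points Breakpoints to request from [bottomup_segment()]
#'   (default 4; over-specify rather than under-specify).
#' @param detrend If `TRUE` (default), remove a per-ROI linear trend before
#'   z-scoring. Photobleaching is coherent across the whole FOV, so without
#'   detrending the leading principal component is the slow drift itself and
#'   abrupt z-shifts hide behind it; detrending leaves level shifts intact
#'   while removing the ramp.
#' @inheritParams classify_artifact_segments
#' @inheritParams validate_synchrony
#' @param synchrony_check If `TRUE` (default), candidate intervals must also
#'   pass [validate_synchrony()]: at least `min_affected_fraction` of ROIs
#'   showing an individual sustained level shift. This is what separates a
#'   FOV-wide z-shift from a dominant axon's calcium transient, which can
#'   drive PC1 just as hard but only moves a handful of ROIs.
#' @return A `subprep_artifacts` tibble (see [classify_artifact_segments()]);
#'   attributes `pc1` and `explained_variance_ratio` carry the diagnostics.
#' @export
detect_artifacts <- function(traces, n_change_points = 4,
                             min_artifact_duration_s = 2, deviation_k = 3,
                             detrend = TRUE, synchrony_check = TRUE,
                             min_affected_fraction = 0.25) {
  raw <- traces
  if (detrend) {
    det <- t(apply(unclass(traces), 1, detrend_series))
    traces <- tm_like(det, traces)
  }
  pc <- first_principal_component(zscore_traces(traces))
  bk <- bottomup_segment(pc$pc1, n_change_points)
  iv <- classify_artifact_segments(
    pc$pc1, bk, frame_rate(traces),
    min_artifact_duration_s = min_artifact_duration_s,
    deviation_k = deviation_k,
    source = if (attr(traces, "channel") == "static") {
      "static_channel"
    } else {
      "activity_channel"
    }
  )
  if (synchrony_check) {
    iv <- validate_synchrony(raw, iv,
      deviation_k = deviation_k,
      min_affected_fraction = min_affected_fraction, detrend = detrend
    )
  }
  attr(iv, "pc1") <- pc$pc1
  attr(iv, "explained_variance_ratio") <- pc$explained_variance_ratio
  iv
}

#' Verify artifact intervals against a static-fluorophore channel
#'
#' Runs the same z-score / PCA / segmentation / classification chain on the
#' static (activity-independent) channel and measures, for each
#' activity-channel interval, its best Jaccard overlap with any
#' static-channel interval. Overlap of at least 0.5 counts as confirmed: the
#' level change is present in a fluorophore that cannot report neural
#' activity, so it must be motion. Unconfirmed intervals are candidate
#' population-coactivity events rather than z-shifts.
#'
#' @param static_traces A `"static"`-channel [trace_matrix()] with the same
#'   ROI set and frame count as the activity channel.
#' @param intervals A `subprep_artifacts` tibble from the activity channel.
#' @inheritParams detect_artifacts
#' @return The input intervals with added columns `jaccard` and `confirmed`;
#'   attribute `static_intervals` holds the static-channel detections.
#' @export
verify_with_static_channel <- function(static_traces, intervals,
                                       n_change_points = 4,
                                       min_artifact_duration_s = 2,
                                       deviation_k = 3, detrend = TRUE) {
  stopifnot(inherits(static_traces, "trace_matrix"))
  if (nrow(intervals) == 0) {
    out <- dplyr::mutate(intervals, jaccard = numeric(0), confirmed = logical(0))
    return(out)
  }
  red_iv <- detect_artifacts(static_traces,
    n_change_points = n_change_points,
    min_artifact_duration_s = min_artifact_duration_s,
    deviation_k = deviation_k, detrend = detrend
  )
  jac <- vapply(seq_len(nrow(intervals)), function(i) {
    if (nrow(red_iv) == 0) return(0)
    max(vapply(seq_len(nrow(red_iv)), function(j) {
      interval_jaccard(
        intervals$start_frame[i], intervals$end_frame[i],
        red_iv$start_frame[j], red_iv$end_frame[j]
      )
    }, numeric(1)))
  }, numeric(1))
  out <- dplyr::mutate(intervals, jaccard = jac, confirmed = jac >= 0.5)
  attr(out, "static_intervals") <- red_iv
  out
}

interval_jaccard <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  union <- (a1 - a0) + (b1 - b0) - inter
  if (union <= 0) 0 else inter / union
}

#' Remove or split on artifact intervals
#'
#' `mode = "drop"` removes the flagged frames from every ROI, leaving a single
#' shorter matrix — appropriate for brief shifts after which the FOV returns
#' to the original plane. `mode = "split"` instead returns the contiguous
#' unflagged stretches as independent matrices — appropriate when the FOV
#' settles in a new z-plane and the two epochs sample different structures.
#' Either way an attribute `frame_map` records, for every kept frame, its
#' index in the original recording.
#'
#' @param traces A [trace_matrix()].
#' @param intervals A `subprep_artifacts` tibble (may have zero rows).
#' @param mode `"drop"` or `"split"`.
#' @return For `"drop"`, one [trace_matrix()]; for `"split"`, a list of them.
#' @export
apply_artifact_mask <- function(traces, intervals, mode = c("drop", "split")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traces, "trace_matrix"))
  nfr <- n_frames(traces)
  flagged <- rep(FALSE, nfr)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start_frame[i]
    e <- intervals$end_frame[i]
    if (s < 1 || e > nfr + 1 || e <= s) abort("Invalid interval for this matrix.")
    flagged[s:(e - 1)] <- TRUE
  }
  if (all(flagged)) abort("Artifact intervals cover every frame; nothing left.")
  if (mode == "drop") {
    keep <- which(!flagged)
    out <- tm_like(unclass(traces)[, keep, drop = FALSE], traces)
    attr(out, "frame_map") <- keep
    return(out)
  }
  r <- rle(!flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep_runs <- which(r$values)
  lapply(keep_runs, function(k) {
    idx <- starts[k]:ends[k]
    out <- tm_like(unclass(traces)[, idx, drop = FALSE], traces)
    attr(out, "frame_map") <- idx
    out
  })
}

#' @export
glance.subprep_artifacts <- function(x, ...) {
  tibble(
    n_intervals = nrow(x),
    frames_flagged = sum(x$end_frame - x$start_frame),
    seconds_flagged = sum(x$end_s - x$start_s),
    explained_variance_ratio =
      attr(x, "explained_variance_ratio") %||% NA_real_
  )
}

#' @export
tidy.subprep_artifacts <- function(x, ...) as_tibble(x)
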