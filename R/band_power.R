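#' One-sided normalized power spectrum of a single trace
#'
#' Computes the periodogram of a detrended trace and normalizes it to unit
#' total power over the positive-frequency bins, so spectra are comparable
#' across traces, sessions and animals. The DC bin is excluded by
#' construction (the trend, including the mean, is removed before the
#' transform); by default a linear trend is removed as well, because slow
#' photobleaching otherwise leaks low-frequency power into the denominator of
#' every band-power ratio.
#'
#' @param trace Numeric vector (one ROI's trace, typically smoothed).
#' @param frame_rate_hz Sampling rate in Hz.
#' @param detrend `"linear"` (default) removes an ordinary least-squares line;
#'   `"constant"` removes only the mean.
#' @return A tibble with columns `freq_hz` (strictly increasing, in
#'   `(0, Nyquist]`) and `power` (non-negative, summing to 1).
#' @export
power_spectrum <- function(trace, frame_rate_hz,
                           detrend = c("linear", "constant")) {
  detrend <- match.arg(detrend)
  n <- length(trace)
  if (n < 16) abort("Need at least 16 frames for a power spectrum.")
  if (!all(is.finite(trace))) abort("Trace contains non-finite values.")
  x <- detrend_series(trace, detrend)
  p <- Mod(fft(x))^2
  k <- seq_len(floor(n / 2)) # positive-frequency bins
  pw <- p[k + 1]
  tot <- sum(pw)
  if (tot <= n * 1e-24 * max(1, mean(trace)^2)) {
    abort("Degenerate signal: no power left after detrending (constant trace?).")
  }
  tibble(freq_hz = k * frame_rate_hz / n, power = pw / tot)
}

detrend_series <- function(x, detrend = "linear") {
  if (detrend == "linear") {
    t <- seq_along(x)
    stats::lm.fit(cbind(1, t), x)$residuals
  } else {
    x - mean(x)
  }
}

#' Fraction of spectral power inside a frequency band
#'
#' The ROI-selection statistic: power of the detrended trace summed over
#' periodogram bins whose centre frequency lies inside `band`, divided by the
#' total power over all positive-frequency bins. Bounded in \[0, 1\] by
#' construction.
#'
#' @inheritParams power_spectrum
#' @param band Numeric length-2, band edges in Hz (default the GCaMP6s axon
#'   transient band 0.03-0.13 Hz).
#' @return A single fraction in \[0, 1\].
#' @export
normalized_band_power <- function(trace, frame_rate_hz, band = c(0.03, 0.13),
                                  detrend = c("linear", "constant")) {
  band <- frequency_band(band[1], band[2], frame_rate_hz)
  ps <- power_spectrum(trace, frame_rate_hz, detrend = match.arg(detrend))
  sum(ps$power[ps$freq_hz >= band[1] & ps$freq_hz <= band[2]])
}

#' Estimate the transient frequency band from exemplar ROIs
#'
#' Compares the mean spectrum of a few hand-picked exemplar ROIs with clear
#' transients against the mean spectrum of the whole population (mostly noise
#' ROIs). Bins where the exemplar mean exceeds `(1 + margin)` times the
#' population mean are "elevated"; the longest contiguous elevated run of at
#' least `min_bins` bins becomes the band of interest (ties broken toward
#' lower frequency, where transient power lives).
#'
#' Raw periodograms of sparse-event traces are spiky (each bin has ~100%
#' relative variance), so the two mean spectra are smoothed with a short
#' moving average before the comparison; otherwise a single dip bin splits
#' an elevated run in two.
#'
#' @param example_spectra,population_spectra Lists of spectra from
#'   [power_spectrum()], all on a common frequency grid.
#' @param margin Relative elevation required (default 0.5, i.e. 1.5x).
#' @param min_bins Minimum run length in bins (default 3).
#' @param smooth_bins Moving-average width (odd, in bins) applied to both
#'   mean spectra before comparison; 1 disables (default 9).
#' @return A named numeric vector `c(low_hz, high_hz)`.
#' @export
estimate_band_of_interest <- function(example_spectra, population_spectra,
                                      margin = 0.5, min_bins = 3,
                                      smooth_bins = 9) {
  stopifnot(length(example_spectra) >= 1, length(population_spectra) >= 1)
  grid <- example_spectra[[1]]$freq_hz
  all_sp <- c(example_spectra, population_spectra)
  same <- vapply(all_sp, function(s) {
    length(s$freq_hz) == length(grid) && all(abs(s$freq_hz - grid) < 1e-9)
  }, logical(1))
  if (!all(same)) abort("All spectra must share a common frequency grid.")
  mean_ex <- rowMeans(vapply(example_spectra, `[[`, numeric(length(grid)), "power"))
  mean_pop <- rowMeans(vapply(population_spectra, `[[`, numeric(length(grid)), "power"))
  if (smooth_bins > 1) {
    box <- rep(1 / smooth_bins, smooth_bins)
    sm <- function(p) {
      as.numeric(stats::filter(p, box, sides = 2)) |>
        (\(v) ifelse(is.na(v), p, v))()
    }
    mean_ex <- sm(mean_ex)
    mean_pop <- sm(mean_pop)
  }
  elevated <- mean_ex > (1 + margin) * mean_pop
  r <- rle(elevated)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= min_bins)
  if (length(ok) == 0) {
    abort(paste(
      "No contiguous elevated frequency run found; the exemplars do not",
      "stand out from the population. Enter the band manually."
    ))
  }
  best <- ok[which.max(r$lengths[ok])] # which.max takes the first (lowest-f) tie
  c(low_hz = grid[starts[best]], high_hz = grid[ends[best]])
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a third-order (by default) Butterworth low-pass at the upper band
#' edge, then a high-pass at the lower edge, each run forward and backward
#' (`filtfilt`) so the net phase response is zero and transient timing is
#' preserved. The low-pass removes frame noise; the high-pass removes slow
#' drift such as bleaching and z-plane creep.
#'
#' @param trace Numeric vector.
#' @param band Numeric length-2 band edges in Hz.
#' @param frame_rate_hz Sampling rate in Hz.
#' @param order Filter order (default 3).
#' @return Filtered numeric vector, same length as the input.
#' @export
bandpass_filter <- function(trace, band = c(0.03, 0.13), frame_rate_hz,
                            order = 3) {
  band <- frequency_band(band[1], band[2], frame_rate_hz)
  minlen <- 9 * (order + 1)
  if (length(trace) <= minlen) {
    abort(sprintf(
      "Trace too short for stable forward-backward filtering (need > %d frames).",
      minlen
    ))
  }
  ny <- frame_rate_hz / 2
  lp <- signal::butter(order, band[2] / ny, type = "low")
  hp <- signal::butter(order, band[1] / ny, type = "high")
  out <- filtfilt_zi(lp$b, lp$a, trace)
  filtfilt_zi(hp$b, hp$a, out)
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initial conditions, so constant inputs produce their exact
# steady-state response and edge transients are suppressed.
filtfilt_zi <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nf <- max(length(a), length(b))
  n <- length(x)
  pad <- 3 * nf
  if (n <= pad) abort("Trace too short for forward-backward filtering.")
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- .iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(.iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

# Initial filter state that makes the step response start at steady state
# (the standard construction via the companion-matrix linear system).
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, numeric(nf - length(a)))
  b <- c(b, numeric(nf - length(b)))
  comp <- matrix(0, nf - 1, nf - 1)
  comp[1, ] <- -a[-1] / a[1]
  if (nf > 2) comp[cbind(2:(nf - 1), 1:(nf - 2))] <- 1
  iminus_a <- diag(nf - 1) - t(comp)
  rhs <- b[-1] - a[-1] * b[1]
  solve(iminus_a, rhs)
}

#' Per-ROI normalized band power
#'
#' Vectorized over a [trace_matrix()]; typically applied to smoothed traces.
#'
#' @param traces A [trace_matrix()], usually from [smooth_traces()].
#' @inheritParams normalized_band_power
#' @return A tibble with columns `roi_id` and `normalized_power`.
#' @export
band_power <- function(traces, band = c(0.03, 0.13),
                       detrend = c("linear", "constant")) {
  stopifnot(inherits(traces, "trace_matrix"))
  detrend <- match.arg(detrend)
  p <- apply(unclass(traces), 1, normalized_band_power,
    frame_rate_hz = frame_rate(traces), band = band, detrend = detrend
  )
  tibble(roi_id = roi_ids(traces), normalized_power = unname(p))
}

#' Select ROIs whose band power exceeds a threshold
#'
#' An ROI is selected iff its normalized band power strictly exceeds
#' `threshold` ("exceeded" in the decision rule; boundary values are
#' discarded). Selection is therefore monotone: raising the threshold can
#' only shrink the selected set, trading yield for signal-to-noise.
#'
#' @param powers A tibble with columns `roi_id` and `normalized_power` (from
#'   [band_power()]), or a bare numeric vector of powers.
#' @param threshold Selection threshold in (0, 1); default 0.3.
#' @return A `subprep_selection` tibble with columns `roi_id`,
#'   `normalized_power`, `selected`.
#' @export
#' @examples
#' select_rois(c(black = 0.454, green = 0.182), threshold = 0.3)
select_rois <- function(powers, threshold = 0.3) {
  if (!(threshold > 0 && threshold < 1)) abort("`threshold` must be in (0, 1).")
  if (is.numeric(powers)) {
    ids <- names(powers) %||% paste0("roi_", seq_along(powers))
    powers <- tibble(roi_id = ids, normalized_power = unname(powers))
  }
  stopifnot(all(c("roi_id", "normalized_power") %in% names(powers)))
  if (any(powers$normalized_power < 0 | powers$normalized_power > 1)) {
    abort("Normalized powers must lie in [0, 1].")
  }
  out <- dplyr::mutate(powers, selected = .data$normalized_power > threshold)
  structure(out,
    threshold = threshold,
    class = c("subprep_selection", class(tibble())))
}

#' Smooth, score and select ROIs in one call
#'
#' Convenience wrapper for the first two pipeline stages: Savitzky-Golay
#' smoothing, per-ROI normalized band power, threshold selection.
#'
#' @inheritParams smooth_traces
#' @inheritParams band_power
#' @inheritParams select_rois
#' @param smooth If `TRUE` (default), smooth before the spectral analysis.
#' @return A `subprep_selection` tibble (see [select_rois()]).
#' @export
select_by_band_power <- function(traces, band = c(0.03, 0.13), threshold = 0.3,
                                 smooth = TRUE, window_frames = 15,
                                 polyorder = 3) {
  if (smooth) traces <- smooth_traces(traces, window_frames, polyorder)
  select_rois(band_power(traces, band = band), threshold = threshold)
}

#' @export
glance.subprep_selection <- function(x, ...) {
  tibble(
    n_rois = nrow(x), n_selected = sum(x$selected),
    threshold = attr(x, "threshold"),
    median_power_selected = median(x$normalized_power[x$selected]),
    median_power_discarded = median(x$normalized_power[!x$selected])
  )
}

#' @export
tidy.subprep_selection <- function(x, ...) as_tibble(x)
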