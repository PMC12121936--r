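fs <- 15.49

test_that("rolling percentile equals the brute-force windowed percentile", {
  set.seed(14)
  for (case in list(
    list(x = rnorm(800, 100, 5), w = 20, p = 8),
    list(x = cumsum(rnorm(500)), w = 10, p = 8),
    list(x = rnorm(300), w = 5, p = 50)
  )) {
    got <- rolling_percentile_baseline(case$x, fs, case$w, case$p)
    want <- brute_percentile_baseline(case$x, fs, case$w, case$p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("baseline tracks constants, ignores sparse transients, follows drift", {
  n <- 2000
  expect_equal(
    rolling_percentile_baseline(rep(7, n), fs),
    rep(7, n)
  )
  # constant + sparse positive transients occupying < 8% of each window
  x <- rep(10, n)
  for (s in seq(100, 1900, by = 400)) x[s:(s + 10)] <- 25
  bl <- rolling_percentile_baseline(x, fs)
  expect_equal(bl, rep(10, n), tolerance = 1e-9)
  # slow linear drift: baseline follows within one window of lag
  a <- 0.01
  drift <- a * seq_len(n)
  bl2 <- rolling_percentile_baseline(drift, fs)
  wf <- round(20 * fs)
  expect_lte(max(abs(bl2 - drift)), a * wf)
  expect_error(rolling_percentile_baseline(rnorm(100), fs, window_s = 20), "exceeds")
})

test_that("dF/F identities and planted-amplitude recovery", {
  f0 <- rep(100, 1000)
  expect_equal(compute_dff(f0, f0), rep(0, 1000))
  expect_equal(compute_dff(2 * f0, f0), rep(1, 1000))
  expect_error(compute_dff(f0, rep(-1, 1000)), "non-positive")
  # planted transient amplitude in dF/F comes back within 2%
  x <- make_transient_trace(2000, peak_frame = 1000, amp = 0.5, fs = fs)
  bl <- rolling_percentile_baseline(x, fs)
  dff <- compute_dff(x, bl)
  expect_equal(max(dff), 0.5, tolerance = 0.02)
  # subtract-only mode returns the raw numerator
  expect_equal(compute_dff(2 * f0, f0, subtract_only = TRUE), f0)
})

test_that("peak detection applies all three gates", {
  # a clean 0.5 dF/F transient ~2 s wide -> exactly one peak
  x <- make_transient_trace(1500, 700, 0.5, fs = fs)
  dff <- compute_dff(x, rolling_percentile_baseline(x, fs))
  pk <- detect_peaks(dff, fs)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$peak_frame - 700), 2)
  expect_gte(pk$width_s, 0.5)
  # amplitude gate: 0.11 misses the 0.12 bar
  x2 <- make_transient_trace(1500, 700, 0.11, fs = fs)
  dff2 <- compute_dff(x2, rolling_percentile_baseline(x2, fs))
  expect_equal(nrow(detect_peaks(dff2, fs)), 0)
  # duration gate: a tall single-frame spike fails
  spike <- numeric(1000)
  spike[500] <- 1.0
  expect_equal(nrow(detect_peaks(spike, fs)), 0)
})

test_that("no reported peak ever violates a gate (random traces)", {
  set.seed(15)
  min_w <- ceiling(0.5 * fs)
  for (i in 1:200) {
    x <- cumsum(rnorm(400, 0, 0.05))
    x <- x - min(x)
    pk <- detect_peaks(x, fs)
    if (nrow(pk) > 0) {
      expect_true(all(pk$amplitude >= 0.12))
      expect_true(all(pk$prominence >= 0.1))
      expect_true(all(pk$width_s * fs >= min_w))
    }
  }
})

test_that("peak prominence and width agree with a direct evaluation", {
  # hand-checkable double-peak profile
  x <- c(0, 1, 3, 1, 0.5, 2, 0.5, 0)
  pr <- subprep:::peak_prominences(x, c(3L, 6L))
  expect_equal(pr$prominence, c(3, 1.5))
  expect_equal(pr$left_base, c(1L, 5L))
  wd <- subprep:::peak_widths(x, c(3L, 6L), pr)
  # peak 1: ref 1.5 -> crossings interpolated between (2,3) and (3,4)
  expect_equal(wd$width_frames[1], (3 + 0.75) - (2 + 0.25))
})

test_that("transient masking zeroes everything outside peak extents", {
  dff <- rnorm(200, 0, 0.01)
  pk <- tibble::tibble(
    peak_frame = c(60L, 80L), time_s = 0, amplitude = 0.5, prominence = 0.5,
    width_s = 1, extent_start = c(50L, 85L), extent_end = c(90L, 120L)
  )
  m <- mask_to_transients(dff, pk)
  expect_equal(m[1:49], rep(0, 49))
  expect_equal(m[50:119], dff[50:119]) # union of overlapping extents
  expect_equal(m[120:200], rep(0, 81))
  expect_equal(mask_to_transients(dff, pk[0, ]), rep(0, 200))
})

test_that("planted events are detected; pure noise yields almost no peaks", {
  set.seed(16)
  detected <- 0
  total <- 0
  for (i in 1:10) {
    n <- 3000
    peaks_at <- seq(300, 2700, by = 400)
    x <- 100 + rnorm(n, 0, 3) # noise sd 0.03 * F0
    k <- transient_kernel(0.2, 1.5, fs)
    for (p in peaks_at) {
      onset <- p - which.max(k) + 1
      L <- min(length(k), n - onset + 1)
      x[onset:(onset + L - 1)] <- x[onset:(onset + L - 1)] +
        100 * runif(1, 0.3, 0.8) * k[seq_len(L)]
    }
    dff <- compute_dff(x, rolling_percentile_baseline(x, fs))
    pk <- detect_peaks(dff, fs)
    total <- total + length(peaks_at)
    for (p in peaks_at) {
      if (any(abs(pk$peak_frame - p) <= 0.5 * fs)) detected <- detected + 1
    }
  }
  expect_gte(detected / total, 0.9)
  # false peaks on pure noise: <= 0.1 per minute. Detection operates on
  # Savitzky-Golay-preprocessed traces, as in the pipeline.
  minutes <- 0
  false_peaks <- 0
  for (i in 1:10) {
    x <- 100 + rnorm(6000, 0, 3)
    x <- unclass(smooth_traces(trace_matrix(rbind(x), fs)))[1, ]
    dff <- compute_dff(x, rolling_percentile_baseline(x, fs))
    false_peaks <- false_peaks + nrow(detect_peaks(dff, fs))
    minutes <- minutes + 6000 / fs / 60
  }
  expect_lte(false_peaks / minutes, 0.1)
})
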