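fs <- 15.49

test_that("z-scoring gives exact zero mean, unit population sd, affine invariance", {
  tm <- trace_matrix(rbind(c(1, 2, 3)), fs)
  z <- unclass(zscore_traces(tm))[1, ]
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  set.seed(9)
  x <- rnorm(100)
  tm2 <- trace_matrix(rbind(x, 5 * x + 7), fs)
  z2 <- unclass(zscore_traces(tm2))
  expect_equal(z2[1, ], z2[2, ], tolerance = 1e-10)
  expect_equal(rowMeans(z2), c(0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(
    zscore_traces(trace_matrix(rbind(x, rep(1, 100)), fs)),
    "roi_2"
  )
})

test_that("PC1 handles rank-1 and planted-step geometries", {
  set.seed(10)
  x <- rnorm(300)
  two <- zscore_traces(trace_matrix(rbind(x, x + 0), fs))
  pc <- first_principal_component(two)
  expect_equal(pc$explained_variance_ratio, 1, tolerance = 1e-9)
  expect_gte(abs(cor(pc$pc1, x)), 1 - 1e-9)

  anti <- zscore_traces(trace_matrix(rbind(x, -x), fs))
  expect_equal(first_principal_component(anti)$explained_variance_ratio, 1,
    tolerance = 1e-9
  )

  # 60 independent noise ROIs sharing a 4-sd step in frames [1000, 1160)
  n <- 2000
  v <- matrix(rnorm(60 * n), 60)
  v[, 1000:1159] <- v[, 1000:1159] + 4
  pc1 <- first_principal_component(
    zscore_traces(trace_matrix(v, fs))
  )$pc1
  inside <- mean(pc1[1000:1159])
  outside <- pc1[-(1000:1159)]
  expect_gte(abs(inside - mean(outside)), 5 * sd(outside))
})

test_that("bottom-up segmentation matches the exhaustive least-squares scan", {
  set.seed(12)
  # one step
  x <- c(rep(0, 99), rep(5, 201)) + rnorm(300, 0, 0.5)
  bk <- bottomup_segment(x, 1)
  expect_equal(length(bk), 1)
  expect_lte(abs(bk - exhaustive_1bkp(x)), 2)
  # two steps (staircase up-down)
  y <- c(rep(0, 99), rep(5, 100), rep(0, 101)) + rnorm(300, 0, 0.5)
  bk2 <- bottomup_segment(y, 2)
  oracle <- exhaustive_2bkp(y)
  expect_equal(length(bk2), 2)
  expect_true(all(abs(bk2 - oracle) <= 2))
  # count contract on pure noise
  expect_equal(length(bottomup_segment(rnorm(300), 4)), 4)
  expect_error(bottomup_segment(rnorm(5), 1), "too short")
})

test_that("segment classification applies the deviation and duration gates", {
  set.seed(13)
  n <- 3000
  pc1 <- rnorm(n, 0, 0.5)
  lo <- 1500
  hi <- lo + round(10 * fs) # 10 s elevated segment
  scale <- 1.4826 * mad(pc1, constant = 1)
  pc1[lo:(hi - 1)] <- pc1[lo:(hi - 1)] + 6 * scale
  bk <- bottomup_segment(pc1, 4)
  iv <- classify_artifact_segments(pc1, bk, fs)
  expect_equal(nrow(iv), 1)
  expect_gte(
    jaccard_iv(
      c(iv$start_frame, iv$end_frame),
      c(lo, hi)
    ), 0.8
  )
  # flat signal: nothing flagged regardless of breakpoints
  flat <- rnorm(n, 0, 0.5)
  expect_equal(nrow(classify_artifact_segments(flat, bk, fs)), 0)
  # elevated but only 0.5 s: duration gate rejects
  short <- rnorm(n, 0, 0.5)
  s0 <- 1500
  s1 <- s0 + round(0.5 * fs)
  short[s0:s1] <- short[s0:s1] + 10 * scale
  bks <- sort(unique(c(s0, s1 + 1, 800, 2400)))
  expect_equal(nrow(classify_artifact_segments(short, bks, fs)), 0)
})

test_that("planted z-shifts are recovered and clean sessions stay clean", {
  hits <- 0
  fp <- 0
  n_seeds <- 5
  for (seed in 1:n_seeds) {
    zs <- list(list(
      start_s = 120, duration_s = 10, magnitude_sd = 3,
      affected_fraction = 0.8
    ))
    ses <- simulate_session(sim_config(
      n_rois = 60, n_frames = 4000, groups = integer(0),
      z_shift = zs, seed = seed
    ))
    iv <- detect_artifacts(ses$activity)
    truth <- ses$truth$artifact_intervals
    if (nrow(iv) >= 1) {
      j <- max(vapply(seq_len(nrow(iv)), function(i) {
        jaccard_iv(
          c(iv$start_frame[i], iv$end_frame[i]),
          c(truth$start_frame[1], truth$end_frame[1])
        )
      }, numeric(1)))
      if (j >= 0.8) hits <- hits + 1
    }
    clean <- simulate_session(sim_config(
      n_rois = 60, n_frames = 4000, groups = integer(0), seed = seed + 100
    ))
    if (nrow(detect_artifacts(clean$activity)) > 0) fp <- fp + 1
  }
  expect_gte(hits, n_seeds - 1)
  expect_lte(fp, 1)
})

test_that("static channel confirms real shifts and rejects coactivity", {
  zs <- list(list(
    start_s = 120, duration_s = 10, magnitude_sd = 3,
    affected_fraction = 0.8
  ))
  ses <- simulate_session(sim_config(
    n_rois = 60, n_frames = 4000, groups = integer(0), z_shift = zs, seed = 21
  ))
  iv <- detect_artifacts(ses$activity)
  expect_gte(nrow(iv), 1)
  ver <- verify_with_static_channel(ses$static, iv)
  expect_true(all(ver$confirmed))
  expect_true(all(ver$jaccard >= 0.8))

  # synchronous "activity" in the green channel only: static must reject it
  clean <- simulate_session(sim_config(
    n_rois = 60, n_frames = 4000, groups = integer(0), seed = 22
  ))
  act <- unclass(clean$activity)
  s <- round(120 * fs)
  e <- s + round(10 * fs)
  for (i in sample(60, 48)) {
    act[i, s:e] <- act[i, s:e] + 3 * sd(act[i, ]) # coactivation: same sign
  }
  bumped <- trace_matrix(act, fs, roi_ids = roi_ids(clean$activity))
  iv2 <- detect_artifacts(bumped)
  expect_gte(nrow(iv2), 1)
  ver2 <- verify_with_static_channel(clean$static, iv2)
  expect_false(any(ver2$confirmed))

  # empty intervals in, empty report out
  empty <- subprep:::artifact_intervals(
    tibble::tibble(start_frame = integer(0), end_frame = integer(0)), fs
  )
  expect_equal(nrow(verify_with_static_channel(clean$static, empty)), 0)
})

test_that("artifact masking conserves frames in both modes", {
  tm <- trace_matrix(matrix(rnorm(3 * 1000), 3), fs)
  iv <- subprep:::artifact_intervals(
    tibble::tibble(start_frame = 101L, end_frame = 201L), fs
  )
  dropped <- apply_artifact_mask(tm, iv, "drop")
  expect_equal(n_frames(dropped), 900)
  expect_equal(attr(dropped, "frame_map"), c(1:100, 201:1000))
  parts <- apply_artifact_mask(tm, iv, "split")
  expect_equal(vapply(parts, n_frames, integer(1)), c(100L, 800L))
  expect_equal(attr(parts[[2]], "frame_map"), 201:1000)
  expect_equal(
    sum(vapply(parts, n_frames, integer(1))) + (201 - 101),
    n_frames(tm)
  )
  # no intervals: identity
  none <- subprep:::artifact_intervals(
    tibble::tibble(start_frame = integer(0), end_frame = integer(0)), fs
  )
  expect_equal(
    unclass(apply_artifact_mask(tm, none, "drop"))[, ],
    unclass(tm)[, ]
  )
  # full cover is an error
  all_iv <- subprep:::artifact_intervals(
    tibble::tibble(start_frame = 1L, end_frame = 1001L), fs
  )
  expect_error(apply_artifact_mask(tm, all_iv, "drop"), "every frame")
})
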