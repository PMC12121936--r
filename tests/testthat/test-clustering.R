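fs <- 15.49

make_block_corr <- function(sizes, within = 0.95, between = 0.05) {
  n <- sum(sizes)
  r <- matrix(between, n, n)
  at <- 1
  for (s in sizes) {
    r[at:(at + s - 1), at:(at + s - 1)] <- within
    at <- at + s
  }
  diag(r) <- 1
  dimnames(r) <- list(paste0("roi_", 1:n), paste0("roi_", 1:n))
  r
}

test_that("correlation matrix basics and zero-variance routing", {
  set.seed(17)
  x <- rnorm(500)
  tm <- trace_matrix(rbind(x, 2 * x, -x), fs)
  r <- correlation_matrix(tm)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_equal(r, t(r), tolerance = 1e-12)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  # independent noise decorrelates
  tm2 <- trace_matrix(matrix(rnorm(2 * 5000), 2), fs)
  expect_lte(abs(correlation_matrix(tm2)[1, 2]), 0.05)
  # an all-zero (masked, transient-free) ROI becomes a forced singleton
  tm3 <- trace_matrix(rbind(x, rnorm(500), rep(0, 500)), fs)
  expect_warning(r3 <- correlation_matrix(tm3), "singleton")
  expect_equal(nrow(r3), 2)
  expect_equal(attr(r3, "forced_singletons"), "roi_3")
})

test_that("maximum-correlation prefilter splits candidates from singletons", {
  r <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.1, 0.1, 0.1, 1), 3)
  dimnames(r) <- list(letters[1:3], letters[1:3])
  attr(r, "forced_singletons") <- character(0)
  pf <- prefilter_singletons(r, 0.8)
  expect_setequal(pf$candidates, c("a", "b"))
  expect_equal(pf$singletons, "c")
  # all below threshold: everyone a singleton
  r2 <- r
  r2[r2 == 0.9] <- 0.5
  expect_equal(length(prefilter_singletons(r2, 0.8)$candidates), 0)
  # all perfectly correlated: all candidates
  r3 <- matrix(1, 3, 3)
  dimnames(r3) <- dimnames(r)
  expect_equal(length(prefilter_singletons(r3, 0.8)$candidates), 3)
})

test_that("both clustering methods recover a planted two-block structure", {
  r <- make_block_corr(c(4, 4))
  truth_split <- brute_best_2partition(r)
  for (labels in list(
    cluster_hierarchical(r, 2),
    cluster_kmeans(r, 2, seed = 1)
  )) {
    expect_equal(length(unique(labels)), 2)
    # same partition as the exhaustive oracle
    expect_true(
      all(labels[truth_split] == labels[truth_split][1]) &&
        all(labels[!truth_split] == labels[!truth_split][1]) &&
        labels[truth_split][1] != labels[!truth_split][1]
    )
  }
  # k = n: every ROI its own cluster (hierarchical)
  expect_equal(length(unique(cluster_hierarchical(r, 8))), 8)
  expect_error(cluster_hierarchical(r, 1), "k")
  expect_error(cluster_kmeans(r, 9), "k")
})

test_that("k-means is deterministic given a seed and survives degeneracy", {
  r <- make_block_corr(c(5, 5), within = 0.8, between = 0.2)
  l1 <- cluster_kmeans(r, 3, seed = 7)
  l2 <- cluster_kmeans(r, 3, seed = 7)
  expect_identical(l1, l2)
  # identical correlation profiles: a single effective cluster, no error
  rid <- matrix(0.5, 4, 4)
  diag(rid) <- 1
  # all rows of a compound-symmetric matrix differ only via the diagonal;
  # build truly identical rows instead
  rows <- matrix(rep(c(1, 1, 1, 1), 4), 4, byrow = TRUE)
  dimnames(rows) <- list(letters[1:4], letters[1:4])
  expect_silent(lab <- cluster_kmeans(rows, 2, seed = 1))
  expect_equal(length(unique(lab)), 1)
})

test_that("silhouette matches the hand calculation and its limits", {
  # two tight blocks, far apart: near-perfect score
  r <- make_block_corr(c(3, 3), within = 0.999, between = 0.1)
  lab <- rep(1:2, each = 3)
  expect_gte(silhouette_score(r, lab), 0.85)
  # 4-point toy dissimilarity checked against the definition
  set.seed(18)
  r4 <- matrix(runif(16, -0.2, 0.9), 4)
  r4 <- (r4 + t(r4)) / 2
  diag(r4) <- 1
  lab4 <- c(1, 1, 2, 2)
  expect_equal(
    silhouette_score(r4, lab4),
    brute_silhouette(1 - r4, lab4),
    tolerance = 1e-12
  )
  # random labels on a structureless matrix hover near zero
  set.seed(19)
  vals <- replicate(40, {
    m <- matrix(rnorm(12 * 500), 12)
    rr <- cor(t(m))
    silhouette_score(rr, sample(1:2, 12, replace = TRUE))
  })
  expect_lte(abs(mean(vals)), 0.1)
  expect_error(silhouette_score(r4, rep(1, 4)), "single cluster")
})

test_that("AMI is 1 for identical or relabeled partitions, ~0 for random", {
  a <- rep(1:4, each = 10)
  expect_equal(ami_score(a, a), 1)
  relab <- c(4, 3, 2, 1)[a] # permuted cluster ids
  expect_equal(ami_score(a, relab), 1)
  set.seed(20)
  vals <- replicate(100, {
    ami_score(
      sample(1:5, 200, replace = TRUE),
      sample(1:5, 200, replace = TRUE)
    )
  })
  expect_lte(abs(mean(vals)), 0.02)
  expect_error(
    ami_score(c(a = 1, b = 2), c(a = 1, c = 2)),
    "different ROI sets"
  )
})

test_that("K-scan finds the planted k and warns on structureless input", {
  r <- make_block_corr(rep(4, 5)) # 5 groups of 4
  truth <- setNames(rep(1:5, each = 4), rownames(r))
  ks <- scan_k(r, truth = truth, seed = 1)
  expect_equal(ks$best$k, c(5, 5), ignore_attr = TRUE)
  expect_true(all(ks$best$k_agrees))
  at5 <- dplyr::filter(ks$scores, k == 5)
  expect_equal(at5$ami, c(1, 1))
  # n_candidates = 4: the scan is the single value k = 2
  r4 <- make_block_corr(c(2, 2))
  ks4 <- scan_k(r4, method = "hierarchical")
  expect_equal(unique(ks4$scores$k), 2)
  # structureless matrix: low silhouette and an explicit warning
  set.seed(23)
  noise <- cor(t(matrix(rnorm(12 * 2000), 12)))
  dimnames(noise) <- list(paste0("r", 1:12), paste0("r", 1:12))
  expect_warning(ksn <- scan_k(noise, method = "hierarchical"), "weak")
  expect_lte(max(ksn$scores$silhouette), 0.25)
})

test_that("ground-truth grouping requires consistency across environments", {
  ra <- make_block_corr(c(2, 1), within = 0.9, between = 0.3)
  rb <- ra
  gt <- ground_truth_groups(ra, rb)
  expect_equal(gt$group[1], gt$group[2])
  expect_false(gt$group[3] == gt$group[1])
  # high in one environment only: NOT the same axon
  rb2 <- make_block_corr(c(2, 1), within = 0.3, between = 0.3)
  gt2 <- ground_truth_groups(ra, rb2)
  expect_equal(length(unique(gt2$group)), 3)
  # chain i-j, j-k above threshold, i-k below: one connected component
  r3 <- matrix(c(
    1, 0.8, 0.2,
    0.8, 1, 0.8,
    0.2, 0.8, 1
  ), 3)
  dimnames(r3) <- list(letters[1:3], letters[1:3])
  gt3 <- ground_truth_groups(r3, r3)
  expect_equal(length(unique(gt3$group)), 1)
  expect_error(
    ground_truth_groups(r3, make_block_corr(c(2, 2))),
    "same ROI set"
  )
})

test_that("dual-environment sessions: exact recovery and metric agreement", {
  for (G in c(3, 5)) {
    cfg_a <- sim_config(
      n_rois = 4 * G, n_frames = 3000, fraction_noise_rois = 0,
      groups = rep(4L, G), noise_sd = 0.03, seed = 30 + G
    )
    cfg_b <- cfg_a
    cfg_b$seed <- 60 + G
    ses_a <- simulate_session(cfg_a)
    ses_b <- simulate_session(cfg_b)
    ma <- extract_transients(ses_a$activity)$masked_dff
    mb <- extract_transients(ses_b$activity)$masked_dff
    ra <- correlation_matrix(ma)
    rb <- correlation_matrix(mb)
    gt <- ground_truth_groups(ra, rb)
    planted <- ses_a$truth$roi_info$group[
      match(gt$roi_id, ses_a$truth$roi_info$roi_id)
    ]
    expect_equal(ami_score(gt$group, planted), 1)
    truth <- setNames(planted, gt$roi_id)
    ks <- scan_k(ra, truth = truth, seed = 1)
    expect_equal(ks$best$k, c(G, G), ignore_attr = TRUE)
    expect_true(all(ks$best$k_agrees))
    at <- dplyr::filter(ks$scores, k == G)
    expect_equal(at$ami, c(1, 1))
  }
})

test_that("cluster_rois partitions every ROI exactly once", {
  ses <- simulate_session(sim_config(
    n_rois = 40, n_frames = 3000, fraction_noise_rois = 0.5,
    groups = rep(4L, 4), seed = 41
  ))
  tr <- extract_transients(ses$activity)
  suppressWarnings(cl <- cluster_rois(tr$masked_dff))
  expect_equal(sort(cl$groups$roi_id), sort(roi_ids(ses$activity)))
  expect_equal(anyDuplicated(cl$groups$roi_id), 0)
  expect_equal(
    sum(!cl$groups$is_singleton) + length(cl$singletons),
    n_rois(ses$activity)
  )
})
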