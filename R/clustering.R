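#' Pairwise zero-lag correlation matrix of ROI traces
#'
#' Pearson correlation at zero lag between every pair of ROI traces
#' (normally the transient-masked dF/F, so correlations reflect shared
#' transients rather than shared noise or drift). ROIs with zero temporal
#' variance — e.g. masked traces with no detected transient — cannot be
#' correlated and are excluded from the matrix; they are reported via the
#' `forced_singletons` attribute and treated as singleton groups downstream.
#'
#' @param traces A [trace_matrix()] (or plain numeric matrix, ROIs x frames).
#' @return A symmetric correlation matrix with ROI ids as dimnames and
#'   attribute `forced_singletons` (character, possibly empty).
#' @export
correlation_matrix <- function(traces) {
  v <- if (inherits(traces, "trace_matrix")) unclass(traces) else traces
  if (nrow(v) < 2) abort("Need at least 2 ROIs to correlate.")
  ids <- rownames(v) %||% paste0("roi_", seq_len(nrow(v)))
  s <- apply(v, 1, sd)
  dead <- which(s == 0)
  if (length(dead) > 0) {
    warn(sprintf(
      "%d zero-variance ROI(s) excluded from the correlation matrix (forced singletons): %s",
      length(dead), paste(head(ids[dead], 5), collapse = ", ")
    ))
    v <- v[-dead, , drop = FALSE]
    ids <- ids[-dead]
  }
  if (nrow(v) < 2) abort("Fewer than 2 ROIs with nonzero variance.")
  r <- cor(t(v))
  dimnames(r) <- list(ids, ids)
  attr(r, "forced_singletons") <- if (length(dead)) {
    rownames(traces)[dead] %||% character(0)
  } else {
    character(0)
  }
  r
}

#' Split ROIs into clustering candidates and singletons
#'
#' An ROI whose maximum correlation with any other ROI exceeds `prefilter_r`
#' is likely one of several fragments of the same axon and enters the
#' clustering stage; all others are kept as singleton groups. This maximum-
#' correlation prefilter keeps obviously independent ROIs from distorting the
#' K-scan.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param prefilter_r Threshold on the maximum off-diagonal correlation
#'   (default 0.8).
#' @return A list with character vectors `candidates` and `singletons`.
#' @export
prefilter_singletons <- function(corr, prefilter_r = 0.8) {
  if (!(prefilter_r > -1 && prefilter_r < 1)) {
    abort("`prefilter_r` must be in (-1, 1).")
  }
  m <- corr
  diag(m) <- -Inf
  mx <- apply(m, 1, max)
  ids <- rownames(corr)
  list(
    candidates = ids[mx > prefilter_r],
    singletons = c(ids[mx <= prefilter_r], attr(corr, "forced_singletons"))
  )
}

#' Agglomerative clustering of ROIs at a fixed k
#'
#' Hierarchical clustering on the dissimilarity `1 - r`, cut to `k` clusters.
#'
#' @param corr Correlation (sub)matrix over candidate ROIs.
#' @param k Number of clusters, `2 <= k <= nrow(corr)`.
#' @param linkage Linkage criterion (default `"average"`).
#' @return Integer cluster labels named by ROI id.
#' @export
cluster_hierarchical <- function(corr, k, linkage = "average") {
  if (k < 2 || k > nrow(corr)) abort("`k` must be in [2, n_candidates].")
  hc <- hclust(as.dist(1 - corr), method = linkage)
  cutree(hc, k = k)
}

#' k-means clustering of ROI correlation profiles
#'
#' Each ROI's feature vector is its row of the correlation matrix (its
#' correlation profile against every other candidate), and k-means minimizes
#' within-cluster sum of squares over those profiles. Runs `nstart` seeded
#' restarts with k-means++ initial centers (distance-squared-weighted
#' seeding, which avoids the empty-cluster and split-cluster failures of
#' uniform random starts at larger k) and keeps the best inertia; results
#' are deterministic given `seed`. Degenerate geometries (fewer distinct
#' profiles than `k`) fall back to the distinct-profile assignment instead
#' of erroring.
#'
#' @inheritParams cluster_hierarchical
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts (default 10).
#' @return Integer cluster labels named by ROI id.
#' @export
cluster_kmeans <- function(corr, k, seed = 1, nstart = 10) {
  if (k < 2 || k > nrow(corr)) abort("`k` must be in [2, n_candidates].")
  x <- unname(corr)
  n_distinct <- nrow(unique(round(x, 12)))
  if (n_distinct < k) {
    # fewer distinct profiles than clusters: one label per distinct profile
    key <- apply(round(x, 12), 1, paste, collapse = ",")
    labels <- as.integer(factor(key, levels = unique(key)))
    return(setNames(labels, rownames(corr)))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(nstart)) {
    fit <- tryCatch(
      suppressWarnings(
        kmeans(x, centers = kmeanspp_centers(x, k), iter.max = 100)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
  }
  if (is.null(best)) abort("k-means failed on every restart.")
  setNames(as.integer(best$cluster), rownames(corr))
}

# k-means++ seeding: each next center is drawn with probability proportional
# to the squared distance from the nearest center chosen so far.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    idx[j] <- if (sum(d2) <= 0) {
      sample.int(n, 1)
    } else {
      sample.int(n, 1, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums(
      (x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2
    ))
  }
  x[idx, , drop = FALSE] + 0 # drop names; duplicates handled by caller
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Mean silhouette score of a clustering
#'
#' Mean silhouette width over all ROIs with dissimilarity `1 - r`, the same
#' dissimilarity used by the hierarchical method, so scores are comparable
#' across clustering methods. Ranges over \[-1, 1\]; higher is better.
#'
#' @param corr Correlation (sub)matrix.
#' @param labels Cluster labels (any type coercible to a factor).
#' @return Mean silhouette width.
#' @export
silhouette_score <- function(corr, labels) {
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2) {
    abort("Silhouette is undefined for a single cluster.")
  }
  sil <- cluster::silhouette(cl, dist = as.dist(1 - corr))
  mean(sil[, "sil_width"])
}

#' Adjusted Mutual Information between two partitions
#'
#' Mutual information between the two labelings, corrected for chance under
#' the permutation model (expected MI for random partitions with the same
#' group sizes) and normalized by the arithmetic mean of the two entropies.
#' Identical partitions score 1 regardless of label naming; independent
#' random partitions score ~0.
#'
#' @param labels,truth_labels Two labelings of the same items, aligned by
#'   position (or by name when both are named).
#' @return AMI score (a value <= 1; can be slightly negative by chance).
#' @export
ami_score <- function(labels, truth_labels) {
  if (!is.null(names(labels)) && !is.null(names(truth_labels))) {
    if (!setequal(names(labels), names(truth_labels))) {
      abort("`labels` and `truth_labels` cover different ROI sets.")
    }
    truth_labels <- truth_labels[names(labels)]
  }
  if (length(labels) != length(truth_labels)) {
    abort("`labels` and `truth_labels` must have the same length.")
  }
  u <- as.integer(factor(labels))
  v <- as.integer(factor(truth_labels))
  n <- length(u)
  tab <- table(u, v)
  a <- rowSums(tab)
  b <- colSums(tab)
  hu <- entropy_counts(a, n)
  hv <- entropy_counts(b, n)
  if (hu == 0 && hv == 0) return(1.0) # both trivial partitions, identical
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
    }
  }
  emi <- expected_mi(a, b, n)
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < 1e-15) return(0)
  unname((mi - emi) / denom)
}

entropy_counts <- function(cnt, n) {
  p <- cnt[cnt > 0] / n
  -sum(p * log(p))
}

# Expected mutual information under the hypergeometric permutation model.
expected_mi <- function(a, b, n) {
  emi <- 0
  lg <- lgamma
  for (i in seq_along(a)) {
    ai <- a[i]
    for (j in seq_along(b)) {
      bj <- b[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lg(ai + 1) + lg(bj + 1) + lg(n - ai + 1) + lg(n - bj + 1) -
          lg(n + 1) - lg(nij + 1) - lg(ai - nij + 1) - lg(bj - nij + 1) -
          lg(n - ai - bj + nij + 1)
        emi <- emi + exp(lp) * nij / n * log(n * nij / (ai * bj))
      }
    }
  }
  emi
}

#' Scan cluster counts and pick the best-supported k
#'
#' Clusters the candidate ROIs for every `k` from `k_min` to
#' `floor(k_max_fraction * n_candidates)` with the requested method(s),
#' scoring each solution by mean silhouette (and by AMI against `truth` when
#' a ground-truth partition is available). The chosen `k` per method
#' maximizes the silhouette; when truth is supplied the result also records
#' the argmax-AMI `k` and whether the two criteria agree — if they do,
#' silhouette alone is a trustworthy model-selection signal for datasets
#' without ground truth.
#'
#' @param corr Correlation (sub)matrix over candidate ROIs (n >= 4).
#' @param k_min Smallest k (default 2).
#' @param k_max_fraction Largest k as a fraction of candidates (default 0.5).
#' @param method `"both"` (default), `"hierarchical"` or `"kmeans"`.
#' @param linkage Linkage for the hierarchical method.
#' @param seed Seed for k-means restarts.
#' @param truth Optional named ground-truth labels covering the candidates.
#' @return A `subprep_kscan` object: list with `scores` (tibble: k, method,
#'   silhouette, ami), `best` (tibble per method: chosen k, scores,
#'   `k_agrees` when truth given) and `labels` (list of label vectors at the
#'   chosen k per method).
#' @export
scan_k <- function(corr, k_min = 2, k_max_fraction = 0.5,
                   method = c("both", "hierarchical", "kmeans"),
                   linkage = "average", seed = 1, truth = NULL) {
  method <- match.arg(method)
  n <- nrow(corr)
  if (n < 4) abort("Need at least 4 candidate ROIs to scan k.")
  k_max <- max(k_min, floor(k_max_fraction * n))
  if (k_max < k_min) abort("Empty k range.")
  methods <- if (method == "both") c("hierarchical", "kmeans") else method
  rows <- list()
  all_labels <- list()
  for (m in methods) {
    for (k in k_min:k_max) {
      labels <- if (m == "hierarchical") {
        cluster_hierarchical(corr, k, linkage)
      } else {
        cluster_kmeans(corr, k, seed = seed)
      }
      sil <- if (length(unique(labels)) < 2) {
        NA_real_
      } else {
        silhouette_score(corr, labels)
      }
      ami <- if (is.null(truth)) {
        NA_real_
      } else {
        ami_score(labels, truth[rownames(corr)])
      }
      rows[[length(rows) + 1]] <- tibble(
        k = k, method = m, silhouette = sil, ami = ami
      )
      all_labels[[paste(m, k)]] <- labels
    }
  }
  scores <- dplyr::bind_rows(rows)
  if (max(scores$silhouette, na.rm = TRUE) < 0.25) {
    warn(paste(
      "Maximum silhouette < 0.25: the correlation structure gives weak",
      "support for any grouping; treat cluster labels with caution."
    ))
  }
  best <- scores |>
    dplyr::group_by(.data$method) |>
    dplyr::slice_max(.data$silhouette, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (!is.null(truth)) {
    best_ami <- scores |>
      dplyr::group_by(.data$method) |>
      dplyr::slice_max(.data$ami, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(method, k_ami = "k")
    best <- dplyr::left_join(best, best_ami, by = "method") |>
      dplyr::mutate(k_agrees = .data$k == .data$k_ami)
  }
  chosen <- setNames(
    lapply(seq_len(nrow(best)), function(i) {
      all_labels[[paste(best$method[i], best$k[i])]]
    }),
    best$method
  )
  structure(list(scores = scores, best = best, labels = chosen),
    class = "subprep_kscan"
  )
}

#' @export
print.subprep_kscan <- function(x, ...) {
  cat("<subprep_kscan>\n")
  print(x$best)
  invisible(x)
}

#' @export
tidy.subprep_kscan <- function(x, ...) x$scores

#' @export
glance.subprep_kscan <- function(x, ...) x$best

#' Group ROIs by clustering their transient correlations
#'
#' The full grouping stage: correlation matrix, maximum-correlation
#' prefilter, K-scan on the candidates, and assembly of a final partition in
#' which every selected ROI appears exactly once — either in a cluster or as
#' a singleton.
#'
#' @param traces A [trace_matrix()] of transient-masked dF/F (recommended;
#'   see [extract_transients()]) or any ROI x frame matrix.
#' @inheritParams prefilter_singletons
#' @inheritParams scan_k
#' @return A `subprep_clusters` object: list with `groups` (tibble: roi_id,
#'   group, is_singleton), `kscan` (the [scan_k()] result, or NULL if too few
#'   candidates), `singletons`, `method` and `k`.
#' @export
cluster_rois <- function(traces, prefilter_r = 0.8, k_min = 2,
                         k_max_fraction = 0.5,
                         method = c("both", "hierarchical", "kmeans"),
                         linkage = "average", seed = 1, truth = NULL) {
  method <- match.arg(method)
  corr <- correlation_matrix(traces)
  pf <- prefilter_singletons(corr, prefilter_r)
  kscan <- NULL
  labels <- integer(0)
  used_method <- method
  if (length(pf$candidates) >= 4 &&
      floor(k_max_fraction * length(pf$candidates)) >= k_min) {
    sub <- corr[pf$candidates, pf$candidates, drop = FALSE]
    kscan <- scan_k(sub,
      k_min = k_min, k_max_fraction = k_max_fraction,
      method = method, linkage = linkage, seed = seed, truth = truth
    )
    used_method <- kscan$best$method[which.max(kscan$best$silhouette)]
    labels <- kscan$labels[[used_method]]
  } else if (length(pf$candidates) > 0) {
    warn("Too few clustering candidates; all ROIs kept as singletons.")
    pf$singletons <- c(pf$candidates, pf$singletons)
    pf$candidates <- character(0)
  }
  groups <- dplyr::bind_rows(
    tibble(
      roi_id = names(labels),
      group = paste0("cluster_", labels),
      is_singleton = FALSE
    ),
    tibble(
      roi_id = pf$singletons,
      group = paste0("singleton_", seq_along(pf$singletons)),
      is_singleton = TRUE
    )
  )
  structure(
    list(
      groups = groups, kscan = kscan, singletons = pf$singletons,
      method = used_method,
      k = if (length(labels)) length(unique(labels)) else 0L
    ),
    class = "subprep_clusters"
  )
}

#' @export
print.subprep_clusters <- function(x, ...) {
  cat(sprintf(
    "<subprep_clusters> %d ROIs: %d clustered into k = %d groups (%s), %d singletons\n",
    nrow(x$groups), sum(!x$groups$is_singleton), x$k, x$method,
    length(x$singletons)
  ))
  invisible(x)
}

#' @export
tidy.subprep_clusters <- function(x, ...) x$groups

#' @export
glance.subprep_clusters <- function(x, ...) {
  tibble(
    n_rois = nrow(x$groups), n_clustered = sum(!x$groups$is_singleton),
    n_singletons = length(x$singletons), k = x$k, method = x$method,
    silhouette = if (is.null(x$kscan)) {
      NA_real_
    } else {
      max(x$kscan$best$silhouette)
    }
  )
}

#' Ground-truth axon groups from paired-environment correlations
#'
#' ROIs from the same axon must co-fire wherever the animal is, while
#' distinct neurons that happen to co-fire in one environment are very
#' unlikely to also co-fire in a second one (hippocampal remapping). A pair
#' is therefore linked iff its correlation exceeds `threshold` in *both*
#' environments, and groups are the connected components of the resulting
#' graph (the only partition-consistent reading of pairwise links);
#' unlinked ROIs form singleton groups.
#'
#' @param corr_env_a,corr_env_b Correlation matrices over the same ROI set,
#'   one per environment.
#' @param threshold Per-environment correlation threshold (default 0.7).
#' @return A tibble with columns `roi_id` and `group` (integer component id).
#' @export
ground_truth_groups <- function(corr_env_a, corr_env_b, threshold = 0.7) {
  ids <- rownames(corr_env_a)
  if (!identical(dim(corr_env_a), dim(corr_env_b)) ||
      !setequal(ids, rownames(corr_env_b))) {
    abort("The two environments must cover the same ROI set.")
  }
  b <- corr_env_b[ids, ids]
  adj <- (corr_env_a > threshold) & (b > threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  tibble(roi_id = ids, group = as.integer(comp[ids]))
}
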