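# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity and avoid the code paths
# they are checking.

# Periodogram band-power fraction via an explicit DFT sum (no fft()).
brute_band_power <- function(x, fs, lo, hi, detrend = "linear") {
  n <- length(x)
  t <- seq_len(n)
  x <- if (detrend == "linear") {
    stats::residuals(stats::lm(x ~ t))
  } else {
    x - mean(x)
  }
  ks <- seq_len(floor(n / 2))
  pw <- vapply(ks, function(k) {
    w <- 2 * pi * k * (t - 1) / n
    sum(x * cos(w))^2 + sum(x * sin(w))^2
  }, numeric(1))
  f <- ks * fs / n
  sum(pw[f >= lo & f <= hi]) / sum(pw)
}

# Windowed percentile baseline, frame by frame.
brute_percentile_baseline <- function(x, fs, window_s, pct) {
  wf <- max(3L, as.integer(round(window_s * fs)))
  half <- wf %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    unname(quantile(x[lo:hi], pct / 100, type = 7))
  }, numeric(1))
}

# Exhaustive least-squares scan for 1 or 2 breakpoints (half-open convention:
# a breakpoint b means segments [.., b) and [b, ..)).
sse_of <- function(x) sum((x - mean(x))^2)
exhaustive_1bkp <- function(x) {
  n <- length(x)
  costs <- vapply(2:n, function(b) sse_of(x[1:(b - 1)]) + sse_of(x[b:n]),
    numeric(1)
  )
  (2:n)[which.min(costs)]
}
exhaustive_2bkp <- function(x) {
  n <- length(x)
  best <- c(NA, NA)
  best_cost <- Inf
  for (b1 in 2:(n - 1)) {
    c1 <- sse_of(x[1:(b1 - 1)])
    for (b2 in (b1 + 1):n) {
      cost <- c1 + sse_of(x[b1:(b2 - 1)]) + sse_of(x[b2:n])
      if (cost < best_cost) {
        best_cost <- cost
        best <- c(b1, b2)
      }
    }
  }
  best
}

# Exhaustive best 2-partition of a correlation matrix by within-minus-between
# mean correlation.
brute_best_2partition <- function(corr) {
  n <- nrow(corr)
  best <- NULL
  best_score <- -Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (sum(grp) == 0 || sum(grp) == n) next
    w <- c(corr[grp, grp][lower.tri(corr[grp, grp])],
           corr[!grp, !grp][lower.tri(corr[!grp, !grp])])
    b <- corr[grp, !grp]
    score <- mean(w) - mean(b)
    if (is.nan(score)) next
    if (score > best_score) {
      best_score <- score
      best <- grp
    }
  }
  best
}

# Direct silhouette evaluation from the definition.
brute_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# A clean isolated calcium transient on a flat trace.
make_transient_trace <- function(n, peak_frame, amp, fs = 15.49,
                                 tau_rise = 0.2, tau_decay = 1.5,
                                 noise_sd = 0, f0 = 100) {
  k <- transient_kernel(tau_rise, tau_decay, fs)
  onset <- peak_frame - which.max(k) + 1
  dff <- numeric(n)
  L <- min(length(k), n - onset + 1)
  dff[onset:(onset + L - 1)] <- amp * k[seq_len(L)]
  f0 * (1 + dff) + rnorm(n, 0, noise_sd * f0)
}

# Jaccard overlap between two half-open frame intervals.
jaccard_iv <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  inter / ((a[2] - a[1]) + (b[2] - b[1]) - inter)
}
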