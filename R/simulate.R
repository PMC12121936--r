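#' Canonical calcium transient kernel
#'
#' Double-exponential impulse response `k(t) = (1 - exp(-t/tau_rise)) *
#' exp(-t/tau_decay)`, normalized to unit peak and truncated once it falls
#' below 1% of the peak. The defaults (0.2 s rise, 1.5 s decay) model a slow
#' indicator such as GCaMP6s: the rise lives in a faster frequency band than
#' the decay, and together they concentrate the spectral power of transient
#' activity at low frequencies.
#'
#' @param tau_rise_s Rise time constant in seconds (must be < `tau_decay_s`).
#' @param tau_decay_s Decay time constant in seconds.
#' @param frame_rate_hz Sampling rate in Hz.
#' @return Numeric kernel sampled at the frame rate, unit peak.
#' @export
transient_kernel <- function(tau_rise_s = 0.2, tau_decay_s = 1.5,
                             frame_rate_hz = 15.49) {
  if (!(tau_rise_s > 0 && tau_decay_s > 0 && tau_rise_s < tau_decay_s)) {
    abort("Need 0 < tau_rise_s < tau_decay_s.")
  }
  # generous horizon, then truncate at 1% of peak
  t <- seq(0, 20 * tau_decay_s, by = 1 / frame_rate_hz)
  k <- (1 - exp(-t / tau_rise_s)) * exp(-t / tau_decay_s)
  k <- k / max(k)
  last <- max(which(k >= 0.01))
  k[seq_len(last)]
}

#' Configuration for a synthetic imaging session
#'
#' Defaults emulate the recording regime the pipeline targets: a resonant-
#' scanned FOV at 15.49 Hz, ~10 minutes long, in which the vast majority
#' (90%) of Suite2P ROIs carry only noise and slow bleaching, active ROIs
#' fire sparse GCaMP6s-like transients (Poisson events at 0.03 /s,
#' log-normal amplitudes around 0.5 dF/F), axon fragments from the same cell
#' share an event train up to a per-fragment gain, and an occasional z-plane
#' shift steps many ROIs synchronously in random directions on both
#' channels.
#'
#' @param n_rois Total ROI count (default 200).
#' @param n_frames Session length in frames (default 9000, ~9.7 min).
#' @param frame_rate_hz Frame rate in Hz (default 15.49).
#' @param fraction_noise_rois Fraction of ROIs with no events (default 0.9).
#' @param event_rate_hz Poisson event rate per active unit (default 0.03).
#' @param tau_rise_s,tau_decay_s Kernel time constants (defaults 0.2, 1.5).
#' @param amplitude_mean_dff,amplitude_sd_dff Mean and sd of the log-normal
#'   event amplitude distribution in dF/F units (defaults 0.5, 0.2).
#' @param noise_sd Gaussian noise sd in dF/F units (default 0.03; applied as
#'   `noise_sd * F0` in fluorescence units).
#' @param bleach_tau_s Multiplicative exponential bleaching time constant in
#'   seconds (default 1800).
#' @param z_shift List of z-shift artifact specs, each a list/vector with
#'   `start_s`, `duration_s`, `magnitude_sd` (step height in units of the
#'   per-ROI trace sd) and `affected_fraction`. Default: none (a stable
#'   FOV); pass e.g. `list(list(start_s = 300, duration_s = 10,
#'   magnitude_sd = 3, affected_fraction = 0.8))` to plant one.
#' @param groups Integer vector of axon-group sizes among the active ROIs
#'   (default five groups of four). Must sum to at most the active count.
#' @param gain_range Per-member gain range within a group (default 0.5-1.5).
#' @param f0_range Range of baseline fluorescence F0 (default 80-120 a.u.).
#' @param seed Integer seed; the session is fully reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_rois = 200, n_frames = 9000, frame_rate_hz = 15.49,
                       fraction_noise_rois = 0.9, event_rate_hz = 0.03,
                       tau_rise_s = 0.2, tau_decay_s = 1.5,
                       amplitude_mean_dff = 0.5, amplitude_sd_dff = 0.2,
                       noise_sd = 0.03, bleach_tau_s = 1800,
                       z_shift = list(),
                       groups = rep(4L, 5), gain_range = c(0.5, 1.5),
                       f0_range = c(80, 120), seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$fraction_noise_rois >= 0, cfg$fraction_noise_rois <= 1,
    cfg$tau_rise_s > 0, cfg$tau_decay_s > 0, cfg$bleach_tau_s > 0,
    cfg$event_rate_hz >= 0, cfg$noise_sd >= 0
  )
  n_active <- round(cfg$n_rois * (1 - cfg$fraction_noise_rois))
  if (sum(cfg$groups) > n_active) {
    abort(sprintf(
      "Group sizes sum to %d but only %d ROIs are active.",
      sum(cfg$groups), n_active
    ))
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-channel session with planted ground truth
#'
#' Generates an activity channel, a static channel and the complete planted
#' truth needed to score every pipeline stage. Active ROI fluorescence is
#' `F0 * (1 + sum_i a_i k(t - t_i)) * bleach(t) + noise`; group members share
#' one Poisson event train (times and amplitudes) scaled by a per-member
#' gain; noise ROIs omit the event sum. Each z-shift adds, to both channels
#' of each affected ROI, a step over the shift interval whose height is the
#' configured magnitude (in units of that ROI's pre-artifact sd) scaled by
#' Uniform(0.5, 1.5) with a random sign — synchronous in time, heterogeneous
#' in direction, as a real z-plane shift is. The static channel is otherwise
#' flat F0 plus noise.
#'
#' @param config A [sim_config()].
#' @return A list with `activity` and `static` ([trace_matrix()]) and
#'   `truth`: a list with `roi_info` (tibble: roi_id, is_active, group),
#'   `events` (named list of event tibbles with `frame` and `amplitude`),
#'   `artifact_intervals` (tibble, 1-based half-open frames) and `f0`.
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_rois
  nf <- config$n_frames
  fs <- config$frame_rate_hz
  n_active <- round(n * (1 - config$fraction_noise_rois))
  kern <- transient_kernel(config$tau_rise_s, config$tau_decay_s, fs)
  # group membership: first the grouped actives, then solo actives, then noise
  group_of <- rep(NA_integer_, n)
  gi <- 1L
  for (g in seq_along(config$groups)) {
    sz <- config$groups[g]
    if (sz > 0) group_of[gi:(gi + sz - 1)] <- g
    gi <- gi + sz
  }
  is_active <- seq_len(n) <= n_active
  ids <- paste0("roi_", seq_len(n))
  f0 <- runif(n, config$f0_range[1], config$f0_range[2])
  f0_red <- runif(n, config$f0_range[1], config$f0_range[2])
  tvec <- (seq_len(nf) - 1) / fs
  bleach <- exp(-tvec / config$bleach_tau_s)
  # log-normal amplitude parameters from mean/sd
  cv2 <- (config$amplitude_sd_dff / config$amplitude_mean_dff)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(config$amplitude_mean_dff) - sdlog^2 / 2
  # one event train per group, one per solo active ROI
  n_units <- length(config$groups) + (n_active - sum(config$groups))
  unit_of <- ifelse(is.na(group_of), NA_integer_, group_of)
  solo <- which(is_active & is.na(group_of))
  unit_of[solo] <- length(config$groups) + seq_along(solo)
  trains <- lapply(seq_len(max(n_units, 0)), function(u) {
    ev <- which(runif(nf) < config$event_rate_hz / fs)
    tibble(frame = ev, amplitude = rlnorm(length(ev), meanlog, sdlog))
  })
  act <- matrix(0, n, nf)
  red <- matrix(0, n, nf)
  events <- setNames(vector("list", n), ids)
  gains <- rep(1, n)
  for (i in seq_len(n)) {
    dff_sum <- numeric(nf)
    if (is_active[i]) {
      tr <- trains[[unit_of[i]]]
      gains[i] <- if (!is.na(group_of[i])) {
        runif(1, config$gain_range[1], config$gain_range[2])
      } else {
        1
      }
      for (e in seq_len(nrow(tr))) {
        s <- tr$frame[e]
        L <- min(length(kern), nf - s + 1)
        dff_sum[s:(s + L - 1)] <- dff_sum[s:(s + L - 1)] +
          gains[i] * tr$amplitude[e] * kern[seq_len(L)]
      }
      events[[i]] <- dplyr::mutate(tr, amplitude = .data$amplitude * gains[i])
    } else {
      events[[i]] <- tibble(frame = integer(0), amplitude = numeric(0))
    }
    act[i, ] <- f0[i] * (1 + dff_sum) * bleach +
      rnorm(nf, 0, config$noise_sd * f0[i])
    red[i, ] <- f0_red[i] + rnorm(nf, 0, config$noise_sd * f0_red[i])
  }
  # z-shift artifacts: synchronous steps, random per-ROI sign and scale
  art <- tibble(start_frame = integer(0), end_frame = integer(0))
  for (zs in config$z_shift) {
    zs <- as.list(zs)
    s <- as.integer(round(zs$start_s * fs)) + 1L
    e <- min(nf + 1L, s + as.integer(round(zs$duration_s * fs)))
    if (s >= e || s > nf) next
    hit <- sort(sample(n, round(zs$affected_fraction * n)))
    for (i in hit) {
      sgn <- sample(c(-1, 1), 1)
      sc <- runif(1, 0.5, 1.5)
      act[i, s:(e - 1)] <- act[i, s:(e - 1)] +
        sgn * sc * zs$magnitude_sd * sd(act[i, ])
      red[i, s:(e - 1)] <- red[i, s:(e - 1)] +
        sgn * sc * zs$magnitude_sd * sd(red[i, ])
    }
    art <- dplyr::bind_rows(art, tibble(start_frame = s, end_frame = e))
  }
  list(
    activity = trace_matrix(act, fs, roi_ids = ids, channel = "activity"),
    static = trace_matrix(red, fs, roi_ids = ids, channel = "static"),
    truth = list(
      roi_info = tibble(
        roi_id = ids, is_active = is_active,
        group = group_of, gain = gains
      ),
      events = events,
      artifact_intervals = art,
      f0 = setNames(f0, ids)
    )
  )
}
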