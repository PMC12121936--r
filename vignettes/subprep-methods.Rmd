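---
title: "Preprocessing subcellular calcium imaging traces: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessing subcellular calcium imaging traces: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(subprep)
```

## The problem

Two-photon calcium imaging of axons and dendrites produces fluorescence
traces that are much harder to work with than somatic recordings. Subcellular
ROIs are small and dim, so the vast majority of ROIs emitted by upstream
segmentation (Suite2P or similar) — typically around 85–95% — contain nothing
but shot noise and slow photobleaching. The thin, branched structures drift
in and out of the imaging plane, so a small movement along the optical axis
(a *z-shift*) abruptly changes which structures are being sampled and steps
many traces up or down at once. And because one axon fragments into many
ROIs, independent-looking traces may all report the same neuron.

`subprep` addresses these problems in sequence, starting from extracted
traces (an ROIs × frames matrix plus the frame rate; the package performs no
image registration and no ROI segmentation):

1. **Smoothing** — Savitzky–Golay filtering of each trace.
2. **Selection** — keep ROIs whose spectral power is concentrated in the
   frequency band characteristic of calcium transients.
3. **Motion artifacts** — find synchronous level shifts with PCA and
   bottom-up change-point segmentation; drop or split on them.
4. **Transients** — rolling-percentile baseline to ΔF/F, then peak detection
   with amplitude, duration and prominence gates.
5. **Clustering** — group ROIs whose transient-masked ΔF/F traces correlate,
   choosing the number of groups by silhouette (and AMI when ground truth
   exists).

Every stage is an ordinary function on a `trace_matrix`; `run_pipeline()`
chains them and writes per-stage tables plus a deterministic JSON manifest.

## Frequency-band ROI selection

A GCaMP6s transient has a fast rise (~0.2 s) and a slow decay (>1 s), and
events arrive sparsely; the resulting spectral signature of an active trace
is power concentrated at low frequencies, in a band that a pure-noise trace
cannot imitate. The selection statistic is the *normalized band power*

$$
P_{band} = \frac{\sum_{f \in [f_{lo}, f_{hi}]} |X(f)|^2}
                {\sum_{f > 0} |X(f)|^2},
$$

the fraction of the periodogram of the (detrended, smoothed) trace that
falls inside the band — bounded in [0, 1] and hence comparable across ROIs,
sessions and animals. The default band is 0.03–0.13 Hz and the default
threshold 0.3, with strict inequality: an ROI at exactly the threshold is
discarded. Selection is monotone in the threshold, so raising it trades
yield for signal-to-noise.

Two numerical choices matter here:

* **Detrending.** The DC bin must be excluded (the mean is physically
  arbitrary), and we go one step further and remove a least-squares line
  before the transform. In-session photobleaching is approximately linear
  over ~10 minutes, and its spectral leakage otherwise inflates the
  denominator of $P_{band}$ enough to drag genuinely active ROIs below
  threshold. `detrend = "constant"` restores plain mean subtraction.
* **Total power from the unfiltered spectrum.** The denominator uses the
  same (unfiltered) periodogram as the numerator, which is what bounds the
  ratio by 1. A zero-phase Butterworth bandpass (`bandpass_filter()`, 3rd
  order, low-pass at the upper edge then high-pass at the lower edge, each
  run forward and backward) is provided for trace conditioning and
  visualization, but the selection statistic itself is spectral.

The band can be estimated from data with `estimate_band_of_interest()`:
bins where the mean spectrum of a few exemplar ROIs (clear transients, high
SNR) exceeds 1.5× the population mean spectrum are "elevated", and the
longest contiguous elevated run of ≥ 3 bins wins, ties going to the lower
frequencies. Because raw periodogram bins of sparse-event traces have ~100%
relative variance, both mean spectra are smoothed with a short moving
average (9 bins by default) before the comparison. The band depends on the
indicator and the structure being imaged — faster indicators or dendrites
shift it — so it should be re-estimated per dataset.

Note one honest caveat about the zero-phase property: forward–backward
filtering has exactly zero *phase* response, so a symmetric pulse keeps its
peak frame exactly (this is what the tests assert). An asymmetric pulse such
as the GCaMP kernel additionally gets reshaped by the *magnitude* response
of the narrow band — its mode moves toward its centroid — which no zero-phase
implementation avoids. Peak timing for quantitative use should be read from
the ΔF/F traces, not from the bandpassed ones.

## Motion artifact detection

A z-shift moves many ROIs at the same frames but in ROI-specific directions
and amounts. After z-scoring each trace (population SD), frames become
comparable across ROIs, and the shift becomes the dominant shared variance:
the first principal component — computed with frames as observations, so it
is itself a time series — shows a sustained level change over the shift
period.

Change points are found with bottom-up segmentation: the series is cut into
2-frame atoms and adjacent segments are greedily merged, always the pair
whose merge increases the total within-segment sum of squared errors the
least, until the user-specified number of interior breakpoints remains. The
number of change points is deliberately a user input; the guidance is to
over-specify (default 4) and let the classifier reject spurious segments.

Segments are classified by an explicit rule (the quantitative stand-in for
by-eye review): a segment is an artifact candidate iff

* its median deviates from the baseline median by more than `deviation_k`
  (default 3) robust scale units (1.4826 × MAD), with baseline statistics
  re-estimated over unflagged segments in a second pass, **and**
* it lasts at least `min_artifact_duration_s` (default 2 s) — population
  coactivity is brief (a second or two), a plane shift persists.

Two additions proved necessary beyond that rule:

* **Per-ROI linear detrending before z-scoring** (`detrend = TRUE`).
  Bleaching is coherent across the whole FOV; without detrending the first
  PC *is* the bleach ramp (explained variance ~0.7 in simulations at
  τ = 1800 s) and segmentation describes the ramp, not the shift.
* **Population-synchrony validation** (`validate_synchrony()`, default on).
  A large transient in a dominant axon group drives PC1 as hard as a
  z-shift and outlasts the 2 s gate, so PC1-level rules alone flag
  transient-rich stable sessions. A genuine z-shift, however, moves many
  ROIs individually: a candidate interval is kept only if at least
  `min_affected_fraction` (default 0.25) of ROIs show a sustained median
  shift beyond `deviation_k` times their own robust scale inside it. In
  simulations this takes the false-flag rate on stable transient-rich
  sessions from 14/20 to 0/20 while leaving planted-shift recovery at
  Jaccard ≥ 0.99.

When a static-fluorophore channel (e.g. mRuby) is available,
`verify_with_static_channel()` reruns the whole detection on it and marks
each activity-channel interval confirmed iff it overlaps a static-channel
interval with Jaccard ≥ 0.5. An interval found in the activity channel only
is population coactivity, not motion — `run_pipeline()` therefore removes
only confirmed intervals when verification ran. Flagged frames are either
dropped (`mode = "drop"`) or the session is split into stable epochs
(`mode = "split"`), each carrying a `frame_map` back to original frame
numbers. Frame indices are 1-based and all intervals half-open
`[start, end)`, so interval lengths are differences and kept + flagged
frames always sum to the session length.

Within-frame or rhythmic (breathing, heartbeat) motion is out of scope: the
method targets rare, abrupt, FOV-wide shifts from a stable baseline.

## Baseline correction and transient detection

The baseline F0 at each frame is the 8th percentile of the fluorescence in a
centred ~20 s window (truncated at the session edges — reflection would
fabricate data). Transients are sparse and positive, so a low percentile
tracks bleaching and slow drift while ignoring events;
ΔF/F = (F − F0)/max(F0, ε) with ε defaulting to 1% of the trace median
(floor 1e−6). The text description of this step is subtractive, but the
quantity is named ΔF/F, so division is the default; `subtract_only = TRUE`
gives the strict subtractive reading. The rolling percentile is implemented
in C++ (sorted sliding window, R type-7 quantile) and agrees with the
brute-force windowed percentile exactly at every frame.

Peaks must pass all three gates: amplitude ≥ 0.12 ΔF/F, width at
half-prominence ≥ 0.5 s (⌈0.5 · f_s⌉ frames — "duration" is interpreted as
the standard half-prominence width), prominence ≥ 0.1 ΔF/F. Amplitude is
absolute post-correction ΔF/F height. Each accepted peak's *extent* is its
prominence base interval clipped at the first frame on either side where
ΔF/F dips below zero, which keeps long shallow shoulders out of the
transient. Everything outside the union of extents is set exactly to zero
(`mask_to_transients()`), so downstream correlations see only significant
transients. Detection operates on the Savitzky–Golay-smoothed traces, as in
the pipeline; on raw unsmoothed noise the false-peak rate roughly doubles.

## Clustering ROIs into putative axons

Correlations are zero-lag Pearson correlations between transient-masked
ΔF/F traces (a flag allows raw ΔF/F). ROIs whose maximum correlation with
any other ROI does not exceed `prefilter_r = 0.8` are kept as singletons;
the rest are clustered with both hierarchical clustering (average linkage on
1 − r; linkage configurable) and k-means on correlation-matrix rows
(k-means++ seeding, 10 restarts, best inertia, deterministic given the
seed). `scan_k()` scans k from 2 to 50% of the candidate count and picks the
k maximizing the mean silhouette on 1 − r — the same dissimilarity for both
methods, so scores are comparable. If the maximum silhouette is below 0.25
the scan warns that the data do not support grouping.

Ground truth, when two environments were recorded, links a pair iff its
correlation exceeds 0.7 in *both* environments (place-field remapping makes
consistent cross-environment co-firing of distinct cells very unlikely);
groups are the connected components of that graph — the only
partition-consistent reading of pairwise links, which means a chain a–b–c
can group a and c without a direct a–c link. AMI (adjusted mutual
information under the permutation model, arithmetic normalization) compares
partitions; singletons count as their own groups on both sides. The package
implements AMI directly from the expected-MI hypergeometric formula. On
synthetic sessions the argmax-AMI k and the argmax-silhouette k agree, which
is the practical justification for using silhouette alone on datasets
without ground truth.

## The synthetic session generator

`simulate_session()` produces the two-channel regime the pipeline targets,
with complete planted truth. Per active ROI:

$$
F(t) = F_0 \left(1 + \textstyle\sum_i a_i\, k(t - t_i)\right) e^{-t/\tau_b}
       + \varepsilon(t),
$$

with kernel $k(t) = (1 - e^{-t/\tau_r}) e^{-t/\tau_d}$ normalized to unit
peak and truncated at 1% ($\tau_r$ = 0.2 s, $\tau_d$ = 1.5 s: GCaMP6s-like),
Poisson events at 0.03 /s, log-normal amplitudes (mean 0.5, SD 0.2 ΔF/F —
log-normal so the 0.12 gate has a genuine amplitude diversity to filter),
multiplicative bleaching with τ_b = 1800 s, Gaussian noise with SD
0.03 · F0, and F0 uniform in 80–120 a.u. Noise ROIs (90% of the default 200)
omit the event sum. Axon groups share one event train (times and
amplitudes) scaled by a per-member gain in 0.5–1.5. A z-shift adds to both
channels of each affected ROI a step over the interval with height
`magnitude_sd` × that ROI's SD, scaled by Uniform(0.5, 1.5) with random
sign — synchronous in time, heterogeneous in direction. The static channel
is otherwise flat F0 plus noise. Everything is reproducible from one seed.

The defaults describe a stable FOV; artifact studies pass `z_shift`
explicitly. That matters because a 10 s step has its spectral power almost
entirely inside 0.03–0.13 Hz: planting one in every session would push
noise ROIs over the selection threshold, which is a physical fact about
z-shifts, not a flaw in the statistic — selection assumes the FOV is mostly
stable, and the motion stage exists precisely to find the exceptions.

What the generator does *not* emulate: neuropil contamination, correlated
noise between nearby ROIs, nonstationary event rates (behavioural
modulation), indicator saturation, and within-frame motion. Passing tests
on this generator therefore demonstrates the algorithms do what they claim
under the stated model, not that the default thresholds are optimal for any
particular real dataset.

## Problem sizes and determinism

The test-suite simulations use 40–200 ROIs and 3000–9000 frames (about
3–10 minutes at 15.49 Hz), 10–20 seeds per property — sizes at which every
property is measured on the same order as a real single-FOV session.
`scripts/acceptance.R` recomputes the headline quantities at the same
scale. All stochastic stages take explicit seeds; `run_pipeline()` writes a
manifest without timestamps so that identical input, config and seed give
byte-identical output.

```{r example, eval = FALSE}
# a minimal session: simulate, run, inspect
zs <- list(list(start_s = 120, duration_s = 10, magnitude_sd = 3,
                affected_fraction = 0.8))
ses <- simulate_session(sim_config(n_rois = 60, n_frames = 4000,
                                   groups = rep(3L, 2), z_shift = zs,
                                   seed = 1))
run <- run_pipeline(ses$activity, ses$static)
glance(run$selection)
tidy(run$artifacts)
glance(run$clusters)
autoplot(run$selection)
```

## Known limitations

* The selection threshold (0.3) and band (0.03–0.13 Hz) are defaults for
  GCaMP6s axons at 15.49 Hz, not universal constants.
* The number of change points remains a user input; an information-criterion
  stopping rule would remove that bias but is not implemented.
* The synchrony validation assumes enough ROIs per FOV (a few dozen) for a
  fraction threshold to be meaningful.
* Clustering is purely activity-based; anatomical evidence (pixel overlap,
  branch geometry) is not used.
* Suite2P input is read from `F.npy`/`F_chan2.npy`/`iscell.npy`; the pickled
  `ops.npy` is not parsed, so the frame rate comes from an `ops.json` (key
  `fs`) or the `frame_rate_hz` argument.
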