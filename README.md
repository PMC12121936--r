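# subprep

Preprocessing for two-photon calcium imaging of **subcellular** structures —
axons and dendrites — starting from the fluorescence traces produced by
upstream segmentation (e.g. Suite2P). Subcellular recordings are dominated
by problems that somatic pipelines can ignore: the large majority of
extracted ROIs (roughly 85–95%) carry only noise and bleaching, small
movements along the optical axis (*z-shifts*) step many traces at once, and
a single axon fragments into several ROIs that all report the same neuron.

`subprep` is for experimenters who already have an ROIs × frames trace
matrix and a frame rate and need, in order:

1. **ROI selection by normalized band power.** Calcium transients (slow
   indicator: ~0.2 s rise, >1 s decay; sparse events) concentrate spectral
   power at low frequencies. For each Savitzky–Golay-smoothed, detrended
   trace the statistic is
   `P_band = Σ_{f∈[0.03,0.13]} |X(f)|² / Σ_{f>0} |X(f)|²`,
   bounded in [0, 1]; ROIs with `P_band > 0.3` (strict) are kept. A
   zero-phase 3rd-order Butterworth bandpass (low-pass 0.13 Hz then
   high-pass 0.03 Hz, forward–backward) is available for conditioning, and
   the band itself can be estimated from exemplar ROIs.
2. **z-shift artifact removal.** Traces are detrended, z-scored and
   projected onto the first principal component (frames as observations, so
   PC1 is a time series); bottom-up change-point segmentation (2-frame
   atoms, squared-error cost, greedy merging to a user-set number of change
   points, default 4) cuts PC1 into segments; a segment is flagged iff its
   median deviates from baseline by > 3 robust scale units **and** lasts
   ≥ 2 s, and then only if ≥ 25% of ROIs individually shift inside it
   (a z-shift moves the population; a big transient moves one axon). A
   static-fluorophore channel, when present, must confirm each interval
   (Jaccard ≥ 0.5) before frames are dropped.
3. **Transient extraction.** Baseline F0 is the rolling 8th percentile of a
   centred ~20 s window; ΔF/F = (F − F0)/F0. Peaks must have amplitude
   ≥ 0.12 ΔF/F, width at half-prominence ≥ 0.5 s and prominence ≥ 0.1 ΔF/F;
   everything outside detected transient extents is set to 0.
4. **ROI grouping.** Zero-lag Pearson correlations of transient-masked
   ΔF/F; ROIs with max correlation ≤ 0.8 stay singletons; the rest are
   clustered by hierarchical (average linkage on 1 − r) and k-means
   (k-means++, 10 restarts) methods with k scanned from 2 to 50% of the
   candidates and chosen by silhouette; AMI scores the result when a
   dual-environment ground truth (pairs with r > 0.7 in both environments,
   connected components) is available.

A synthetic-session generator (`simulate_session()`) plants transients,
axon groups, bleaching, noise ROIs and z-shifts with full ground truth, and
backs the entire test suite.

## Worked example

```r
library(subprep)

# a 60-ROI, ~4.3-minute session: 6 active ROIs in two axon groups of 3,
# 90% noise ROIs, one 10 s z-shift at t = 120 s hitting 80% of the FOV
zs  <- list(list(start_s = 120, duration_s = 10, magnitude_sd = 3,
                 affected_fraction = 0.8))
ses <- simulate_session(sim_config(n_rois = 60, n_frames = 4000,
                                   groups = rep(3L, 2), z_shift = zs,
                                   seed = 1))
ses$activity
#> <trace_matrix> 60 ROIs x 4000 frames @ 15.49 Hz (activity channel, 258.2 s)

run <- run_pipeline(ses$activity, ses$static)

glance(run$selection)
#> # A tibble: 1 × 5
#>   n_rois n_selected threshold median_power_selected median_power_discarded
#> 1     60         46       0.3                 0.361                 0.0932
```

46 of 60 ROIs pass selection — more than the 6 truly active ones, because
the 10 s z-shift itself is in-band power (its step spectrum lives almost
entirely inside 0.03–0.13 Hz). That is exactly why the motion stage comes
next:

```r
tidy(run$artifacts)
#> # A tibble: 1 × 7
#>   start_frame end_frame start_s end_s affected_fraction jaccard confirmed
#> 1        1861      2013    120.  130.             0.978   0.987 TRUE
```

The planted shift (frames 1860–2015 in truth) is recovered almost exactly,
97.8% of ROIs shift inside it, and the static (red) channel confirms it, so
those 152 frames are dropped before ΔF/F. Transient detection then finds
peaks only where they were planted, and clustering recovers the two planted
axon groups:

```r
glance(run$transients)
#> # A tibble: 1 × 5
#>   n_rois n_peaks n_rois_with_peaks peaks_per_min mean_amplitude
#> 1     46      63                 6         0.331          0.564

run$clusters
#> <subprep_clusters> 46 ROIs: 6 clustered into k = 2 groups (hierarchical),
#>   40 singletons
```

The 40 noise ROIs that slipped through selection end as singletons — every
input ROI lands in exactly one of: discarded-by-power, singleton, or
clustered. `autoplot()` methods exist for traces, selection histograms,
PC1-with-intervals, ΔF/F-with-peaks and the K-scan; `tidy()`/`glance()`
return tibbles at every stage. A command-line front end with
`simulate`/`select`/`motion`/`transients`/`cluster`/`run` subcommands is
installed at `exec/subprep`.

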