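# avalanchr

Analysis of two-photon calcium-imaging population activity in the
neuronal-avalanche framework, for researchers studying how local cortical
network dynamics change in disease models and pharmacological
interventions.

Ongoing cortical activity organizes into *neuronal avalanches*:
spatiotemporal clusters of population activity, delimited by silent
frames, whose size distribution near criticality follows
P(s) ∝ s<sup>−τ</sup> with τ ≈ 1.5, whose mean size scales with duration
as ⟨s⟩(T) ∝ T<sup>χ</sup> with χ ≈ 2, and whose *branching parameter*
σ — descendant activity divided by ancestor activity within a cluster —
sits near 1. A subtler, single-neuron phenotype can masquerade as altered
avalanche dynamics: *persistent bursting*, where neurons stay active
across consecutive frames. `avalanchr` implements the full chain needed
to measure and disentangle the two:

- AR(1) deconvolution of ΔF/F traces into spike-rate rasters
  (`deconvolve`), plus the forward model for testing
  (`spikes_to_fluorescence`);
- ISI-preserving surrogate rasters and shuffle-corrected zero-lag
  correlation / event synchronization (`shuffle_raster`,
  `shuffle_correct`, `event_synchronization`);
- avalanche extraction, log-binned size distributions, power-law fits
  (least-squares and MLE) with Kolmogorov–Smirnov distance, and
  size–duration scaling (`extract_clusters`, `size_distribution`,
  `fit_power_law`, `size_duration_scaling`);
- temporal and spatial branching parameters with an exact decomposition
  of downstream activations into **new** vs **repeat** activators
  (`temporal_branching`, `spatial_branching`);
- burst statistics and the persistent-burst-removal intervention
  (`extract_bursts`, `burst_length_stats`, `remove_persistent_bursts`);
- a branching-process raster generator with controlled cascade strength
  and burst persistence (`simulate_branching_raster`, `make_cohort`),
  SAL-like (near-critical cascades) and PCP-like (elevated burst
  persistence) presets;
- normality-gated statistics (Shapiro–Wilk gate, Welch t / rank-sum,
  ANOVA+Tukey / Kruskal–Wallis) and reporting (`compare_two`,
  `compare_multi`, `per_bin_distribution_test`, `report`).

See the vignette (`vignettes/avalanche-dynamics.Rmd`) for the models,
parameter rationales, and numerical choices.

## Worked example

Simulate a two-group cohort, analyze it, and apply the burst-removal
intervention to the PCP-like group:

```r
library(avalanchr)

co <- make_cohort(movies_per_group = 5, seed = 1)
cs <- analyze_cohort(co, analysis_config(n_shuffles = 10))

sal <- cs$summaries[cs$table$group == "SAL"]
pcp <- cs$summaries[cs$table$group == "PCP"]
compare_two(sal, pcp, field = "fraction_multiframe")
#> group_comparison: Welch t, statistic -33.54, p = 5.252e-07 (n = 5/5; normality TRUE/TRUE)
compare_two(sal, pcp, field = "sigma_spatial_repeat")
#> group_comparison: Welch t, statistic -42.01, p = 3.114e-08 (n = 5/5; normality TRUE/TRUE)

rasters <- lapply(co, `[[`, "raster")
grp     <- sapply(co, `[[`, "group")
round(group_avalanche_metrics(rasters[grp == "SAL"]), 3)
#>  fraction_multiframe sigma_spatial_repeat             exponent                  chi
#>                0.061                0.239                1.664                1.225
round(group_avalanche_metrics(rasters[grp == "PCP"]), 3)
#>  fraction_multiframe sigma_spatial_repeat             exponent                  chi
#>                0.255                1.110                1.479                1.273

rem <- lapply(which(grp == "PCP"), function(k)
  remove_persistent_bursts(rasters[[k]], 1/3, seed = 100 + k))
round(group_avalanche_metrics(rem), 3)
#>  fraction_multiframe sigma_spatial_repeat             exponent                  chi
#>                0.170                0.719                1.556                1.258
```

Reading the numbers: the PCP-like group has four times the fraction of
multi-frame bursts (0.255 vs 0.061), an almost fivefold higher repeat
spatial branching (1.110 vs 0.239) with comparable *new* branching (not
shown), a shallower avalanche size distribution (exponent 1.479 vs
1.664), and steeper size–duration scaling (1.273 vs 1.225) — the
persistent-bursting phenotype. Truncating one third of the multi-frame
bursts after their first frame moves every one of these statistics back
toward the SAL-like values, showing that the avalanche-level anomalies are
driven by single-neuron burst persistence rather than altered cascade
propagation.

The generator is also the test bed for the estimators themselves: at
`offspring_mean = 1` (a critical cascade) the pipeline recovers the
mean-field size exponent and scaling exponent:

```r
critical_benchmark(seed = 1)
#> critical_benchmark: 64971 clusters; exponent 1.464 (theory 1.5), chi 1.859 (theory 2), KS 0.0046
```

## File formats

Rasters and ΔF/F traces are exchanged as delimited text (one header line
`# frame_rate=<Hz>`, a frame-index header row, one row per neuron) via
`read_raster`/`write_raster` and `read_traces`/`write_traces`; ROI
centroid maps as CSV (`roi_id,x_um,y_um`) via `read_roi_map`; cluster
tables via `write_cluster_table`; full analysis reports as CSV + JSON via
`report`.
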