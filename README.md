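# slicetrack

Longitudinal 4D single-cell analysis for organotypic slice-culture imaging.

Brain-slice cultures imaged at an air–liquid interface yield weeks-long
5-D datasets (time × channel × z × y × x) in which individual labelled
neurons must be followed, measured and scored for death. `slicetrack`
implements the full analysis chain for such experiments, for lab scientists
and image analysts who need single-cell longitudinal statistics rather than
per-image summaries:

- **imgio** — calibrated OME-style TIFF I/O, maximum z-projection, tile
  stitching with feathered blending, translation alignment by phase
  correlation, and two-colour before/after overlays;
- **segment** — normalised-threshold segmentation (scale `I` by its 99.9th
  percentile, threshold at a fixed fraction of the unit range), 8-connected
  labelling, calibrated size/intensity filters, intensity-weighted
  centroids;
- **track** — proximity-based longitudinal tracking: each object at frame
  *t* inherits the ID of the closest object at frame *t − 1* if their
  centroid distance *d* satisfies *d* ≤ *d*<sub>max</sub> (default
  64.5 µm), and receives a fresh ID otherwise; no gap closing, optional
  one-to-one conflict resolution;
- **quantify** — step distances, path length, net displacement, velocity;
  motility calls (max pairwise separation > 2 soma lengths); intensity,
  cell-count and mean-distance time trends with ANCOVA/ANOVA comparisons;
- **puncta** — inclusion-body analysis inside neuron masks: 8-bit rescale,
  5–255 threshold, ≥ 10 µm² particles, small/large classes split at 80 µm²,
  cumulative accumulation comparisons between groups;
- **survival** — automated death calling from morphology-channel traces
  (drop to background + *k*·σ, or track disappearance), Kaplan–Meier
  curves, Gehan–Breslow–Wilcoxon test (weights = number at risk), Cox
  proportional hazards (Efron ties) with hazard ratio
  HR = exp(β) and Wald CI, Nelson–Aalen cumulative hazard, and a
  constant-hazard (linear cumulative hazard) likelihood-ratio test;
- **simulate** — a seeded generator of ground-truthed synthetic 4D movies,
  detection series, intensity traces, random-walk tracks and survival
  datasets, so every stage is testable without microscope data;
- **pipeline** — one-call orchestration (`run_pipeline()`) plus a thin CLI
  (`inst/scripts/slicetrack`) with `simulate` and `analyze` subcommands.

## Worked example

Simulate a small two-channel movie (4 neurons, 6 daily sessions, two of
which die), run the full pipeline, and inspect the survival bookkeeping:

```r
library(slicetrack)

cfg <- pipeline_config(
  simulate = sim_config(seed = 42, image_shape = c(2L, 224L, 224L),
                        n_timepoints = 6L, n_cells = 4L,
                        death_hazard_per_h = 0.004),
  out_dir = "demo_out", seed = 42)
res <- run_pipeline(cfg, align = FALSE)
res$report
#> $n_timepoints  6
#> $n_detections  21
#> $n_tracks      4
#> $n_events      2
#> $n_censored    2
#> $n_puncta      6
res$survival_records
#>   cell_id group time_h event          call
#> 1       1   all    120     1 disappearance
#> 2       2   all    120     0      censored
#> 3       3   all    120     0      censored
#> 4       4   all     96     1 disappearance
```

Four tracks were recovered; cells 4 and 1 lost their morphology signal
after 96 h and 120 h of observation and were scored as deaths at the first
frame where they were gone, while the two survivors are right-censored at
the last session. `demo_out/` contains the track, feature, puncta and
survival CSVs (each with the seed in its header), a JSON report and a
count-vs-time plot.

Two-group survival analysis on simulated single-cell data (161 control and
180 disease cells, disease hazard 1.9-fold the control's):

```r
rec <- simulate_survival(n_control = 161, n_disease = 180,
                         log_hr = log(1.9),
                         baseline_rate_per_h = -log(0.4) / 336,
                         censor_time_h = 336, frame_interval_h = 0,
                         seed = 42)
cph_fit(rec)
#> <SurvivalFit> HR(disease vs control) = 1.539, 95% CI [1.186, 1.996], Wald p = 0.00118
gbw_test(rec)[c("statistic", "p")]
#> $statistic 9.93
#> $p         0.0016
hazard_linearity(rec)[c("chisq", "p", "weibull_shape")]
#> chisq 0.666, p 0.414, weibull shape 1.05
```

A single replicate estimates the hazard ratio with sampling error (here
1.54 against a generating 1.9, CI excluding 1); averaged over 20 seeds the
estimate centres on the generating value (see below). The
constant-hazard test correctly finds no deviation from linearity for these
exponential event times (shape ≈ 1).

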