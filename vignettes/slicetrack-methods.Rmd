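---
title: "Methods: longitudinal 4D single-cell tracking and survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal 4D single-cell tracking and survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicetrack)
```

## The problem

Organotypic brain-slice cultures can be imaged at an air–liquid interface for
weeks, with automated return to the same field every imaging session
(typically every 24 h). Each session yields a multi-channel confocal z-stack;
over a time course this becomes a 5-D dataset (time × channel × z × y × x).
The scientific questions are longitudinal and single-cell: how does each
neuron's morphology, position and fluorescence change; when does each neuron
die; and how do perturbations (here, a polyglutamine-expanded huntingtin
fragment that forms inclusion bodies) shift the per-cell risk of death.

`slicetrack` implements the full analysis chain for such data — projection,
alignment, segmentation, proximity tracking, quantification, inclusion-body
(puncta) analysis and survival statistics — together with a seeded simulator
that produces ground-truthed synthetic movies, so that every stage can be
validated without access to microscope data.

## Image model and preprocessing

All analysis operates on 2-D maximum-intensity z-projections: each
projection pixel is the maximum over z at that (t, c, y, x). This is
appropriate because labelled cells are sparse in z and the platform's focus
lock keeps the axial position stable; consequently in-plane translation is
the only registration degree of freedom we model. Alignment uses
translation-only phase correlation between consecutive frames, with the
per-frame drift chained cumulatively back to the first timepoint. Rotation
is deliberately not modelled: stage-return jitter in this acquisition regime
is translational, and adding rotation would make the contract harder to test
without improving it.

Tiled acquisitions (e.g. 3 × 3 arrays covering a whole slice) are stitched
with linear feathering in the overlap zones. Feathering was chosen because
it is the simplest blend that is exact whenever the overlapping tiles agree,
which makes the split-and-restitch identity a sharp test.

Physical units are carried on every object: projections know their pixel
size (default 0.3225 × 0.3225 µm in-plane, 0.5 µm z-steps) and timepoint;
coordinates are pixel centres, `(index − 0.5) × pixel size`, with y
increasing downward. No operation drops calibration silently.

### File format

Movies are written as multi-page 16-bit TIFF with planes ordered z-fastest,
then channel, then time, plus an OME-XML companion file holding axis sizes,
voxel size, frame interval and channel names. Sixteen-bit integer storage
matches what cameras produce and round-trips bit-exactly. A plain TIFF
without metadata is read as a single-timepoint, single-channel z-stack with
default calibration and a warning.

## Segmentation

Cells are segmented by *normalised thresholding*: intensities are scaled by
a robust maximum (the 99.9th percentile), clipped to [0, 1], and thresholded
at a fixed fraction (default 0.2) of that range. This makes segmentation
invariant to global intensity rescaling — a property tested directly — and
requires no per-image tuning. An Otsu option exists for comparison.
Connected components use 8-connectivity (diagonal soma pixels belong
together), components outside a calibrated area window are discarded
(default minimum 20 µm², a package default rather than a published value),
and centroids are intensity-weighted so that bright somata dominate dim
neurites. An optional minimum mean intensity filters out low-contrast
components; the pipeline sets it automatically to background mean + 3 SD so
that frames containing no real signal segment to nothing rather than to
noise.

## Tracking

The tracker is deliberately simple and matches the acquisition design: at
the first timepoint every object receives a unique ID; at each subsequent
timepoint, each object searches all previous-frame objects for the closest
centroid (the running "closest distance" starts at the longest image
dimension and is updated whenever a strictly closer object is found, so
exact ties resolve to the lowest previous ID). If the closest distance is
within the hard cutoff — 64.5 µm, the furthest a cell is expected to travel
between 24 h sessions, with the boundary itself linking — the ID is
inherited; otherwise a fresh ID is issued. There is no gap closing, no
motion model and no division linking: a divided cell appears as one
continuing track plus one new ID, and a cell that reappears after a missed
frame starts a new track.

The raw closest-predecessor rule permits two objects to inherit the same ID.
Because duplicated IDs would corrupt single-cell survival bookkeeping, the
default mode enforces one-to-one assignment: competing claims are granted in
ascending distance order and losers receive fresh IDs. The permissive mode
(`one_to_one = FALSE`) is retained and is proven equivalent to an exhaustive
all-pairs nearest-neighbour oracle on random instances up to n = 50.

## Quantification

Per-track kinematics are step distances between consecutive detections, net
first-to-last displacement, path length and mean velocity. A cell is called
*motile* when its maximum centroid separation over all detection pairs
strictly exceeds two soma lengths, where the soma length is the
equivalent-circle diameter of the track's median area — median, because
neurite-driven area fluctuations would otherwise distort the scale. The
motile fraction is an output, not an assumption: rare somal movement is
exactly the kind of event the threshold is meant to flag.

"Mean distance travelled" per timepoint is the mean per-interval step
distance, not the cumulative path: only the former can decline over a time
course, which is the trend of interest. Its time trend is reported in
nm/day, with a one-way ANOVA over timepoints and Tukey HSD pairwise
comparisons. Cumulative tracked-cell counts are regressed on time in days
to give an accumulation rate in cells/day. Intensity trends pool per-cell
mean intensities into one regression and compare the slope against flat
background traces by ANCOVA, implemented as the F-test of the group × time
interaction in a linear model; the same routine serves the puncta module.

## Puncta (inclusion-body) analysis

Neuron masks are segmented from the morphology channel and applied to the
reporter channel, zeroing signal outside neurons. The masked image is
min–max rescaled to 8-bit; pixels in the 5–255 range are foreground;
components of at least 10 µm² (calibrated units; a pixel-unit mode exists)
become puncta. Puncta strictly below 80 µm² are "small", 80 µm² and above
"large" — the boundary is assigned to the large class so the two classes
partition all areas. For cumulative formation counts, a punctum is matched
to one at the previous timepoint when both lie in the same cell within one
soma radius; unmatched puncta are first appearances. Per-slice cumulative
small-puncta series are compared between groups by an endpoint t-test and
by the ANCOVA rate comparison.

Intensity-based inclusion-body calling is out of scope: without
deconvolution, spherical aberration makes intensity an unreliable
discriminator, so only punctate morphology is used.

## Survival analysis

Death is scored from the morphology-channel trace: the first timepoint at
which mean intensity falls to within 3 background SDs of the background
mean, sustained for 2 consecutive frames, marks membrane rupture (abrupt
loss of the freely diffusing marker). A track that vanishes mid-movie with
no spatially proximate successor is likewise scored dead at its first
missing frame; tracks surviving to the end are right-censored at last
observation. Manually scored death times, when supplied, override the
automated calls. Event times are recorded at the first frame where loss is
observed (interval censoring approximated by the right endpoint, the usual
convention on a 24 h grid), measured from the first imaging session.

Group survival is summarised by Kaplan–Meier curves; groups are compared by
the Gehan–Breslow–Wilcoxon test (weighted log-rank with weights equal to the
number at risk, emphasising early deaths) and by Cox proportional-hazards
regression with group as the only covariate and Efron tie handling — daily
sampling creates heavy ties, for which Efron is the less biased standard.
The hazard ratio is reported with a Wald 95% CI.

Whether the death *rate* is constant over time (equivalently, whether the
cumulative hazard is linear) is tested by a likelihood-ratio comparison of
Weibull versus exponential parametric fits: the exponential is the Weibull
with shape fixed at 1, so the statistic is χ² with 1 df under the
constant-hazard null. An alternative sometimes described — adding a
time-transform covariate shared by all subjects to the Cox model — is not
estimable: a covariate that takes the same value for everyone at risk at a
given time cancels out of the partial likelihood. The Weibull-shape test
addresses the same null directly and is calibrated (exponential data are
rarely rejected) and powerful (Weibull shape-2 data are reliably rejected)
in the test suite. Nelson–Aalen cumulative-hazard curves are returned for
visual assessment, and `cox.zph` diagnostics remain available on the
underlying fit object.

## The simulator

The simulator is first-class, tested code, and its defaults are the study
conditions the analysis is designed for: 0.3225 × 0.3225 × 0.5 µm voxels,
24 h frame intervals, ~8 µm soma radius, a 0.7 a.u./h linear intensity
drift in live cells, and death rendered as a hard step to background at the
first frame after the event (an optional fade rate exists, default 0).
Cells are soma disks plus thin neurite strokes blurred by a Gaussian PSF
proxy (σ = 1 px); neurites are rendered at 12% of soma intensity, below the
default segmentation threshold, keeping segmentation soma-centric and the
ground-truth correspondence exact. Somata are placed with at least
2 × radius + 2 µm centre separation (the 2 µm absorbing PSF blur), with 100
retries before an overcrowded configuration is rejected. Arrivals (new
labelled cells) and divisions are Poisson processes; one daughter is
displaced by a soma diameter, a crude proxy for mitotic somal translocation
that creates exactly the linking ambiguity the tracker must resolve. Motile
cells take fixed-length steps in random directions; the motile fraction is
a parameter, because no quantitative motility distribution is established
for the rare moving somata. Event times are exponential, with a disease
group's hazard scaled by a configurable log hazard ratio.

What the simulator does *not* emulate: light scattering and depth
attenuation, neurite graph dynamics, photobleaching, segmentation errors
from touching cells, or z-drift. Passing tests therefore demonstrate that
the algorithms are correct on data satisfying their stated assumptions, not
that those assumptions hold for any particular microscope.

Two lighter generators cover specific analyses without rendering pixels:
`simulate_detection_series()` emits the detection tables perfect
segmentation would produce, `simulate_traces()` emits linear-drift intensity
traces with flat background companions, `simulate_walk_tracks()` emits
random walks whose mean step declines linearly (the migratory-slowdown
scenario), and `simulate_survival()` emits grid-discretised exponential
event times for two groups.

## Problem sizes and numerical choices

The validation suite uses deliberately modest problem sizes chosen to give
statistically meaningful checks quickly: rendered movies of 2 z-slices ×
~200² pixels with 3–5 cells and 5–8 frames; detection-series scenarios with
up to ~700 tracks over 20 daily frames; survival recoveries at the realistic
design (161 + 180 cells, 336 h, 24 h grid) averaged over 20 seeded
replicates. Stochastic recoveries assert the mean over 20 seeds within
10–15% of the generating value, matching the Monte Carlo error at those
sizes. All randomness flows from a single integer seed; identical
configuration and seed give bit-identical movies, tables and pipeline
outputs. Degenerate inputs (all-zero images, empty masks, single-detection
tracks, zero-event survival sets) return empty or flagged results rather
than errors wherever the quantity is well defined as "nothing".

## Known limitations

- Tracking is nearest-neighbour with a hard cutoff; it will swap identities
  if two cells pass within the cutoff of each other's positions between
  frames. This matches the intended acquisition regime (mostly stationary
  somata, 24 h sampling) and is not a general-purpose tracker.
- Death calling assumes the morphology marker's loss is abrupt relative to
  the frame interval; slow fades spanning many frames would be scored at
  the threshold crossing, not at rupture.
- Puncta identity over time is heuristic (same cell, within one soma
  radius); fission/fusion of inclusion bodies is not modelled.
- The ANCOVA and regression routines assume independent errors; per-cell
  longitudinal correlation is not modelled (no mixed-effects option).
- The hazard-linearity test fits continuous parametric models; on event
  times coarsely discretised to a frame grid (interval width comparable to
  the mean event time) the Weibull/exponential comparison absorbs the
  rounding as spurious shape, so it should be applied to times on a scale
  finer than the typical survival time, or read qualitatively alongside the
  Nelson–Aalen curves it returns.
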