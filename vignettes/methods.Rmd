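---
title: "Models and methods behind retinaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retinaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

retinaquant quantifies retinal structure and function from three modalities —
en-face OCT angiography, structural OCT B-scans, and multifocal ERG traces —
and compares the derived metrics across a three-group cohort (control,
diabetes without retinopathy, diabetes with mild retinopathy). This vignette
records the models, the tunable parameters, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## OCTA vessel quantification

An en-face angiogram is a calibrated intensity image of one vascular plexus
(SVP, ICP or DCP). Eyes whose signal-strength Q score (0–40 scale) is below
30 are excluded outright; the threshold is strict (29 fails, 30 passes).

The quantification chain is binarize → skeletonize → four metrics:

* **Binarization.** Global Otsu threshold on the raw intensities, no
  pre-filtering; vessel = at-or-above threshold (the foreground class —
  display polarity, where vessels print dark on white, is presentational).
  The method is pluggable (`"mean"`, `"fixed"`) because no published
  consensus exists for en-face OCTA binarization; Otsu is the most common
  choice. Constant images are refused (`degenerate histogram`).
* **Skeletonization.** Zhang–Suen morphological thinning to one-pixel-wide,
  8-connected centerlines. Connectivity of components is preserved; an empty
  mask thins to an empty skeleton.
* **Metrics.** VAD and VLF are exact pixel-count ratios. VDI is mask pixels
  per skeleton pixel times the pixel pitch — the average caliber in µm; it
  is undefined (error) on an empty skeleton. The fractal dimension is the
  OLS slope of log N(s) against log(1/s), where N(s) counts occupied boxes
  on a grid anchored at the image corner, over the ladder of powers of two
  from 2 px to a quarter of the shorter image side. At least three ladder
  points are required — images smaller than 32 px on a side are refused. A
  straight line scores ≈ 1, a filled plane exactly 2 with this ladder.
* **FAZ.** The foveal avascular zone is a manually traced polygon; its area
  is the shoelace formula times the two pixel pitches, in mm². Polygons must
  be simple (an O(n²) proper-intersection test) with ≥ 3 vertices.

## Synthetic vessel networks

The generator grows correlated random walks from image-edge seeds: each step
moves 1 px and turns by N(0, (1 − persistence)·π) radians (persistence 0.95
by default — retinal vessels curve gently); with probability `branch_prob`
per step a branch walker spawns at ±40–70°; with probability `death_prob` a
walker terminates (0 by default, i.e. walkers run until they exit). Visited
pixels form the centerline; the mask is its dilation by a discrete disc of
the requested odd caliber. The disc's radius-squared cutoff (caliber²/4 −
0.5) excludes corner pixels so ribbons keep their nominal caliber along
diagonals; the rendered mean caliber (mask pixels / centerline pixels) is
recorded in the truth alongside the nominal one and is the reference that
caliber-recovery checks use.

Ground truth is exact by construction: density is the mask fraction,
centerline length the count of distinct centerline pixels, branch count the
number of spawn events. Generation stops when the mask reaches
`target_density` (checked every few hundred steps, so overshoot stays under
about 2 % of the image) or, with `target_density = NULL`, after one batch of
`n_seeds` walkers within a global step budget.

Two regimes matter for validation. Truth-recovery experiments run at target
density 0.15: at SVP-like densities (≈ 0.35) independently grown vessels
fuse, and the planted centerline is genuinely no longer the medial axis of
the rendered image — the comparison would measure fusion, not the estimator.
The branching-complexity experiment (fractal dimension increasing with
branch probability) runs in the subcritical regime (`death_prob = 0.1 >
branch_prob`), where more branching means more vessel mass and a more
space-filling skeleton; with a density target instead, total mass is clamped
and the effect disappears by construction.

## Structural OCT: layers and hyperreflective foci

**Layer thickness.** Eleven segmentation markers (ILM, RNFL/GCL, GCL/IPL,
IPL/INL, INL/OPL, OPL/ONL, ELM, MZ/EZ, EZ/OS, OS/RPE, BM) delimit the seven
reported layers: RNFL, GCL, IPL, INL, OPL, ONL, and ORL defined as ELM down
to RPE/Bruch's membrane — so the seven layers partition the full ILM–BM
stack and per-sector sums reconcile with total thickness to rounding error.
Per column, thickness = boundary-row difference × axial pitch; columns are
assigned to ETDRS sectors (C1 < 0.5 mm; inner 0.5–1.5 mm; outer 1.5–3 mm;
quadrants split at the ±45° diagonals, nasal/temporal resolved by a
laterality flag, right eye by default) and averaged. A horizontal scan
samples C1 and the nasal/temporal quadrants; adding a vertical scan covers
superior/inferior. The per-layer summary is the C1 mean and the mean of the
available ring-quadrant sector means. Boundary traces that cross at any
column are refused with the offending column named.

**HRF detection.** Candidates come from a scale-normalized
Laplacian-of-Gaussian ladder spanning 10–40 µm equivalent diameters.
Anisotropic pixels are handled by blurring with per-axis σ in pixels and
assembling the Laplacian in µm units. Numerical choices that earned their
place:

* a 6 µm Gaussian pre-smoothing tames speckle; the ladder accounts for it
  (a blob of diameter d peaks at σ² = d²/8 + 6²);
* layer bands are bright *ridges*, not blobs: a candidate must draw at least
  25 % of its response from the lateral Laplacian component (`ridge_frac`);
* the diameter is measured as the lateral half-maximum width of the blob
  profile on the pre-smoothed image — Gaussian blur leaves a step edge's
  half-level crossing in place, so this estimate is robust both to speckle
  and to the bright bands above/below that corrupt a scale-space argmax for
  foci near the RNFL;
* greedy non-maximum suppression with a 30 µm floor removes duplicates.

Retained foci must satisfy the grading criteria: diameter ≤ 30 µm;
reflectivity (raw-image mean over the measured footprint) within ±20 % of
the RNFL band mean of the same scan; shadow score — mean intensity of the
column strip below the focus down to RPE/BM divided by the same strip in
3-column flanks — ≥ 0.8; and a lateral contrast ≥ 1.5 against same-depth
flanking segments, which operationalizes "a discrete bright spot" and
rejects speckle bumps inside the RNFL or RPE bands that pass the
reflectivity window trivially. The analysis window is the central 3 mm,
closed at both ends with half-pixel tolerance. All thresholds are config
keys; the grading they mimic was visual, so the detector is validated by
recovery properties (recall/precision ≥ 0.9 on planted compliant foci, 100 %
rejection of oversized/shadowed plants), not by any claim of equivalence to
a human grader.

Compartments: the inner retina defaults to ILM → lower IPL border and the
outer retina to upper ONL → RPE/BM. The alternative inner-retina convention
(upper INL → lower OPL) is available as `ir_definition = "text"`; the two
conventions genuinely disagree for GCL/IPL foci, and the choice is
deliberately a switch rather than a guess.

**Synthetic B-scans** render flat reflectivity bands (typical macular
thicknesses; RNFL and the EZ/RPE complex bright, nuclear layers dark), plant
foci as µm-circular discs at the RNFL band mean ("moderate") or 1.5× it
("high", to be rejected), optionally halve everything below a focus down to
BM (back-shadow), and multiply by speckle. Speckle is gamma-distributed
(shape 4, mean 1) averaged over 7 frames, emulating the residual texture of
ART frame-averaged clinical scans rather than raw single-frame speckle. IR
foci are planted between the RNFL/GCL boundary and the lower IPL border, OR
foci inside the ONL — on the dark bands where graders find them; foci on the
bright bands would be invisible to any intensity criterion, human or
machine.

## Multifocal ERG

Traces are 103 per-hexagon first-order responses (rings R1–R6 with 1, 6, 12,
18, 24, 42 hexagons; the 19 hexagons of R1–R3 are the central set), sampled
at ≥ 600 Hz (1200 Hz default, the conventional rate).

**The synthetic waveform** is −a·g(t; µ₁, w) + b·g(t; µ₂, w) with Gaussian
lobes of width w = 6 ms. The generator calibrates (a, b, µ₁, µ₂) by fixed
point so that the rendered waveform's minimum sits exactly at the requested
N1 implicit time with depth N1-A, and its trough-to-peak span equals P1-A at
the requested P1 time — the planted truth is therefore the truth of the
curve, not of the lobe parameters. Amplitudes scale as 1/ring; control
defaults (P1-IT 30 ms, ring-1 P1-A 80 nV/deg², N1-A half of P1-A) are
conventional values, not measurements.

**Feature extraction.** Baseline = mean of the first 10 ms; N1 = trough in
10–45 ms; P1 = peak after the trough up to 60 ms; N1-A is
isoelectric-to-trough (positive), P1-A trough-to-peak. The default
localization fits the biphasic two-lobe model (free amplitudes, centers,
common width; `nlminb` on the 0–70 ms segment) and reports the fitted
curve's extrema snapped to the sample grid; a plain `argmax` mode takes the
raw window extrema. On noise-free biphasic traces the two agree exactly. The
fit exists because a raw argmax wanders over the flat peak top under noise —
at an amplitude-to-noise ratio of 10 its implicit-time error is several
samples, while the fitted estimate stays within one. In fit mode the fitted
isoelectric level replaces the first-10-ms mean as the N1-A reference, since
the N1 lobe's tail reaches into the baseline window. Degenerate (flat)
traces raise an extraction error; a failed fit falls back to argmax. An
optional zero-phase 10–300 Hz Butterworth band-pass is available for raw
synthetic traces; acquisition systems deliver pre-filtered data.

**Normative database and classification.** Per hexagon, mean and sample SD
(n − 1) of P1-IT and P1-A over ≥ 2 control eyes; a zero SD is refused as
degenerate rather than patched. A central hexagon is abnormal when
z(P1-IT) ≥ 2 **or** z(P1-A) ≤ −2 — both thresholds inclusive; the
conjunctive reading is available (`rule = "and"`), and N1-A can be
substituted as the amplitude feature. An eye is abnormal with at least one
abnormal central hexagon. Because implicit times are grid-quantized, a
normative database built from very few, very homogeneous control eyes can
be degenerate at some hexagon; the cohort model therefore carries realistic
inter-subject implicit-time variability (patient-level SD 0.8 ms plus
eye-level SD 1.0 ms).

## Cohort statistics

Both eyes of each patient are measured, so eyes are not independent units.
The default analysis collapses fellow eyes to patient means and runs a
one-way ANOVA across the three groups with patients as units — conservative
and correct for type-I error under any within-patient correlation; the
naive eye-level ANOVA is computed alongside and labeled, since the exact
repeated-measures formulation used in practice varies by software. With two
groups the omnibus F equals the squared two-sample t (pooled variance).
Pairwise contrasts are pooled-variance t-tests, Bonferroni-adjusted by the
number of pairs (×3 for three groups, capped at 1). No correction is applied
across metrics — only across group contrasts. The correlation screen is an
OLS slope with a Student-t test on n − 2 degrees of freedom; a constant
regressor is an error, not a p-value.

The metric-level cohort simulator draws each patient's multiplier from
N(1, 5 %), each eye's from N(1, 3 %), applies group effects
(multiplicative on per-plexus density and branching, additive on P1-IT,
Poisson-mean shift on HRF counts), and is the instrument for the two
calibration claims the package tests: with identity effects the omnibus
rejection rate is compatible with α = 0.05 (binomial check over 50
replicate cohorts), and a planted 15 % SVP density reduction with 11
patients per group is detected (Bonferroni-adjusted, noDR vs control) in at
least 80 % of replicates. The rendered cohort generator shares the same
random structure and additionally writes the images, boundary tables and
trace files the pipeline ingests.

## What the synthetic data does not emulate

Flow decorrelation statistics, projection artifacts and their removal,
curved/foveally-dipped layer geometry, pathological lesions other than HRF,
eye-movement artifacts, m-sequence derivation of the first-order kernel, and
device-specific calibration. Passing recovery tests therefore demonstrates
that the measurement chain is correct on data satisfying its stated
assumptions — not that any specific clinical result would replicate on real
scans. The problem sizes used by the test-suite and the acceptance script
(256-px angiograms, 320×620-px B-scans, 20–50 replicates per property) were
chosen as the smallest at which the checked properties are stable.

## Defaults at a glance

| Parameter | Default | Why |
|---|---|---|
| Quality gate | Q ≥ 30 (of 40) | device exclusion rule, strict |
| Binarization | global Otsu | common published choice |
| Box ladder | 2 … min(side)/4, powers of 2 | ≥ 3 points, stable slope |
| HRF ladder | 10–40 µm, 8 scales | spans the graded size range |
| HRF size cap | ≤ 30 µm | grading criterion |
| HRF reflectivity | ±20 % of RNFL mean | "similar to RNFL" |
| HRF shadow score | ≥ 0.8, 3-col flanks | "no back-shadowing" |
| HRF contrast | ≥ 1.5 lateral | discrete-spot requirement |
| mfERG windows | N1 10–45 ms, P1 ≤ 60 ms, baseline 10 ms | first-order kernel morphology |
| Abnormality | z ≥ +2 (IT) or ≤ −2 (A), inclusive | z-score rule |
| Clustering | patient means | correct type-I error |
| Bonferroni | ×3 contrasts | three group pairs |
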