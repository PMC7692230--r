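# retinaquant

Quantitative retinal morpho-functional analysis for three-group diabetic-eye
cohort studies (healthy controls, diabetes without retinopathy, diabetes with
mild retinopathy). The package turns three modalities into per-eye metric
tables and repeated-measures-aware group statistics:

* **OCT angiography (OCTA)** — en-face angiograms of the superficial (SVP),
  intermediate (ICP) and deep (DCP) capillary plexuses are binarized (global
  Otsu by default) and morphologically skeletonized; the pipeline reports

  - vessel area density `VAD = vessel pixels / total pixels`,
  - vessel length fraction `VLF = skeleton pixels / total pixels`,
  - vessel diameter index `VDI = (vessel pixels / skeleton pixels) × µm/px`
    (mean caliber),
  - box-counting fractal dimension `FD = slope of log N(s) ~ log(1/s)` on the
    skeleton,
  - foveal avascular zone (FAZ) area in mm² from a traced polygon (shoelace),

  with eyes failing the device signal-strength gate (Q score < 30 on the
  0–40 scale) excluded.

* **Structural OCT** — retinal layer thickness per ETDRS sector (1/3/6 mm
  grid, nine sectors, seven layers from the 11 segmentation boundaries), and
  hyperreflective foci (HRF) counted in the central 3 mm of the B-scan under
  the grading criteria: maximum diameter ≤ 30 µm, moderate reflectivity
  (within ±20 % of the RNFL band), no back-shadowing; counts are split into
  inner-retina (IR) and outer-retina (OR) compartments.

* **Multifocal ERG** — N1/P1 amplitudes and implicit times per hexagon of the
  103-hexagon array, ring summaries R1–R6, a control-group normative database
  (per-hexagon mean/SD of P1-IT and P1-A), and z-score abnormality
  classification: a central hexagon (rings R1–R3, 19 hexagons) is abnormal
  when `z(P1-IT) ≥ 2` or `z(P1-A) ≤ −2`; an eye is abnormal with ≥ 1 abnormal
  central hexagon.

* **Cohort statistics** — one-way ANOVA across the three groups with fellow
  eyes collapsed to patient means (a naive eye-level mode is reported
  alongside), Bonferroni-adjusted pairwise contrasts (×3), and an OLS
  regression screen (Student-t on the slope) between OCTA parameters and HRF
  counts.

Because no patient data ship with the package, a first-class synthetic-data
module generates every input with known ground truth: branching vessel
networks (correlated random walks rasterized at a chosen caliber, exact
centerline/density bookkeeping), layered B-scans with gamma speckle and
planted foci of controlled size/reflectivity/shadow, biphasic mfERG waves with
calibrated trough/peak, and full three-group cohorts with planted
plexus-specific effects and a shared patient-level random effect.

## Worked example

```r
library(retinaquant)

## generate a small rendered cohort (2 patients per group, both eyes)
co <- generate_cohort(n_per_group = 2, seed = 42, dir = "cohort")

## run the whole pipeline: per-eye metrics, group comparisons, correlations
res <- run_pipeline(co$manifest_path, out_dir = "cohort/out")
res$metrics[1:2, c("eye_id", "group", "vad_svp", "fd_svp", "hrf_ir", "p1_it_central")]
#>    eye_id   group   vad_svp   fd_svp hrf_ir p1_it_central
#> 1 P001_E1 control 0.3712500 1.526239      0      30.43860
#> 2 P001_E2 control 0.3547266 1.517859      0      31.62281
```

`vad_svp` is the superficial-plexus vessel area density (the generator's
planted density for this eye was 0.37125 — the noise-free binarization
recovers it exactly), `fd_svp` the box-counting fractal dimension of its skeleton
(between 1 for a line and 2 for a filled plane), `hrf_ir` the retained
inner-retina hyperreflective-focus count, and `p1_it_central` the mean P1
implicit time (ms) over the 19 central mfERG hexagons. `cohort/out/` also
holds `comparisons.csv` (omnibus and Bonferroni-adjusted pairwise p-values
per metric, both clustering modes) and `correlations.csv` (OCTA-vs-HRF
regression screen).

Single stages are available directly: `compute_all_metrics()`,
`count_hrf()`, `layer_thickness()`, `extract_wave_features()`,
`classify_abnormal()`, `compare_groups()`, `correlate()`. A thin CLI over
these functions is installed at `inst/cli/retinaquant.R` with subcommands
`synth`, `octa`, `oct`, `mferg`, `stats`, `all`.

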