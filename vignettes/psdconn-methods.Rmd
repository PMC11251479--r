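---
title: "Methods: lesion-aware connectivity analysis for post-stroke depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-aware connectivity analysis for post-stroke depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Post-stroke depression (PSD) affects a substantial fraction of stroke
survivors, and resting-state fMRI offers a window on the network-level
disruptions that accompany it. The analytic strategy implemented here
compares three groups — healthy controls (HC), nondepressed stroke patients
(Stroke), and PSD patients — in two data-driven stages:

1. **Hub mapping.** Voxel-wise degree centrality (DC) treats every
   gray-matter voxel as a node of the whole-brain correlation graph; the
   degree of a voxel is the number of other voxels whose time series
   correlate with it above a threshold (r > 0.32, strictly). DC maps are
   normalized by their own mean, compared across the three groups with a
   voxel-wise ANCOVA (age and gender covaried), thresholded by
   Benjamini-Hochberg FDR (q < 0.05) and a cluster-extent criterion
   (more than 20 contiguous voxels, 26-connectivity), and followed by a
   PSD-vs-Stroke post-hoc t map (NIHSS additionally covaried). Regions
   where the PSD group differs from *both* other groups in the same
   direction, each pairwise Welch test surviving Bonferroni correction over
   the three pairwise comparisons (p x 3 < 0.05), are *PSD-specific* and
   become seeds.
2. **Seed connectivity and behavior.** For each seed, Fisher-z-transformed
   seed-based functional connectivity (FC) maps pass through the same
   inference path; PSD-specific FC regions provide (a) Spearman
   brain-behavior correlations with the three depression scales (PHQ-9,
   HAMD, CES-D) at the Bonferroni level p < 0.05/3, and (b) features for a
   ridge regression predicting each scale, with the penalty chosen by
   leave-one-out cross-validation (LOOCV) and performance measured as the
   Spearman correlation between observed and out-of-fold predicted scores.

Everything upstream is lesion-aware: volumes of right-lesion patients are
mirrored so the ipsilesional hemisphere is always the left one, lesioned
voxels are excluded from masks (and can be enantiomorphically filled in
structural images), and stroke patients receive a per-voxel hemodynamic lag
correction by time-shift analysis before filtering.

## Preprocessing model and its order

Per subject, the pipeline applies, in fixed order: hemisphere flip (right
lesions only) → slice-timing hook (a registered no-op for synthetic data) →
removal of the initial volumes (default 10) → motion QC → one-pass nuisance
regression → hemodynamic lag correction (patients only) → ideal band-pass
filter (0.01-0.08 Hz). Degree centrality is computed on *unsmoothed*
output; seed FC uses a 6-mm-FWHM smoothed copy.

Design choices worth knowing:

- **QC boundaries are strict.** Exclusion requires maximal displacement
  *exceeding* 3 mm, rotation *exceeding* 3 degrees, or mean framewise
  displacement *exceeding* 0.5; values exactly at a threshold are kept.
  FD follows the Power convention (rotations scaled by a 50 mm sphere
  radius).
- **One regression pass.** The Friston-24 motion set, WM and CSF mean
  signals, intercept and linear trend enter a single design matrix, so the
  result does not depend on the order of sequential residualizations. The
  global signal is deliberately *not* removed.
- **Band-pass as an ideal DFT mask.** Frequency bins inside
  [0.01, 0.08] Hz are kept verbatim, all others zeroed. This is exactly
  testable: a sinusoid on an in-band bin passes with amplitude ratio 1, an
  out-of-band bin is annihilated. The filter errors out, naming the
  smallest usable series length, when no bin falls inside the band.
- **Lag correction.** For each voxel the integer shift in ±`max_lag_tr`
  (default 4 TR) maximizing the overlap Pearson correlation with the
  reference (gray-matter mean by default) is the lag estimate; ties go to
  the smaller magnitude, then to the negative shift; the series is shifted
  back with edge repetition. The pipeline additionally requires the
  correlogram peak to reach `lag_min_r` (default 0.3) before applying a
  nonzero shift: a lag read off an uninformative correlogram is noise, and
  shifting by it merely jitters the series. Setting `lag_min_r = 0`
  restores the pure argmax.
- **Smoothing** is separable Gaussian convolution with
  sigma = FWHM / (2 sqrt(2 ln 2)) per axis in voxel units, under a
  reflective boundary, which preserves constants and total mass.
- **Enantiomorphic filling** mirrors across the grid's central sagittal
  plane; a lesioned mirror voxel falls back to the original value with a
  warning.

## Degree centrality and seed FC

DC streams the correlation computation in voxel blocks (the V x V matrix is
never materialized), counts strictly supra-threshold positive correlations
(negative correlations never contribute; the self-edge is excluded), zeroes
and flags zero-variance voxels, and divides by the mean in-graph degree, so
the normalized map has mean exactly 1. The default threshold 0.32 is the
field's conventional whole-brain Bonferroni point; a helper
(`bonferroni_r_threshold()`) recomputes the exact threshold for any series
length and voxel count, but the constant remains the default because the
equivalence depends on unreported acquisition parameters. Because the map
is normalized by its own mean, DC is a *relative* quantity: elevating true
hubs necessarily depresses the normalized values of everything else, which
is visible in strong-effect simulations as apparent "down" effects in
non-hub regions.

Seed FC correlates the seed-mean series with every voxel and applies
z = atanh(r), capping |r| at 1 - 1e-7 (capped voxels are flagged) so maps
stay finite — the seed's own voxels are computed like any others.

## Group inference

The voxel-wise GLM is solved in closed form across all voxels at once: the
three-group contrast is a partial F test (group indicators added to an
age + gender covariate model), pairwise contrasts are t tests on a group
indicator. NIHSS enters the design exactly when the contrast is PSD vs
Stroke — validation refuses it anywhere else. Post-hoc maps are restricted
to the ANOVA-significant mask by default; the PSD-vs-Stroke map is
thresholded at uncorrected p < 0.05 (configurable to FDR), matching the
two-tier thresholding convention of small clinical samples. Cluster extent
is strict ("k > 20"), the neighborhood defaults to 26-connectivity, and
cluster peaks are maximal |statistic| with ties resolved to the lowest
linear index. Pairwise ROI tests are Welch t tests (group sizes and
variances differ by design); the Bonferroni family defaults to the 3
pairwise tests per ROI, configurable, since the correction family is a
genuinely open choice.

Demographic tables route variables the conventional way: three-group
continuous variables pass a per-group Shapiro-Wilk gate (all normal at
p > 0.05 → one-way ANOVA, otherwise Kruskal-Wallis; a constant group —
e.g. a ceiling-valued ADL in controls — counts as non-normal), two-group
continuous variables use Mann-Whitney U, categorical variables use Pearson
chi-square *without* continuity correction (the uncorrected Pearson
statistic is what standard clinical statistics packages report for these
tables).

## Behavior stage

Spearman correlations use average ranks for ties; p-values come from the t
approximation for n ≥ 10 and from the exact permutation distribution below
that. Ridge regression standardizes features with training-fold statistics
only, leaves the intercept unpenalized, and chooses the penalty minimizing
the LOOCV mean squared error over a 17-point log-spaced grid spanning
1e-3 to 1e3 (ties to the smaller penalty). The reported performance is the
Spearman correlation between observed scores and the LOOCV predictions at
the chosen penalty. This single-loop choice (the same LOOCV errors pick the
penalty and measure performance) is optimistically biased; it is the
default because it mirrors the convention of the analysis being
re-implemented, and the leakage contract that matters — the held-out
subject never touches its own fold's standardization or fit — is asserted
by test.

## The synthetic cohort generator

No patient data accompany this package, so the generator defines the
conditions every claim is tested under. Each voxel series follows a common-factor model

v(t) = sqrt(rho) f_b(t - lag_v) + sqrt(1 - rho) eps_v(t),

with f_b a unit-variance stationary AR(1) factor per network block
(phi = 0.5 — BOLD fluctuations are temporally smooth; a white factor would
make a 1-TR misalignment catastrophic in a way real data never is, while
the equal-time correlation target rho is unchanged), eps white unit
Gaussian noise, and integer lags implemented by circular factor shifts.
Within a block, two lag-aligned voxels have population correlation exactly
rho — the closed form every recovery test checks. PSD-group hub blocks use
rho + delta.

Defaults, chosen once as the desk-scale simulation conditions:

| parameter | default | meaning |
|---|---|---|
| grid | 16 x 16 x 12 voxels (3 mm) | common analysis grid |
| gray-matter mask | inscribed ellipsoid (~1230 voxels) | a brain mask is not a box |
| T, TR | 150 volumes, 2 s | series length |
| groups | 15/15/15 (HC/Stroke/PSD) | configurable up to full clinical scale (74/82/39) |
| blocks | six 27-voxel cubes, mirror-paired | "networks"; flip maps the set onto itself |
| within_block_r | 0.30 | baseline coupling |
| hub blocks | the two right-hemisphere pairs | contralesional hub elevation |
| effect_delta_r | 0.25 | PSD hub elevation |
| lags | ±2 TR, blockwise-constant | coherent lag territories; `lag_mode = "voxel"` for i.i.d. lags |
| lesions | 4-20 voxel unilateral boxes | zero the BOLD; drawn avoiding block centers |
| motion | AR(1), 0.05 mm innovations | passes QC by default |

Generation happens in the canonical ipsilesional-left space; subjects
assigned a right-sided lesion are mirrored to native orientation on output,
and the preprocessing flip restores canonical space exactly, so injected
contralesional effects stay coherent across the cohort.

Behavior coupling: each PSD subject's realized hub coupling (mean pairwise
Fisher z within hub blocks of that subject's actual series) drives the
depression scores, score = base + slope x (z - z_ref) + noise, clipped to
each scale's range (PHQ-9 0-27, HAMD ≥ 0, CES-D ≥ 0) and rounded. The
slopes (PHQ-9 80, HAMD 50, CES-D 110) and noise SDs (1.5, 1.2, 2.5) were
calibrated once at design time from the factor model itself — the
between-subject SD of realized hub coupling is ~0.03 Fisher-z units at the
default conditions — so that score dispersions match the reference
demographic table and the coupling-score correlation is strong (~0.85).
Group-level demographic distributions (age, gender mix, onset, NIHSS, ADL
and the no-depression score ranges) follow the same built-in profiles.

**What the generator does not emulate:** hemodynamic response functions,
physiological noise spectra, scanner drift, T1 anatomy, spatial
autocorrelation of noise, non-box lesion geometry, and any genuine
neuroanatomy. Passing tests therefore demonstrate that the *statistical
machinery* — from lesion-aware preprocessing through specificity
conjunction to LOOCV prediction — behaves as documented under a known
data-generating process; they say nothing about effect sizes in real
patients, and no real-data cluster table can be reproduced without actual
patient volumes.

## Numerical choices and degenerate inputs

- Zero-variance voxels: dropped from the DC graph (degree 0, flagged), lag
  0 (flagged), excluded from FC via r = 0.
- Fisher-z capping at |r| = 1 - 1e-7 keeps maps finite; capped voxels are
  flagged.
- Rank-deficient nuisance designs drop collinear columns with a message;
  rank-deficient inference designs are an error naming the columns.
- `within_block_r = 1` is accepted as the documented noiseless edge case
  (used by the exact lag-recovery validation); rho + delta beyond 1 is a
  validation error.
- All randomness flows from one root seed through named substreams
  (`derive_seed()`), and identical configurations reproduce byte-identical
  pipeline outputs.

## Problem sizes used by the validation suite

The suite validates at sizes that keep a full run in minutes on one CPU:
specificity sensitivity on 100 replicate desk-scale cohorts (15/group,
delta = 0.25), null specificity control on 200 reduced cohorts
(10 x 10 x 8 grid, T = 100, 10/group), FDR control on 200 replicate
30-subject null map stacks of 300 voxels, DC oracle equivalence on 200
random fixtures up to 50 voxels, and the prediction-power check on 100
replicate cohorts at a full clinical PSD group size (n = 39). The end-to-end
pipeline test runs a 12^3-voxel cohort with a widened pass band (0.01-0.2
Hz): at desk scale the default narrow band leaves too few effective degrees
of freedom for voxel-wise FDR detection at n = 10/group, and that test
checks plumbing, not power.

## Known limitations

- Ideal DFT filtering assumes the band edges fall sensibly among the
  available bins; very short series raise an error rather than degrade.
- The specificity conjunction inherits the relative nature of normalized
  DC (see above): its verdicts are about *relative* hubness.
- Single-loop LOOCV performance is optimistically biased; treat reported
  rho as an in-protocol comparison number, not an out-of-sample estimate.
- The time-shift stage estimates lags per voxel independently; no spatial
  regularization is applied beyond the `lag_min_r` gate.

## A worked example

```{r example}
library(psdconn)
cfg <- pipeline_config(
  synthetic = list(grid_shape = c(12, 12, 12), n_timepoints = 120,
                   n_per_group = c(HC = 10, Stroke = 10, PSD = 10),
                   effect_delta_r = 0.35),
  out_dir = "psd-demo", rng_seed = 3,
  preprocess = list(drop_initial = 5, max_lag_tr = 2, band_high_hz = 0.2),
  inference = list(min_extent = 10))
res <- run_pipeline(cfg)
res$seeds                    # PSD-specific DC regions, used as seeds
res$behavior_correlations    # Spearman rho/p per region and scale
res$predictions$PHQ9         # ridge-LOOCV prediction of PHQ-9
```
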