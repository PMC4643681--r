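---
title: "Track-wise lesion-deficit mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Track-wise lesion-deficit mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hodomap)
```

# The problem

After a stroke, a cognitive deficit can arise from damage to a cortical
locus or from disconnection of the white-matter pathway linking the loci
that jointly implement the function. `hodomap` implements the hodological
(track-wise) side of lesion-symptom mapping for exactly this question: given
binary lesion maps in a common space, a probabilistic atlas of white-matter
tracts, and continuous behavioural scores, which tracts' disconnection
predicts which deficit once lesion size and age are controlled?

The behavioural instrument modelled throughout is the complex-figure copy
task of the Birmingham Cognitive Screen (BCoS), whose drawing can be scored
both as a single 47-point accuracy total and as a global/local
decomposition: 6 *global* features carry the figure's large-scale layout
(the middle square, the two flanking rectangles, the left double bar, the
right triangle, the long main diagonal) and 14 *local* features are the
smaller details inside it. Because the two feature counts differ, both are
expressed as percentages of their maxima before entering any model.

# The processing chain

## 1. Automated lesion delineation

Each patient image is compared voxel-by-voxel against a control sample with
the Crawford–Howell single-case t statistic,

$$t = \frac{x - \bar c}{s_c\,\sqrt{(n+1)/n}}, \qquad \mathrm{df} = n - 1,$$

where $\bar c$ and $s_c$ are the control mean and sample standard deviation
at that voxel and $n$ the number of controls. The $\sqrt{(n+1)/n}$ factor
keeps the statistic calibrated when $n$ is small, which matters because
control CT samples are rarely large. The resulting outlier t-map is
thresholded on the hypointense tail (ischemic tissue is dark on CT) to give
a binary lesion map, from which the lesion volume in cm³ follows directly.

Numerical choices:

* **Threshold.** No universal cut-off exists; the default is the t value of
  one-tailed p = 0.01 at df = n − 1 (`auto_t_threshold()`), explicit and
  configurable. At that default roughly 1% of healthy voxels exceed the
  threshold by construction, so for small lesions the optional
  connected-component cleanup (`min_cluster_voxels`) is important: on a
  36 864-voxel grid a 1% false-positive rate scatters ≈ 370 isolated
  voxels, which alone bounds the Dice overlap of a ~400-voxel lesion near
  0.7. Removing components of fewer than 2 voxels already restores Dice
  above 0.9 in the package's recovery simulation; the cleanup is off by
  default because it is not part of the core statistic.
* **Degenerate voxels.** Where the control sd falls below
  $10^{-6}\times\overline{s_c}$ the statistic is undefined; such voxels are
  reported as t = 0 and counted, never silently dropped.

## 2. Disconnection quantification

Tract probability maps are thresholded at 50% — keeping each tract's
anatomical core and discarding the individually variable periphery — and
the disconnection measure for patient i and tract t is the volume in cm³ of
the intersection of lesion i with core t. The threshold comparison is
inclusive (≥ 0.5), and maps supplied on a 0–100 scale are normalised with a
warning. "Disconnected" for descriptive percentages means any shared voxel
(`min_cc = 0`), configurable.

## 3. Track-wise inference

One ordinary-least-squares model per tract and hemisphere:

$$\mathrm{score} \sim \mathrm{disconnection}_t + \mathrm{lesion\ volume} + \mathrm{age}\ (+\ \mathrm{vf}_L + \mathrm{vf}_R),$$

with the visual-field miss counts forming the optional control model. The
reported coefficient is standardized post hoc,
$\beta = b\,\mathrm{sd}(x)/\mathrm{sd}(y)$, which reproduces the common
reporting convention without refitting on z-scores and is invariant to the
disconnection unit. Significance is Bonferroni-corrected over the tract
family — canonically 16 tracts (10 association, 2 commissural, 4
projection; `canonical_tracts()`), giving α = 0.05/16 = 0.003125. The
unrounded value is applied with a strict inequality, so an observed
p = .003 counts as significant even though the α itself is conventionally
printed as ".003". Tracts overlapped by no lesion have a zero-variance
predictor and are skipped with a logged reason rather than fitted; the
Bonferroni family size stays at the full atlas count regardless, because
the correction describes the planned family, not the fitted subset.

A caveat that the synthetic experiments make vivid: fitting one tract at a
time while sharing a lesion-volume covariate invites *suppression*
artifacts. When damage in hemisphere A drives a deficit, the volume
covariate absorbs part of that effect, and tracts of hemisphere B — whose
disconnection correlates with volume but not with the deficit — can reach
significance with a **positive** β (disconnection apparently predicting
better scores). The package therefore treats a tract as *implicated* only
when it is significant in the deficit direction (β < 0 with scores coded
so that higher is better); positive-β survivors are reported but should be
read as artifacts of the single-tract design, not findings.

## 4. Voxel-wise GLM with permutation cluster correction

As a topological complement, `fit_voxelwise_glm()` fits the same OLS model
at every voxel of a set of smoothed per-patient images; in the synthetic
pipeline these images are the lesion masks smoothed with a 12-mm FWHM
Gaussian — a lesion-density surrogate that preserves the inference
structure of a voxel-based analysis without tissue segmentation. Clusters
are formed at one-sided voxel p < 0.001 and an extent threshold of 800 mm³
(exactly 100 voxels on the default 2-mm grid; components *smaller* than
the extent are discarded, so a 100-voxel cluster survives). Cluster-level
family-wise error is controlled by permutation rather than random-field
theory: under the Freedman–Lane scheme the nuisance-only model's residuals
are row-permuted, the full model refitted, and the null distribution of the
maximum suprathreshold cluster size yields

$$p_{\mathrm{cluster}} = \frac{1 + \#\{\max\ \mathrm{size}_\pi \ge \mathrm{size}_{\mathrm{obs}}\}}{1 + n_{\mathrm{perm}}},$$

which is exact under exchangeability and never smaller than
$1/(1+n_\mathrm{perm})$. Default connectivity is 26 (full neighbourhood);
6 and 18 are available.

# The synthetic cohort generator

Because no patient data ship with the package, every downstream stage is
exercised on synthetic cohorts whose ground truth is known exactly
(`cohort_spec()` / `generate_cohort()`).

* **Grid.** 32 × 36 × 32 voxels at 2 mm isotropic, centred on the midline
  — a deliberately scaled-down head volume that keeps a default cohort
  generation in seconds while preserving every geometric relation
  (hemispheres, midline band, mm³/cm³ bookkeeping).
* **Controls.** A smooth low-frequency "anatomy" field (smoothed white
  noise, sd 3, mean level 100 arbitrary units) shared by all subjects on a
  grid, plus per-subject i.i.d. noise (sd 2). Sharing the anatomy makes the
  across-subject sd equal the noise sd, so a lesion of intensity drop
  $k\sigma$ has exactly $k$ control-sd contrast — the quantity the
  delineation statistic sees.
* **Lesions.** Sharp-edged ellipsoids (semi-axes drawn from 5–12 mm),
  single lesion per patient, hypointense by 20 units (10 control sd) by
  default. Ellipsoids were chosen for their analytic volume, giving the
  mask-generation code an exact oracle.
* **Tracts.** Tube-shaped probability maps
  $p(v) = 0.9\,\exp(-d^2/2(r/2)^2)$ around polyline centerlines, four
  lateralized pairs mirroring the asymmetric scenario of interest: IFOF
  (radius 7 mm), SLF III (7 mm), the arc-shaped perisylvian long segment
  (7 mm) and ILF (5 mm) as an inert negative control. Positions scale with
  the grid.
* **Behaviour.** Generated on the percentage scale from a linear
  disconnection→deficit model,
  $\mathrm{score} = \mathrm{clip}(90 - \sum_t w_t d_t - 0.3V - 0.15(\mathrm{age}-65) + \varepsilon,\ 0,\ 100)$,
  with $\varepsilon \sim N(0, 5^2)$. The default weights put 15 points of
  deficit per cm³ on `ifof_left` for the **local** score and on
  `slf3_right` and `long_segment_right` for the **global** score — the
  left-local / right-global dissociation. No published effect-size anchors
  exist for points-per-cm³; 15 was fixed at design time as a
  clearly-suprathreshold effect for a 60-patient cohort with noise sd 5,
  and is a spec knob, not a fitted value.
* **Placement.** 60% of patients get a lesion centred on a designated
  effect tract (cycled deterministically by patient index so each driver
  tract receives a comparable share; centre sampled uniformly along the
  centerline with 2-mm jitter); the rest are placed uniformly at random,
  lateralized away from the midline. Every random draw comes from a stream
  derived from (master seed, patient index), so adding or removing patients
  never perturbs the others.

What the generator does **not** emulate: CT physics (bone, beam hardening,
partial-volume edges), multi-focal or irregular lesion shapes, spatial
normalisation error, atlas–subject anatomical mismatch, and realistic
behavioural floor effects. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under its own assumptions —
not that those assumptions hold in clinical CT data.

# Verification strategy and problem sizes

The test suite pins every computational claim to an independent oracle:
the t-map to a per-voxel scalar loop (10⁻¹⁰), overlap volumes to
brute-force voxel counting (exact), the regression to hand-solved normal
equations plus the t distribution (10⁻⁸), the mass-univariate GLM to
per-voxel `lm()` fits (10⁻⁸), and the ellipsoid masks to the analytic
ellipsoid volume. Calibration claims use seeded simulation at deliberately
desk-scale sizes: 200 null cohorts for the track-wise type-I rate (checked
against family-adjusted binomial bounds and the 1.5% pooled ceiling), 50
replicates of the asymmetric cohort (n = 60, noise sd 5) for recovery of
the planted dissociation, 30 null image datasets × 100 permutations for the
super-uniformity of cluster p-values, and a single planted-effect dataset
(effect 3 × noise sd, n = 40, 200 permutations) for detection. The same
quantities are recomputed from scratch, from the seed passed on the command
line, by `scripts/acceptance.R`.

# Known limitations

* Inputs must already share one axis-aligned RAS grid; there is no
  registration, reorientation or resampling.
* The delineation threshold and cleanup are configuration, not estimated
  from data; a production deployment would calibrate them against manually
  traced lesions.
* Single-tract regressions cannot separate correlated tracts within a
  hemisphere, and the suppression artifact described above is intrinsic to
  the design; a multivariate or permutation-based joint model is out of
  scope.
* Permutation cluster correction assumes exchangeability of residuals
  under the nuisance model — adequate for the synthetic cohorts, an
  approximation for real data with heteroscedastic noise.
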