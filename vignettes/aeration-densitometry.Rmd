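---
title: "Aeration densitometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aeration densitometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aerateCT)
```

## The measurement

Lung CT attenuation, expressed in Hounsfield Units (air ≈ −1000 HU, water
0 HU), is a direct proxy for regional air content: fully inflated alveolar
tissue sits near −900 HU and progressively densified (edematous, inflamed,
fibrotic) tissue drifts toward 0. `aerateCT` quantifies this by
histogramming the HU values of segmented lung parenchyma — operationally,
lung voxels within [−900, −100] HU — into fixed intervals, and expressing
each interval's volume as a percentage of total lung volume.

Two interval schemes are built in:

* the conventional **two-compartment** split: well-aerated `[-900, -500)`
  and poorly-aerated `[-500, -100]`;
* the refined **ten-bin** scheme: ten contiguous 80-HU bins over the same
  800-HU range.

The two are exactly nested (five bins per compartment), so
`aggregate_profile()` reproduces the two-compartment result from the
ten-bin profile bitwise on voxel counts — a conservation property the test
suite asserts. The scientific point of the refinement is that early
densification largely redistributes attenuation *within* the well-aerated
range; a readout that integrates over that whole range cannot see it, while
individual 80-HU bins can.

### Numerical conventions

* **Bins are half-open** `[lo, lo + 80)`, the last closed. On integer HU
  exports this is identical to the conventional integer boundary listing
  (−900/−821, −820/−741, …); for continuous HU it removes boundary
  ambiguity. A voxel at exactly −500 HU is poorly-aerated.
* **The denominator** of the percentages is the total segmented parenchyma
  volume (the sum over bins). This is the only denominator under which
  per-bin percentages are guaranteed to sum to 100; lumen air (< −900 HU)
  and dense structures (> −100 HU) are excluded from both numerator and
  denominator.
* HU are held as doubles in memory regardless of on-disk type; NIfTI-1
  slope/intercept are applied on read. NIfTI headers store voxel spacing as
  32-bit floats, so spacing round-trips exactly at float32 precision.
* The analysis is purely histogram-based and therefore invariant to voxel
  order and image orientation; no reorientation is performed.

## Segmentation

Manual or semi-automated segmentation in commercial tools is not
reproducible from a written description, so the package defines a fully
deterministic pipeline with every threshold exposed in
`segmentation_params()`:

1. **Body**: largest 6-connected component of voxels ≥ −500 HU
   (`body_threshold`), hole-filled per axial slice. Per-slice (2-D) filling
   is deliberate: 3-D filling of a closed thorax would also seal the
   tracheal opening and misclassify ambient air.
2. **Lung**: voxels < −500 HU strictly inside the body, components smaller
   than `min_component_vox` (default 100) removed, then a per-slice
   morphological closing of radius `closing_radius_vox` (default 2 voxels)
   confined to the body. Airway lumen stays in the lung mask for
   visualisation.
3. **Parenchyma**: lung voxels within [`parenchyma_lo`, `parenchyma_hi`]
   (defaults −900/−100 HU). Lumen and trapped air (< −900) and vessels or
   consolidation (> −100) are excluded from densitometry.

Masks satisfy parenchyma ⊆ lung ⊆ body voxelwise, are deterministic, and
are invariant under a common HU offset applied to data and thresholds —
all asserted as properties in the tests. Left/right lungs are not
separated; profiles are whole-lung.

## Group statistics

Two designs mirror the two readouts:

* **`per_bin_t`** — independent two-sample comparisons per bin: unpaired
  two-tailed Student t-test, switching to Welch's unequal-variance form
  when a two-sided F-ratio test of the sample variances rejects at 0.05.
  The F-test-then-Welch rule is a pragmatic reproduction of common
  practice; the pre-test makes realized per-bin type-I error sit slightly
  above nominal (≈ 0.05–0.06 in the calibration experiment), which the
  package reports rather than hides.
* **`anova_dunnett`** — per time point, a two-way fixed-effects ANOVA with
  treatment group and HU bin as factors, *with* interaction by default: a
  group × bin interaction is precisely a shape change of the aeration
  curve, which is the effect of interest (a flag drops it). Per-bin
  treatment-vs-control contrasts then use the pooled residual mean square
  and its degrees of freedom, with familywise adjustment by a seeded
  Monte-Carlo max-|t| procedure.

Groups with a single animal are excluded from all inference and reported
descriptively (means only).

### The Dunnett-type adjustment and its correlation model

`dunnett_adjust()` samples the null maximum of k |t| statistics that share
one residual chi-square, under an equicorrelation model. Monte Carlo
(default 10⁵ draws, seeded, cached) rather than tabulated quantiles keeps
arbitrary (k, df) available; adjusted p values are floored at the
unadjusted p, and the implementation is cross-checked in the tests against
exact multivariate-t probabilities (mvtnorm) to within Monte-Carlo
tolerance.

The correlation deserves care. The textbook many-to-one setting — k
treatment arms each compared with one shared control sample of equal size —
induces pairwise correlation ½, and that is `dunnett_adjust()`'s default.
The per-bin family used by `compare_groups()` is different: its k contrasts
compare the *same two groups* in *different bins*. Measured across
simulated null cohorts, their pairwise correlation is ≈ −1/9 — weakly
negative, through the closure of fractions to 100% — not +½. Using the
corr-½ critical value there understates the familywise error (≈ 0.07–0.08
at nominal 0.05 in a 1000-replicate null experiment); sampling the null
with independent contrasts (correlation 0) is accurate-to-conservative for
negatively correlated families and restores control (measured familywise
error ≈ 0.05–0.06). `compare_groups()` therefore uses
`dunnett_correlation = 0`, with the classical ½ still available.

## The phantom generator

`phantom_spec()` describes a synthetic thorax: a soft-tissue (+40 HU) body
ellipsoid in −1000 HU air, two lung ellipsoids, an optional airway tube,
additive Gaussian noise (default sd 10 HU), and 72 μm isotropic voxels —
the resolution class of high-resolution rodent micro-CT. The grid (default
72³) is a cropped stand-in, not a full field of view, sized so tests run in
seconds.

Parenchymal HU follow a two-component mixture of truncated normals on
[−900, −100]:

* baseline component `N(μ₀ = −700, σ₀ = 100)`: healthy aerated tissue. The
  sd was chosen so a healthy phantom carries a small but nonzero
  poorly-aerated tail (≈ 2%), as healthy-animal aeration curves do. A much
  tighter baseline (e.g. σ₀ ≈ 60) would put essentially zero mass and
  zero between-animal variance above −500 HU, making the two-compartment
  readout implausibly hypersensitive to any boundary crossing — the
  opposite of its documented insensitivity — and leaving the upper bins
  structurally empty.
* densified component `N(μ₁ = −560, σ₁ = 50)`: early fibro-inflammatory
  tissue, centred *below* the −500 boundary so that most of the shifted
  mass stays within the well-aerated compartment — the defining feature of
  early disease that the refined readout exists to detect.
* the **densification fraction** `f ∈ [0, 1]` mixes the two; it is the
  single severity dial, with analytic per-bin ground truth from CDF
  differences (`analytic_bin_fractions()`), against which measured
  profiles are validated to within 1 percentage point at ≥ 10⁵ parenchyma
  voxels.

`cohort_spec()` adds the study structure: arms with severity trajectories
over time points, a persistent per-animal severity offset (sd 0.03,
clipped), and a persistent per-animal baseline shift on μ₀ (sd 20 HU,
representing inflation/positioning differences). Defaults mirror a
chronic low-dose injury design: a 9-animal control, an 11-animal treated
arm (f: 0 → 0.15 → 0.15 across day 0/14/21), and a single-animal
high-dose descriptive arm. `simulate_cohort_profiles()` samples each
animal's parenchymal histogram directly (20 000 voxels by default,
noiseless) without rendering images — the same distributional law as
profiling a noise-free phantom's true parenchyma mask — so replicated
experiments run at simulation speed; `generate_cohort()` writes full NIfTI
volumes for pipeline and CLI testing.

### What the phantoms do and do not show

The generator reproduces the *distributional* signature of densification
and the *statistical* structure of a small-animal study. It deliberately
omits spatially structured lesions, reconstruction physics (beam
hardening, scatter), breathing motion, and anatomically realistic lungs.
Passing tests therefore demonstrate that the pipeline measures HU
distributions correctly, conserves volume, controls error rates, and that
the ten-bin readout detects within-compartment shifts the two-compartment
readout misses — they do not certify segmentation performance on real
anatomy, which has no ground truth here.

## Calibration and power experiments

* **Null calibration** (`type_i_error_experiment()` with
  `null_cohort_spec()`): 9 vs 11 animals, zero severity everywhere, no
  severity dispersion, and a deliberately *near-uniform* baseline
  (μ₀ = −500, σ₀ = 800 over the 800-HU range; 2000 voxels per animal). A
  per-bin error rate is only measurable in bins that contain data, and
  near-equal bin masses keep the pooled-variance assumption of the ANOVA
  contrasts accurate — so this design isolates the calibration of the
  statistics from distributional artifacts. Expected results at α = 0.05:
  per-bin unadjusted type-I ≈ 0.05, Dunnett-adjusted familywise error
  ≤ nominal + Monte-Carlo noise.
* **Detectability** (`effect_detectability_experiment()`): each replicate
  regenerates the cohort and runs both analyses; a replicate "detects" when
  any bin is significant at α (adjusted p for the ten-bin design,
  unadjusted for the two-compartment design, matching how each analysis is
  used in practice). At a small effect (f = 0.08, 9 vs 11 animals) the
  ten-bin analysis has materially higher power than the two-bin analysis —
  the mode bin of the baseline loses mass to first order while the −500
  crossing barely moves; at f = 0.6 both saturate near 1.

Problem sizes used by the shipped experiments — 1000 replicates for
calibration, 200 for power, 50 phantom seeds at ≥ 10⁵ parenchyma voxels
for oracle recovery, 1000 small random phantoms for conservation — were
chosen to give Monte-Carlo standard errors well below the effect sizes
being asserted while keeping a full run in minutes on one core.

## Known limitations

* Per-bin fractions are compositional (they sum to 100); per-bin testing
  is reproduced as practised, without a log-ratio transform, and the
  mild negative cross-bin dependence is handled only through the
  adjustment's correlation model.
* The calibration heuristic for HU (air-reference check in
  `validate_hu_calibration()`) flags implausible volumes; it does not
  reconstruct any scanner's normalisation.
* DICOM import, image registration across time points, lobe/airway/vessel
  segmentation and longitudinal mixed-effects modelling are out of scope;
  time points are analysed separately by design.
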