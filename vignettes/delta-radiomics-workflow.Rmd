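---
title: "Delta-radiomics for MR-guided liver SBRT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-radiomics for MR-guided liver SBRT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltarad)
```

## The problem

Liver lesions treated with MR-guided SBRT are imaged volumetrically before
every fraction. Standard response assessment (RECIST-style restaging) only
happens months after treatment; the hypothesis behind delta-radiomics is that
*texture change inside the gross tumour volume during the course itself*
already carries a response signal. This package implements that analysis as a
reusable pipeline: ROI preprocessing, 3D second-order texture features,
dose-aligned delta features, and a small-cohort modelling stack, plus a
synthetic cohort generator so every stage is testable without patient data.

Throughout, `poor_response = TRUE` denotes local failure (progressive disease
of the treated lesion); labels are inputs, never computed here.

## Preprocessing

MR intensities have no absolute scale, so two normalizations precede any
texture matrix:

1. **Collewet ±3σ clipping** (`collewet_normalize()`): ROI intensities are
   clipped into `[μ − 3σ, μ + 3σ]`, with μ and σ computed *over ROI voxels
   only* — background must not influence the lesion's dynamic range. σ uses
   the population (divide-by-`n`) estimator by default; the `n − 1` variant is
   a configuration flag (`sigma_divisor`) because the divisor only shifts
   which boundary voxels are clipped and conventions differ between
   toolboxes.
2. **Histogram-equalization quantization** (`quantize_equalize()`): levels
   `1..Ng` (default `Ng = 64`) are assigned through the right-continuous
   empirical CDF, `level(x) = max(1, ⌈Ng · F̂(x)⌉)`. The mapping is monotone,
   ties always share a level, it is idempotent on its own output, and for
   continuous inputs with `n ≫ Ng` it flattens the level histogram to
   `n/Ng ± O(√n)` per level, which is what makes texture matrices comparable
   across patients. A zero-variance ROI maps every voxel to level 1 by
   convention, so downstream matrices are still defined.

The order is fixed (normalize, then quantize) and clipping statistics are
ROI-restricted, which also makes the bounding-box question moot: cropping to
the mask bounding box before or after cannot change any statistic.

## Texture features

`extract_features()` emits 39 features in a fixed, documented registry order
(`feature_registry()`): 8 GLCM, 13 GLRLM, 13 GLSZM and 5 NGTDM features. The
identity of the full 39-feature set is a design decision: the four families
and the two pinned members (GLCM energy, GLSZM large zone emphasis) are
fixed by the analysis being implemented, and the classic texture-toolbox
family counts (8 + 13 + 13 + 5) complete the set. The registry is a single
canonical vector so the enumeration can be re-mapped without touching
algorithms.

Geometry conventions, all tested against independent brute-force oracles:

- Offsets live on the voxel lattice: 13 unique 3D directions, both orderings
  counted, so the GLCM is symmetric by construction. Anisotropic spacing is
  carried as metadata but does not reweight directions — no mm-space
  correction is applied.
- GLCM and GLRLM default to **merged** aggregation (one matrix summed over
  the 13 directions, normalized once); per-direction **averaged** features
  are a configuration flag, not a hidden default.
- GLSZM zones are maximal 26-connected equal-level components; the NGTDM
  neighbourhood is the 26 surrounding voxels.
- Computation runs on the mask bounding box; voxels outside the ROI are `NA`
  and can never pair, run, zone or neighbour with ROI voxels, so results are
  identical to full-grid computation (tested via translation invariance).

Degenerate inputs return defined values rather than errors so a longitudinal
cohort never crashes mid-extraction: a singleton ROI has no co-occurring
pairs (all GLCM features 0) and no valid NGTDM neighbours (all NGTDM
features 0); a flat ROI has zero total gray-tone difference, where NGTDM
coarseness — a reciprocal — is capped at 10⁶ and busyness/strength are 0.
GLCM correlation is 1 when the marginal variance is 0.

## BED checkpoints and delta features

`compute_bed()` implements the linear-quadratic `n·d·(1 + d/(α/β))` with
`α/β = 10` Gy. Setup image `k` is acquired *before* fraction `k`, so the
cumulative BED it reflects is `(k−1)·d·(1 + d/(α/β))`. `align_checkpoint()`
uses a ceiling rule — the first image at-or-after the target BED — because
heterogeneous schedules rarely hit 20 or 40 Gy exactly; the realized BED is
stored on the checkpoint so the approximation stays auditable, and no
interpolation between fractions is attempted. A course that never reaches a
checkpoint is excluded *from that feature library only* and reported, never
silently dropped.

Deltas are `f(checkpoint) − f(baseline)`; the opposite convention only flips
every sign, to which rankings and AUCs are invariant.

## Modelling

- **Baseline screening**: per-feature two-sample t-test (Welch by default;
  pooled-variance via `var_equal` since the classical description does not
  specify), Bonferroni-corrected over the 39 tests at α = 0.05.
- **Gini ranking**: 500-tree random forest, `mtry = 6` (≈ √39), bootstrap
  resampling with replacement, importance = mean decrease in Gini. Ties are
  broken by canonical registry order via a stable sort; the seed is explicit,
  so rankings are bit-reproducible.
- **Internal validation**: "sampling 2/3 and testing on the remaining 1/3"
  is implemented as Monte-Carlo subsampling *without* replacement — a
  held-out remainder only exists under that reading. Each of the 1,000
  iterations trains a 2-feature logistic regression and scores the held-out
  patients; iterations whose train or test partition is single-class have no
  defined AUC and are redrawn, with the redraw count reported. The logistic
  fit carries a small fixed ridge penalty (λ = 10⁻³ on the slopes, fitted by
  IRLS in the package) so that complete separation and single-observation
  classes — both deliberately permitted at n = 22 — still give finite,
  monotone scores; the penalty does not change score order, hence not AUC.
- **Clinical/combined forests**: `mtry = 6` and `8` respectively, capped at
  the number of predictors. Two covariate presets ship
  (`clinical_covariate_preset()`): the planned set (BED/fraction, size, sex,
  ethnicity, KPS, cirrhosis) and the reported set (age, total BED,
  BED/fraction, size); the choice is configuration because the two lists
  genuinely differ in the source analysis. AUC estimates are out-of-bag and
  labelled as such. Constant covariates are dropped before fitting (they
  cannot split, and the forest code does not terminate when every predictor
  is constant) and reported with importance 0.

## The synthetic cohort generator

The generator's one texture knob is the correlation length ℓ of a Gaussian
random field: white noise smoothed with a separable Gaussian kernel of width
ℓ (default ℓ₀ = 3 mm). Larger ℓ yields larger uniform regions after
quantization, which raises GLCM energy and GLSZM large zone emphasis
together — an engineered surrogate for "texture homogeneity", not a claim
about tumour biology. Response classes differ only in the trajectory of ℓ
with delivered BED, piecewise-linear through multipliers at 20 and 40 Gy:
responders rise then fall (defaults 1.8, 1.2), non-responders mirror them
(1/1.8, 1/1.2). These defaults are deliberately strong: they define the
"planted strong effect" regime in which the pipeline is expected to recover
the signal almost perfectly, and they are not tuned per test.

Each patient owns one fixed white-noise base field, so images at different
timepoints are longitudinally linked; delivered BED changes only the
smoothing length plus fresh acquisition noise (`noise_sd`, default 0.2 of
the field SD). With zero noise and unit multipliers, baseline and checkpoint
images are bit-identical — a tested degenerate case.

Cohort shape copies the clinical study: 22 patients, 15/7
responder/poor-responder split (so single-class bootstrap partitions occur
at realistic frequency), schedules drawn from the packaged fractionation
menu, ages 49–94, sizes 1.3–8 cm. The image grid (48 × 48 × 16 at
1.5 × 1.5 × 3.0 mm) is far smaller than a clinical field of view — chosen so
a full cohort generates in seconds — but lesions always exceed ~200 voxels,
keeping zone statistics non-degenerate. Table-level surrogates
(`generate_feature_table()`) bypass images entirely: 39 standard-normal
columns with planted columns shifted ±`effect_size` by class.

What passing tests on these cohorts establish: the pipeline's algebra and
the recovery/null behaviour of the selection-plus-validation machinery. What
they cannot establish: anything about real lesions — bSSFP contrast, organ
motion, contouring variability, inter-lesion heterogeneity and true effect
sizes are all absent. In particular the clinical study's reported AUCs
(0.901 at BED₂₀ and so on) depend on unpublished patient images and are
*regime* targets for the synthetic checks, not reproducible numbers.

## Numerical and statistical fine print

- The per-cohort mean bootstrapped AUC at n = 22 is itself highly variable
  under the null (the same 22 patients are resampled every iteration, so
  iteration AUCs are strongly correlated); the null-regime check therefore
  averages mean AUCs over a dozen independently generated null cohorts
  rather than trusting a single cohort.
- Gini selection on the same patients that feed the bootstrap inflates
  apparent AUC under the null (selection bias); null checks use fixed,
  label-independent feature pairs for exactly that reason.
- Problem sizes used by the tests: oracle equivalence runs ≥ 50 random ROIs
  up to 8 × 8 × 4 at Ng ≤ 8 against O(N²) pair-enumeration, graph-component,
  run-walking and per-voxel-neighbourhood oracles; end-to-end checks use the
  default 22-patient cohort and 1,000-iteration bootstraps.
- All generators and model fits take explicit integer seeds and save/restore
  the global RNG state, so library calls never perturb a caller's random
  stream.

## Known limitations

- NIfTI-1 only; DICOM series and RT structure sets must be rasterized to
  voxel masks upstream. No registration or resampling is performed — volume
  and mask must share a grid.
- Offsets are voxel-lattice offsets; strongly anisotropic voxels make the
  13 directions geometrically unequal and no correction is attempted.
- The fractionation-alignment ceiling rule can overshoot a checkpoint
  substantially for large BED/fraction (a 50.4 Gy/fraction course realizes
  both the 20 and 40 Gy checkpoints on the same fraction-2 image); the
  realized BED column is the audit trail.
- The packaged treatment table reproduces the printed per-patient rows; the
  source's prose summary disagrees with its own table in two places (BED
  range, age summary), and the rows were taken as authoritative.
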