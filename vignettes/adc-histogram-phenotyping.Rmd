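---
title: "ADC histogram phenotyping: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ADC histogram phenotyping: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcmap)
```

## The model

Inside the contrast-enhancing region of a glioblastoma, voxel-wise apparent
diffusion coefficient (ADC) values are well described by a two-component
Gaussian mixture,

$$p(\mathrm{ADC}) = f\,N(\mu_L, \sigma_L) + (1 - f)\,N(\mu_H, \sigma_H),$$

with $f$ the proportion of voxels in the lower component. The biological
reading is that the lower mode reflects densely cellular tumor (restricted
diffusion) and the higher mode more edematous or necrotic tissue. The mean
of the lower component, ADC_L $= \mu_L$, is the phenotyping statistic: a
tumor is **high ADC_L** when $\mu_L$ strictly exceeds 1.24&nbsp;µm²/ms,
otherwise **low**. All ADC quantities in this package are in µm²/ms
(1&nbsp;µm²/ms = 10⁻³&nbsp;mm²/s); readers convert declared mm²/s volumes
on load and refuse to guess undeclared units.

The per-voxel **probability index** quantifies membership in the lower
distribution for a voxel with ADC value $x$:

$$I(x) = \frac{\int_x^\infty N(\mu_L,\sigma_L)\,dt -
               \int_0^x N(\mu_H,\sigma_H)\,dt}
              {\int_x^\infty N(\mu_L,\sigma_L)\,dt +
               \int_0^x N(\mu_H,\sigma_H)\,dt} \in [-1, 1].$$

Three implementation commitments deserve note. First, the integrals are
evaluated in closed form via the Gaussian CDF; adaptive quadrature is
retained only as a test oracle (agreement to 10⁻⁸ over a thousand random
cases). Second, the mixture weight $f$ does not enter the index: the
formula compares the component shapes only, and `probability_index()`
implements exactly that, with an `weighted = TRUE` variant available for
exploration but never used by the pipeline defaults. Third, the finite
lower limit 0 of the higher-component integral is honored exactly and the
component Gaussians are *not* truncated or renormalized; for any
physically sensible fit (component masses below zero negligible) the index
therefore runs from $+1$ at ADC $\to 0$ to $-1$ at large ADC. When both
tails underflow double precision the sign-consistent limit is returned with
a warning rather than 0/0.

## Segmentation by normalized T1 subtraction

The enhancing ROI is the set of voxels whose *normalized* post-contrast T1
signal exceeds the normalized pre-contrast signal. Normalization is
realized as z-scoring within the brain mask — the simplest transform under
which "positive difference" is meaningful across scans with arbitrary
scanner scaling, and one that makes segmentation exactly invariant to
positive affine rescaling of either input (a property the test suite
asserts). The voxel-wise difference is thresholded strictly above zero (a
`margin` parameter exists but defaults to 0), restricted to the brain mask,
and cleaned by removing 26-connected components smaller than 10 voxels.
The small-component filter and its connectivity are this package's own
standard-practice choice; whether the original analysis edited its regions
post hoc is not documented, so the filter is exposed as configuration.

A tumor is *measurable* when some axial slice of the mask contains an
in-plane bounding box of at least 10 mm × 10 mm — the "≥ 1 cm × 1 cm"
inclusion criterion, deliberately in-plane only.

## Fitting: nonlinear regression on the histogram

The ROI histogram uses 128 equal-width bins over [0, 4] µm²/ms by default.
The bin count is immaterial within broad limits — the suite checks that
$\hat\mu_L$ moves by less than 0.02 µm²/ms between 64 and 256 bins on
50,000-voxel samples — and the range covers physiological ADC up to CSF.
Out-of-range voxels are counted and reported, never silently dropped.
Histograms are density-normalized, and the objective is unweighted least
squares between the model density and the histogram density. This mirrors
curve-fitting practice for this analysis; fitting counts with Poisson
weights would be a defensible alternative, but the unweighted form is kept
for transparency and because parameter recovery at realistic ROI sizes is
already well inside tolerance (median $|\hat\mu_L - \mu_L| \le 0.03$
µm²/ms at 10,000 voxels across 50 simulated subjects, cross-checked
against an expectation–maximization fit of the raw voxel values).

Optimization is bounded L-BFGS-B ($f \in [0.01, 0.99]$,
$\sigma \in [0.01, 2]$ µm²/ms, means inside the histogram range) with a
deterministic multi-start grid: $\mu_L$ from the 20th/40th percentile,
$\mu_H$ from the 60th/80th, $\sigma$ at IQR/2 × {0.5, 1}, $f = 0.5$. The
best start by residual sum of squares wins, components are relabelled so
$\mu_L \le \mu_H$, and a line-search abort at a solution no worse than a
cleanly converged start still counts as converged. Optimizer failure is
reported through `converged = FALSE`, never as an exception.

**Degeneracy rule.** When the data do not support two components —
$f \le 0.02$, $f \ge 0.98$, or $|\mu_H - \mu_L| < 0.05$ µm²/ms — the fit
is flagged degenerate and the lower-mean component is still reported as
ADC_L. On an exactly single-Gaussian input the flag trips and the reported
ADC_L lands within 0.05 of the single mean. A caveat worth knowing: on
*sampled* single-Gaussian data, least squares can legitimately place a
small second component ($f$ just above the 0.02 cutoff) to absorb sampling
noise; the flag is a rule on the fitted parameters, not a hypothesis test
for bimodality.

## Biopsy-target selection

Targets are 5 mm cubes snapped to the voxel grid
(edge = round(5 mm / voxel size) voxels per axis, minimum 1). A cube is
admissible when it lies wholly inside the ROI, avoids the caller-supplied
exclusion mask (eloquent cortex, vasculature — atlases are out of scope),
and does not overlap previously chosen targets. Each pair greedily takes
the admissible cube with the *highest* mean index (the low-ADC target,
i.e. most confidently in the lower distribution) and the one with the
*lowest*. How an operator would place targets within high/low regions is a
judgment call in practice; greedy mean-index optimization with a
lexicographic tie-break on the cube start index is this package's
deterministic operationalization.

## Cohort statistics

The association layer mirrors a conventional Prism-style analysis:
Pearson correlation with the two-sided $t$-transform $p$-value;
pooled-variance Student's t-tests (Welch available as an option, since the
original tool default is not documented); sample-SD ($n-1$) z-scoring
throughout; Kaplan–Meier product-limit curves with the two-group log-rank
test, $p$ from the upper $\chi^2_1$ tail. Conventions worth stating:
median survival is the *earliest* time the step function falls to ≤ 0.5
(undefined — `NA`, serialized as null — when it never does); median-split
ties go to "low", keeping "high" strictly above the median in the same way
the phenotype threshold is strict. The intratumoral branch z-scores both
ADC_L and expression *within* tumor before correlating across sites — a
reading of a partially specified normalization, surfaced here so users can
pre-normalize differently and skip the branch. No multiple-testing
correction is applied anywhere, deliberately mirroring the analysis style
this package reproduces; treat the suite's $p$-values accordingly.

## What the synthetic generator emulates — and what it does not

`make_subject_volume()` builds an ellipsoidal lesion whose ADC voxels are
drawn from a specified mixture, a CSF-like background Gaussian
(3.1 ± 0.08 µm²/ms) chosen to be disjoint from any plausible lesion
mixture so that segmentation leakage is visible in the histogram, and a
pre/post T1 pair sharing one anatomical field (mean 100, SD 10 signal
units) with +5 enhancement added inside the lesion on the post volume.
Because the anatomy is shared, subtraction cancels it exactly; the only
corruption of the subtraction map is the z-score scale mismatch introduced
by the lesion's own contribution to the post-volume variance, which grows
with the *square* of the enhancement amplitude. Keeping the enhancement
below the anatomical SD keeps the background false-positive rate near
$\Phi(-2\,\sigma_{T1}/E) \approx \Phi(-4)$, and segmentation recovers the
ROI at Dice ≥ 0.9 (in practice 1.0) across seeds.

`make_cohort()` draws a true ADC_L per subject uniformly over
0.31–2.2 µm²/ms — the observed range in the treated cohort this generator
emulates; the distribution across patients is not documented beyond that
range, so uniform is a modeling choice, not data. Expression is
`intercept + slope·ADC_L + N(0, sd)`; the defaults (slope 1, noise SD 1)
give a population R² ≈ 0.23, in the range of reported imaging–expression
correlations. Survival is exponential with rate ln 2 / median per
phenotype group (defaults 9.33 vs 5.87 months about the 1.24 threshold) —
the simplest hazard consistent with a stated median, and closed-form
checkable; right censoring hits each subject with probability 0.15
(uniform censoring time below the true event time). One integer seed
drives everything, with per-subject sub-streams derived deterministically,
and generation never perturbs the caller's RNG state.

What the generator does **not** emulate: MRI noise spectra, bias fields,
partial-volume averaging at the lesion rim, registration error, multi-
scanner harmonization, or any spatial texture within the lesion (voxels
are exchangeable draws). Passing tests therefore demonstrate that the
*analysis chain* is correct under its own model assumptions — they say
nothing about robustness to acquisition artifacts, which real deployments
must assess separately.

## Problem sizes used by the test suite

The suite exercises the chain at sizes chosen to make sampling error
negligible relative to the tolerances: 50,000-voxel samples for
single-fit checks, 50 subjects × 10,000 ROI voxels for the parameter-
recovery sweep, 20 seeds for segmentation fidelity, 500 replicates for the
null-calibration bands ([0.03, 0.07] empirical type-I error at
$\alpha = 0.05$), and 32³–40³ voxel grids for volumetric work. These are
the package's reference conditions; all are plain function arguments and
scale up directly.

## Known limitations

* Two components only; no model-order selection. A genuinely unimodal or
  trimodal histogram is forced into the two-Gaussian frame (the degeneracy
  flag covers the unimodal case).
* The index formula assumes the fitted components have negligible mass
  below zero; for pathological fits with $\mu/\sigma$ small the $+1$ limit
  at ADC $\to 0$ is not attained (the implementation still returns the
  well-defined ratio).
* Registration, skull stripping and ADC map computation from raw
  diffusion-weighted acquisitions are upstream of this package.
* Cox modeling and multivariable adjustment are out of scope; the survival
  layer is two-group Kaplan–Meier / log-rank only.
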