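# adcmap

Quantitative diffusion-MRI phenotyping of contrast-enhancing brain tumors,
from raw co-registered volumes to cohort-level statistics.

Glioblastomas are heterogeneous on diffusion-weighted MRI: the apparent
diffusion coefficient (ADC) inside the enhancing tumor typically shows a
bimodal histogram, and the mean of its *lower* mode (ADC_L) is a prognostic
imaging phenotype — tumors with ADC_L above 1.24 µm²/ms behave differently
under anti-angiogenic therapy than tumors below it. `adcmap` implements that
analysis end to end for neuro-imaging researchers:

1. **Enhancing-ROI segmentation** — pre- and post-contrast T1 volumes are
   intensity-normalized (z-scored within a brain mask) and subtracted
   voxel-wise; strictly positive voxels, cleaned of small 26-connected
   components, form the region of interest.
2. **ADC histogram mixture model** — the ROI's ADC histogram is fit by
   nonlinear least squares with a two-component Gaussian mixture

   p(ADC) = f·N(µ_L, σ_L) + (1 − f)·N(µ_H, σ_H),

   where *f* is the proportion of voxels in the lower component; µ_L is the
   tumor's ADC_L. The fit is bounded, multi-started from quantile-based
   initial values, and relabelled so µ_L ≤ µ_H. Tumors are called **high**
   when ADC_L > 1.24 µm²/ms (strict inequality).
3. **Probability-index maps and biopsy targets** — each ROI voxel with ADC
   value x gets the index

   I(x) = [∫ₓ^∞ N(µ_L,σ_L) dt − ∫₀ˣ N(µ_H,σ_H) dt] /
          [∫ₓ^∞ N(µ_L,σ_L) dt + ∫₀ˣ N(µ_H,σ_H) dt] ∈ [−1, 1],

   with +1 meaning the voxel certainly belongs to the lower distribution.
   Evaluated in closed form via Gaussian CDFs. Paired 5 mm × 5 mm × 5 mm
   biopsy targets (highest and lowest mean index, non-overlapping, outside a
   caller-supplied exclusion mask) are selected greedily and
   deterministically.
4. **Cohort association layer** — Pearson correlation of expression vs
   ADC_L, pooled-variance t-tests between phenotypes, within-tumor z-score
   normalization for multi-site biopsies, median-split stratification, and
   Kaplan–Meier / log-rank survival comparison.
5. **Synthetic-data generator** — subjects with a known ground-truth mixture
   and cohorts with configurable expression coupling, survival medians and
   censoring, so the whole chain is testable without patient data.

Volumes are NIfTI-1 (via RNifti); tables are tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` figures. All ADC values are in
µm²/ms (1 µm²/ms = 10⁻³ mm²/s; readers convert declared mm²/s inputs).

## Worked example

```r
library(adcmap)

spec <- mixture_spec(f = 0.6, mu_L = 1.0, sigma_L = 0.15,
                     mu_H = 1.9, sigma_H = 0.25)
subj <- make_subject_volume(spec, seed = 42)
res  <- analyze_subject(subj$pre_t1, subj$post_t1, subj$adc,
                        brain_mask = subj$brain_mask)
res
#> <adc_pipeline_result>
#>   ROI: 2176 voxels (2.18 cc), measurable: TRUE
#>   ADC_L = 0.998 um^2/ms -> low phenotype (threshold 1.24)
#>   2 biopsy target(s) selected
```

The segmentation recovered a 2.18 cc enhancing ROI that satisfies the
≥ 1 cm × 1 cm measurable-disease criterion; the fitted ADC_L of 0.998 µm²/ms
(truth: 1.0) is below 1.24, so the tumor is called a low-ADC_L phenotype,
and one high/low target pair was placed. The fit itself:

```r
res$fit
#> <double_gaussian_fit>
#>   ADC_L = 0.998 (sd 0.142), ADC_H = 1.909 (sd 0.254), f = 0.587
#>   rss = 0.3605, converged = TRUE
```

Cohort level, with the generator's defaults (172 subjects, ADC_L uniform on
0.31–2.2 µm²/ms, group median survival 9.33 vs 5.87 months):

```r
cohort <- make_cohort(n_subjects = 172, seed = 42)
run_association_suite(cohort)
#> <adc_association_report> n = 172, threshold = 1.24 um^2/ms
#>   analysis                statistic     value        p     n
#> 1 expression_vs_adcl      r_squared     0.241 7.95e-12   172
#> 2 expression_by_phenotype t            -6.52  7.87e-10   172
#> 3 survival_by_phenotype   logrank_chi2  5.43  1.98e- 2   172
#> 4 survival_by_expression  logrank_chi2  0.131 7.18e- 1   172
```

Expression rises with ADC_L (R² = 0.24), high-ADC_L tumors have higher
expression (the negative t compares low minus high), and the planted
survival advantage of the high phenotype is detected by the log-rank test
(p = 0.02). Stratifying survival by median expression — a noisier proxy for
the phenotype — is not significant at this effect size.

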