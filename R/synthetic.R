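#' Simulate one subject's image volumes
#'
#' Builds the volumes the imaging pipeline consumes, with known ground truth:
#' an ellipsoidal "enhancing tumor" ROI whose ADC voxels are drawn from a
#' two-Gaussian mixture, a background ADC drawn from a single Gaussian well
#' separated from the lesion mixture (so segmentation leakage is detectable
#' in the histogram), and a pre/post-contrast T1 pair that are identical
#' except for positive enhancement added inside the ROI — so normalized T1
#' subtraction recovers the ROI.
#'
#' @param spec A [mixture_spec()]: the ground-truth ADC mixture of the lesion.
#' @param grid_shape Integer length-3 array dimensions (voxels).
#' @param voxel_size_mm Voxel spacing (mm), length 1 or 3.
#' @param lesion_radius_mm Ellipsoid semi-axes in mm (length 1 or 3); must be
#'   positive and the lesion must fit inside the brain mask.
#' @param seed Integer seed; output is fully reproducible.
#' @param center_mm Optional lesion center in mm (defaults to grid center).
#' @param background_mean,background_sd Background ADC Gaussian (um^2/ms);
#'   default 3.1 +/- 0.08, CSF-like and disjoint from typical lesion mixtures.
#' @param enhancement Positive T1 signal added inside the ROI on the
#'   post-contrast volume (arbitrary signal units). Pre and post share the
#'   same anatomical field (same brain, co-registered), so subtraction
#'   cancels anatomy exactly; keep the enhancement below `t1_sd` so the
#'   lesion's contribution to the post-volume variance does not tilt the
#'   z-score scaling (the background false-positive rate of normalized
#'   subtraction is about \eqn{\Phi(-2\,t1\_sd/enhancement)}).
#' @param t1_mean,t1_sd Mean and SD of the anatomical T1 field (signal
#'   units).
#'
#' @return A list of class `synthetic_subject`: `adc` ([adc_volume()]),
#'   `pre_t1`, `post_t1` ([anatomical_volume()]), `roi_mask` and `brain_mask`
#'   (logical arrays), and `truth` (the generating `mixture_spec`).
#' @examples
#' spec <- mixture_spec(0.6, 1.0, 0.15, 1.9, 0.25)
#' subj <- make_subject_volume(spec, grid_shape = c(32, 32, 32),
#'                             lesion_radius_mm = 8, seed = 1)
#' sum(subj$roi_mask)
#' @export
make_subject_volume <- function(spec, grid_shape = c(32, 32, 32),
                                voxel_size_mm = c(1, 1, 1),
                                lesion_radius_mm = 8, seed = 1,
                                center_mm = NULL,
                                background_mean = 3.1, background_sd = 0.08,
                                enhancement = 5, t1_mean = 100, t1_sd = 10) {
  validate_mixture_spec(spec)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 4)) {
    rlang::abort("grid_shape must be 3 dimensions of at least 4 voxels")
  }
  vs <- check_voxel_size(voxel_size_mm)
  r <- as.numeric(lesion_radius_mm)
  if (length(r) == 1) r <- rep(r, 3)
  if (any(r <= 0)) rlang::abort("empty lesion: lesion_radius_mm must be > 0")

  extent <- grid_shape * vs
  if (is.null(center_mm)) center_mm <- extent / 2
  # brain: centered ellipsoid filling 90% of each half-extent
  brain_radii <- 0.45 * extent
  brain_mask <- ellipsoid_mask(grid_shape, vs, extent / 2, brain_radii)
  roi_mask <- ellipsoid_mask(grid_shape, vs, center_mm, r)
  if (!sum(roi_mask)) rlang::abort("empty lesion: no voxel falls inside the ellipsoid")
  if (any(center_mm - r < 0) || any(center_mm + r > extent)) {
    rlang::abort("lesion exceeds grid")
  }
  if (any(roi_mask & !brain_mask)) {
    rlang::abort("lesion exceeds brain mask; shrink the lesion or recenter it")
  }

  n_vox <- prod(grid_shape)
  n_roi <- sum(roi_mask)
  with_local_seed(seed, {
    adc <- array(stats::rnorm(n_vox, background_mean, background_sd), grid_shape)
    adc[roi_mask] <- sample_mixture(spec, n_roi,
                                    seed = stats::runif(1, 1, 2^30))
    adc[adc < 0] <- 0
    pre <- array(stats::rnorm(n_vox, mean = t1_mean, sd = t1_sd), grid_shape)
    post <- pre
    post[roi_mask] <- post[roi_mask] + enhancement
  })

  structure(list(
    adc = adc_volume(adc, vs),
    pre_t1 = anatomical_volume(pre, vs),
    post_t1 = anatomical_volume(post, vs),
    roi_mask = roi_mask,
    brain_mask = brain_mask,
    truth = spec,
    seed = as.integer(seed)
  ), class = "synthetic_subject")
}

ellipsoid_mask <- function(grid_shape, voxel_size_mm, center_mm, radii_mm) {
  # voxel centers at (index - 0.5) * spacing, 1-based indices
  cx <- (seq_len(grid_shape[1]) - 0.5) * voxel_size_mm[1]
  cy <- (seq_len(grid_shape[2]) - 0.5) * voxel_size_mm[2]
  cz <- (seq_len(grid_shape[3]) - 0.5) * voxel_size_mm[3]
  dx2 <- ((cx - center_mm[1]) / radii_mm[1])^2
  dy2 <- ((cy - center_mm[2]) / radii_mm[2])^2
  dz2 <- ((cz - center_mm[3]) / radii_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "<synthetic_subject> grid %s, ROI %d voxels, truth ADC_L = %.3f um^2/ms\n",
    paste(dim(x$adc), collapse = "x"), sum(x$roi_mask), x$truth$mu_L))
  invisible(x)
}

#' Simulate a cohort table (and optionally per-subject volumes)
#'
#' Generates the tabular structure the association layer assumes: a true
#' ADC_L per subject drawn uniformly over `adcl_range`; expression linearly
#' coupled to ADC_L with additive Gaussian noise; and survival drawn from an
#' exponential distribution whose median depends on the diffusion phenotype
#' (high when ADC_L exceeds `threshold`), with uniform right censoring.
#' Defaults mirror the bevacizumab-treated cohort the analysis targets:
#' 172 subjects, ADC_L spanning 0.31-2.2 um^2/ms, and group median survival
#' 9.33 vs 5.87 months about the 1.24 um^2/ms threshold.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param adcl_range Interval of true ADC_L across subjects (um^2/ms).
#' @param expr_slope,expr_intercept Linear coupling of expression to ADC_L.
#' @param expr_noise_sd Residual SD of expression (>= 0); 0 gives an exactly
#'   linear relationship.
#' @param median_surv_high,median_surv_low Group median survival (months).
#' @param censor_prob Probability a subject is right-censored, in \[0, 1).
#'   A censored subject's observed time is uniform on (0, true time).
#' @param threshold Phenotype threshold on true ADC_L (um^2/ms).
#' @param seed Integer seed.
#' @param volumes If `TRUE`, attach a `subject` list-column of
#'   [make_subject_volume()] outputs whose ground-truth mixture has
#'   `mu_L = adcl_true`; the higher component sits `delta_h` above it.
#' @param delta_h,sigma_l,sigma_h,f Mixture shape used when `volumes = TRUE`.
#' @param grid_shape,voxel_size_mm,lesion_radius_mm Volume geometry passed to
#'   [make_subject_volume()].
#'
#' @return A tibble with columns `subject_id`, `adcl_true`, `phenotype`
#'   (factor low/high), `expression`, `surv_months`, `event` (1 = death
#'   observed, 0 = censored) and, when `volumes = TRUE`, `subject`.
#' @examples
#' cohort <- make_cohort(n_subjects = 20, seed = 1)
#' head(cohort)
#' @export
make_cohort <- function(n_subjects = 172, adcl_range = c(0.31, 2.2),
                        expr_slope = 1, expr_intercept = 0,
                        expr_noise_sd = 1,
                        median_surv_high = 9.33, median_surv_low = 5.87,
                        censor_prob = 0.15, threshold = 1.24, seed = 1,
                        volumes = FALSE, delta_h = 0.9,
                        sigma_l = 0.15, sigma_h = 0.25, f = 0.6,
                        grid_shape = c(32, 32, 32), voxel_size_mm = c(1, 1, 1),
                        lesion_radius_mm = 8) {
  if (n_subjects < 2) rlang::abort("make_cohort: n_subjects must be >= 2")
  if (expr_noise_sd < 0) rlang::abort("make_cohort: expr_noise_sd must be >= 0")
  if (median_surv_high <= 0 || median_surv_low <= 0) {
    rlang::abort("make_cohort: group median survival must be > 0")
  }
  if (censor_prob < 0 || censor_prob >= 1) {
    rlang::abort("make_cohort: censor_prob must be in [0, 1)")
  }
  if (length(adcl_range) != 2 || diff(adcl_range) < 0 || adcl_range[1] <= 0) {
    rlang::abort("make_cohort: adcl_range must be a positive increasing interval")
  }

  tab <- with_local_seed(seed, {
    adcl <- stats::runif(n_subjects, adcl_range[1], adcl_range[2])
    expression <- expr_intercept + expr_slope * adcl +
      stats::rnorm(n_subjects, 0, expr_noise_sd)
    high <- adcl > threshold
    med <- ifelse(high, median_surv_high, median_surv_low)
    t_true <- stats::rexp(n_subjects, rate = log(2) / med)
    censored <- stats::runif(n_subjects) < censor_prob
    surv <- ifelse(censored, stats::runif(n_subjects, 0, 1) * t_true, t_true)
    subject_seeds <- sample.int(2^30, n_subjects)
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n_subjects)),
      adcl_true = adcl,
      phenotype = factor(ifelse(high, "high", "low"), levels = c("low", "high")),
      expression = expression,
      surv_months = surv,
      event = as.integer(!censored),
      .seed = subject_seeds
    )
  })

  if (volumes) {
    tab$subject <- purrr::map2(tab$adcl_true, tab$.seed, function(mu_l, s) {
      make_subject_volume(
        mixture_spec(f = f, mu_L = mu_l, sigma_L = sigma_l,
                     mu_H = mu_l + delta_h, sigma_H = sigma_h),
        grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
        lesion_radius_mm = lesion_radius_mm, seed = s)
    })
  }
  tab$.seed <- NULL
  attr(tab, "cohort_seed") <- as.integer(seed)
  tab
}

#' Write a cohort table as CSV
#'
#' Persists the tabular columns (`subject_id`, `adcl_true`, `expression`,
#' `surv_months`, `event`, plus `phenotype`) with a header row; the `subject`
#' list-column, if present, is dropped.
#'
#' @param cohort A tibble from [make_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  keep <- setdiff(names(cohort), "subject")
  utils::write.csv(as.data.frame(cohort[keep]), path, row.names = FALSE)
  invisible(path)
}
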