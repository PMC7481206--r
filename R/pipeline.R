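#' Pipeline configuration
#'
#' Bundles the tunable parameters of the single-subject imaging pipeline,
#' validated once up front. The configuration is echoed verbatim into every
#' output directory so a run can be reproduced.
#'
#' @param threshold ADC_L phenotype threshold (um^2/ms, default 1.24).
#' @param n_bins,hist_range Histogram binning (default 128 bins over
#'   \[0, 4\] um^2/ms).
#' @param min_roi_voxels Minimum ROI size for histogram analysis.
#' @param n_starts,seed Mixture-fit multi-start count and seed.
#' @param n_pairs,edge_mm Biopsy-target pair count and cube edge (5 mm).
#' @param min_component_voxels Segmentation small-component filter.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = 1.24, n_bins = 128,
                            hist_range = c(0, 4), min_roi_voxels = 100,
                            n_starts = 8, seed = 1, n_pairs = 1, edge_mm = 5,
                            min_component_voxels = 10) {
  cfg <- list(threshold = threshold, n_bins = as.integer(n_bins),
              hist_range = as.numeric(hist_range),
              min_roi_voxels = as.integer(min_roi_voxels),
              n_starts = as.integer(n_starts), seed = as.integer(seed),
              n_pairs = as.integer(n_pairs), edge_mm = edge_mm,
              min_component_voxels = as.integer(min_component_voxels))
  stopifnot(cfg$threshold > 0, cfg$n_bins >= 4,
            length(cfg$hist_range) == 2, diff(cfg$hist_range) > 0,
            cfg$min_roi_voxels >= 4, cfg$n_starts >= 1, cfg$n_pairs >= 1,
            cfg$edge_mm > 0, cfg$min_component_voxels >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file whose keys
#'   match the arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg[intersect(names(cfg),
                                         names(formals(pipeline_config)))])
}

#' Analyze one subject end to end
#'
#' Runs the full imaging chain on in-memory volumes: T1-subtraction
#' segmentation, measurability check, ADC histogram, double-Gaussian fit,
#' phenotype call, probability-index map, and biopsy-target selection. Any
#' stage failure is re-raised with the stage name so partial runs are
#' diagnosable.
#'
#' @param pre,post Pre-/post-contrast [anatomical_volume()]s.
#' @param adc An [adc_volume()] on the same grid.
#' @param brain_mask,exclusion_mask Optional logical arrays.
#' @param config A [pipeline_config()].
#' @return A list of class `adc_pipeline_result`: `segmentation`,
#'   `measurable`, `histogram`, `fit`, `phenotype`, `probability_map`,
#'   `targets`, and the `config`.
#' @examples
#' subj <- make_subject_volume(mixture_spec(0.6, 1.0, 0.15, 1.9, 0.25),
#'                             seed = 3)
#' res <- analyze_subject(subj$pre_t1, subj$post_t1, subj$adc,
#'                        brain_mask = subj$brain_mask)
#' res$phenotype$label
#' @export
analyze_subject <- function(pre, post, adc, brain_mask = NULL,
                            exclusion_mask = NULL,
                            config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("stage '", name, "': ", conditionMessage(e)))
    })
  }
  seg <- stage("segment", t1_subtraction_mask(
    pre, post, brain_mask,
    min_component_voxels = config$min_component_voxels))
  measurable <- stage("segment", check_measurable(seg))
  hist <- stage("histogram", build_adc_histogram(
    adc, seg, n_bins = config$n_bins, range = config$hist_range,
    min_voxels = config$min_roi_voxels))
  fit <- stage("fit", fit_double_gaussian(
    hist, n_starts = config$n_starts, seed = config$seed))
  phen <- stage("classify", classify_phenotype(fit, config$threshold))
  pmap <- stage("probmap", make_probability_map(adc, seg, fit))
  targets <- stage("targets", tryCatch(
    select_targets(pmap, exclusion_mask, n_pairs = config$n_pairs,
                   edge_mm = config$edge_mm),
    error = function(e) {
      if (grepl("ROI too small", conditionMessage(e))) NULL else stop(e)
    }))
  structure(list(
    segmentation = seg, measurable = measurable, histogram = hist,
    fit = fit, phenotype = phen, probability_map = pmap, targets = targets,
    config = config
  ), class = "adc_pipeline_result")
}

#' @export
print.adc_pipeline_result <- function(x, ...) {
  cat("<adc_pipeline_result>\n")
  cat(sprintf("  ROI: %d voxels (%.2f cc), measurable: %s\n",
              x$segmentation$voxel_count, x$segmentation$volume_cc,
              x$measurable))
  cat(sprintf("  ADC_L = %.3f um^2/ms -> %s phenotype (threshold %.2f)\n",
              x$fit$mu_L, as.character(x$phenotype$label),
              x$phenotype$threshold))
  if (!is.null(x$targets)) {
    cat(sprintf("  %d biopsy target(s) selected\n", nrow(x$targets)))
  }
  invisible(x)
}

#' Run the pipeline on files and persist every stage
#'
#' File-level front end to [analyze_subject()]: reads NIfTI inputs, runs the
#' chain, and writes each stage's output plus a run manifest (tool version,
#' config echo, input checksums, seed, timestamp) into `out_dir`. Inputs are
#' validated before any output is written.
#'
#' @param pre_path,post_path,adc_path NIfTI input files.
#' @param out_dir Output directory (created if missing).
#' @param brain_mask_path,exclusion_mask_path Optional NIfTI masks
#'   (nonzero = true).
#' @param adc_unit ADC unit when no sidecar declares it (`"um2/ms"` or
#'   `"mm2/s"`).
#' @param config A [pipeline_config()].
#' @return The `adc_pipeline_result`, invisibly; outputs under `out_dir`:
#'   `enhancement_mask.nii.gz`, `histogram.csv`, `fit.json`,
#'   `probability_map.nii.gz` (NaN = outside ROI), `targets.csv`,
#'   `manifest.json`, `config.json`.
#' @export
run_pipeline <- function(pre_path, post_path, adc_path, out_dir,
                         brain_mask_path = NULL, exclusion_mask_path = NULL,
                         adc_unit = NULL, config = pipeline_config()) {
  inputs <- c(pre = pre_path, post = post_path, adc = adc_path,
              brain_mask = brain_mask_path, exclusion = exclusion_mask_path)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    rlang::abort(paste0("stage 'read': missing input file(s): ",
                        paste(missing, collapse = ", ")))
  }
  pre <- read_anatomical_volume(pre_path)
  post <- read_anatomical_volume(post_path)
  adc <- read_adc_volume(adc_path, unit = adc_unit)
  brain <- if (!is.null(brain_mask_path)) {
    as.array(read_anatomical_volume(brain_mask_path)) != 0
  }
  excl <- if (!is.null(exclusion_mask_path)) {
    as.array(read_anatomical_volume(exclusion_mask_path)) != 0
  }
  res <- analyze_subject(pre, post, adc, brain_mask = brain,
                         exclusion_mask = excl, config = config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask_arr <- array(as.numeric(res$segmentation$mask), dim(res$segmentation$mask))
  attr(mask_arr, "voxel_size_mm") <- res$segmentation$voxel_size_mm
  write_volume(mask_arr, file.path(out_dir, "enhancement_mask.nii.gz"))
  write_histogram_csv(res$histogram, file.path(out_dir, "histogram.csv"))
  write_fit_json(res$fit, file.path(out_dir, "fit.json"))
  write_volume(res$probability_map,
               file.path(out_dir, "probability_map.nii.gz"))
  if (!is.null(res$targets)) {
    write_targets_csv(res$targets, file.path(out_dir, "targets.csv"))
  }
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tool = "adcmap",
    version = as.character(utils::packageVersion("adcmap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    seed = config$seed,
    inputs = as.list(tools::md5sum(inputs)),
    phenotype = as.character(res$phenotype$label),
    adcl = res$fit$mu_L,
    measurable = res$measurable)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
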