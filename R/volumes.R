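#' 3-D image volumes with voxel spacing
#'
#' Light containers for the rasters the pipeline consumes: an `adc_volume`
#' carries ADC values in um^2/ms; an `anatomical_volume` carries arbitrary
#' T1 signal units. Both are plain 3-D arrays with a `voxel_size_mm`
#' attribute, so array arithmetic works unchanged.
#'
#' @param values A 3-D numeric array.
#' @param voxel_size_mm Voxel edge lengths in mm (length 1 or 3, positive).
#' @param unit ADC unit tag, `"um2/ms"` (canonical) or `"mm2/s"`; values
#'   declared in mm^2/s are converted to um^2/ms (x 1000) on construction and
#'   the original unit recorded.
#' @return An object of class `adc_volume` or `anatomical_volume`.
#' @export
adc_volume <- function(values, voxel_size_mm = c(1, 1, 1), unit = "um2/ms") {
  values <- check_volume_array(values)
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  unit <- match.arg(unit, c("um2/ms", "mm2/s"))
  original_unit <- unit
  if (unit == "mm2/s") values <- values * 1000
  structure(values, voxel_size_mm = voxel_size_mm, unit = "um2/ms",
            original_unit = original_unit,
            class = c("adc_volume", "array"))
}

#' @rdname adc_volume
#' @export
anatomical_volume <- function(values, voxel_size_mm = c(1, 1, 1)) {
  values <- check_volume_array(values)
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  structure(values, voxel_size_mm = voxel_size_mm,
            class = c("anatomical_volume", "array"))
}

check_volume_array <- function(values) {
  if (length(dim(values)) != 3) {
    rlang::abort("expected 3-D volume")
  }
  storage.mode(values) <- "double"
  values
}

check_voxel_size <- function(voxel_size_mm) {
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (length(voxel_size_mm) != 3 || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    rlang::abort("voxel_size_mm must be 3 positive finite lengths (mm)")
  }
  as.numeric(voxel_size_mm)
}

#' @export
print.adc_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<adc_volume> %d x %d x %d voxels, spacing %s mm, unit um2/ms\n",
              d[1], d[2], d[3],
              paste(signif(voxel_size(x), 3), collapse = " x ")))
  invisible(x)
}

#' @export
print.anatomical_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<anatomical_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(voxel_size(x), 3), collapse = " x ")))
  invisible(x)
}

#' Voxel spacing of a volume
#'
#' @param vol A volume created by [adc_volume()], [anatomical_volume()], or
#'   read from NIfTI.
#' @return Numeric length-3 vector of voxel edge lengths in mm.
#' @export
voxel_size <- function(vol) {
  vs <- attr(vol, "voxel_size_mm")
  if (is.null(vs)) c(1, 1, 1) else vs
}

#' Read and write NIfTI-1 volumes
#'
#' `read_adc_volume()` loads a 3-D ADC map, taking voxel spacing from the
#' NIfTI header. NIfTI has no unit field for diffusivity, so the unit must
#' come either from the `unit` argument or from a BIDS-style JSON sidecar
#' (same path with `.json` in place of `.nii`/`.nii.gz`, field `Units` or
#' `unit`); values declared in mm^2/s are multiplied by 1000 on load. With
#' neither source available the reader refuses rather than guess.
#'
#' @param path Path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param unit Explicit ADC unit, `"um2/ms"` or `"mm2/s"`; overrides any
#'   sidecar.
#' @return An [adc_volume()] (values in um^2/ms) or [anatomical_volume()].
#' @export
read_adc_volume <- function(path, unit = NULL) {
  img <- read_nifti_3d(path)
  if (is.null(unit)) unit <- sidecar_unit(path)
  if (is.null(unit)) {
    rlang::abort(paste0(
      "ADC unit for '", path, "' is not declared; pass unit = \"um2/ms\" or ",
      "\"mm2/s\" explicitly (or provide a JSON sidecar with a Units field)"))
  }
  adc_volume(img$values, img$voxel_size_mm, unit = unit)
}

#' @rdname read_adc_volume
#' @export
read_anatomical_volume <- function(path) {
  img <- read_nifti_3d(path)
  anatomical_volume(img$values, img$voxel_size_mm)
}

read_nifti_3d <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) {
    rlang::abort(paste0("expected 3-D volume, got ", length(dim(img)),
                        "-D: ", path))
  }
  list(values = array(as.numeric(img), dim = dim(img)),
       voxel_size_mm = abs(RNifti::pixdim(img))[1:3])
}

sidecar_unit <- function(path) {
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (identical(sidecar, path) || !file.exists(sidecar)) return(NULL)
  meta <- jsonlite::read_json(sidecar)
  u <- meta$Units %||% meta$unit %||% meta$Unit
  if (is.null(u)) return(NULL)
  u <- tolower(gsub("[^a-z0-9/]", "", tolower(as.character(u))))
  if (u %in% c("um2/ms", "m2/ms")) return("um2/ms")
  if (u %in% c("mm2/s")) return("mm2/s")
  rlang::abort(paste0("unrecognized ADC unit in sidecar: ", u))
}

#' @rdname read_adc_volume
#' @param vol Volume (or plain 3-D array) to write; `NA`/`NaN` values are
#'   preserved (used as the undefined sentinel in probability maps).
#' @export
write_volume <- function(vol, path) {
  vs <- voxel_size(vol)
  arr <- array(as.numeric(vol), dim = dim(vol))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; used to score segmentation against the
#' generator's ground-truth ROI.
#'
#' @param a,b Logical arrays of identical shape.
#' @return Dice coefficient in \[0, 1\] (1 when both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) rlang::abort("dice_coefficient: shape mismatch")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
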