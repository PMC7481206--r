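#' Intensity-normalize a volume within a brain mask
#'
#' Z-scores the voxel intensities within the brain mask (sample SD, n - 1
#' denominator) and zeroes everything outside it. Normalizing both members
#' of a pre/post-contrast T1 pair the same way makes their voxel-wise
#' difference comparable across scans, which is what gives the "positive
#' difference" rule of [t1_subtraction_mask()] its meaning. Z-scoring is
#' invariant to positive affine rescaling of the input.
#'
#' @param vol An [anatomical_volume()] (or plain 3-D array).
#' @param brain_mask Logical array of the same shape; `NULL` means the whole
#'   grid.
#' @return An [anatomical_volume()] with masked mean 0 and SD 1.
#' @export
normalize_volume <- function(vol, brain_mask = NULL) {
  vol_arr <- check_volume_array(vol)
  vs <- voxel_size(vol)
  brain_mask <- resolve_mask(brain_mask, dim(vol_arr))
  if (!any(brain_mask)) rlang::abort("normalize_volume: brain_mask is empty")
  v <- vol_arr[brain_mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    rlang::abort("normalize_volume: zero variance within the brain mask")
  }
  out <- array(0, dim(vol_arr))
  out[brain_mask] <- (v - mean(v)) / s
  anatomical_volume(out, vs)
}

resolve_mask <- function(mask, dims) {
  if (is.null(mask)) return(array(TRUE, dims))
  if (!identical(dim(mask), as.integer(dims)) &&
      !identical(dim(mask), dims)) {
    rlang::abort("mask shape does not match volume shape")
  }
  array(as.logical(mask), dims)
}

#' Segment the contrast-enhancing ROI by normalized T1 subtraction
#'
#' Both volumes are intensity-normalized within the brain mask, subtracted
#' voxel-wise (post minus pre), and voxels with a strictly positive
#' difference are kept. Connected components (26-connectivity) smaller than
#' `min_component_voxels` are removed to suppress salt noise. The volumes
#' are assumed already co-registered.
#'
#' @param pre,post Pre- and post-contrast [anatomical_volume()]s of equal
#'   shape.
#' @param brain_mask Logical array restricting the analysis; `NULL` = whole
#'   grid.
#' @param min_component_voxels Minimum connected-component size kept
#'   (default 10).
#' @param margin Threshold on the normalized difference (default 0, i.e.
#'   strictly positive values).
#' @return An object of class `enhancement_mask`: `mask` (logical array),
#'   `voxel_count`, and `volume_cc` (voxel count x voxel volume, in cc).
#' @examples
#' subj <- make_subject_volume(mixture_spec(0.6, 1.0, 0.15, 1.9, 0.25),
#'                             seed = 1)
#' seg <- t1_subtraction_mask(subj$pre_t1, subj$post_t1, subj$brain_mask)
#' dice_coefficient(seg$mask, subj$roi_mask)
#' @export
t1_subtraction_mask <- function(pre, post, brain_mask = NULL,
                                min_component_voxels = 10, margin = 0) {
  if (!identical(dim(pre), dim(post))) {
    rlang::abort("t1_subtraction_mask: pre/post shape mismatch")
  }
  vs <- voxel_size(post)
  brain_mask <- resolve_mask(brain_mask, dim(pre))
  npre <- normalize_volume(pre, brain_mask)
  npost <- normalize_volume(post, brain_mask)
  diff <- array(as.numeric(npost) - as.numeric(npre), dim(pre))
  mask <- (diff > margin) & brain_mask
  if (any(mask) && min_component_voxels > 1) {
    lab <- label_components_26(mask)
    keep <- which(tabulate(lab[mask]) >= min_component_voxels)
    mask <- array(lab %in% keep & mask, dim(mask))
  }
  enhancement_mask(mask, vs)
}

enhancement_mask <- function(mask, voxel_size_mm = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim(mask))
  vs <- check_voxel_size(voxel_size_mm)
  structure(list(
    mask = mask,
    voxel_count = sum(mask),
    volume_cc = sum(mask) * prod(vs) / 1000,
    voxel_size_mm = vs
  ), class = "enhancement_mask")
}

#' @export
print.enhancement_mask <- function(x, ...) {
  cat(sprintf("<enhancement_mask> %d voxels, %.2f cc\n",
              x$voxel_count, x$volume_cc))
  invisible(x)
}

# 26-connectivity component labelling of a 3-D logical array.
# Builds the voxel adjacency graph over the TRUE voxels and labels its
# connected components; returns an integer array (0 = background).
label_components_26 <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dims)
  if (length(idx) == 0) return(lab)
  rank <- integer(prod(dims))
  rank[idx] <- seq_along(idx)
  co <- arrayInd(idx, dims)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # half the offsets suffice: each edge found once
  offsets <- offsets[offsets[, 3] > 0 |
                     (offsets[, 3] == 0 & (offsets[, 2] > 0 |
                      (offsets[, 2] == 0 & offsets[, 1] > 0))), , drop = FALSE]
  edges <- list()
  for (k in seq_len(nrow(offsets))) {
    nb <- sweep(co, 2, offsets[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1) * dims[1] * dims[2] +
              (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    hit <- rank[nb_lin] > 0
    if (!any(hit)) next
    edges[[length(edges) + 1]] <-
      cbind(rank[idx[ok]][hit], rank[nb_lin][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  lab[idx] <- as.integer(comp$membership)
  lab
}

#' Check the measurable-disease criterion
#'
#' A tumor is measurable when some axial slice (third array axis) of the
#' enhancement mask has an in-plane bounding box of at least 10 mm x 10 mm
#' — the "at least 1 cm x 1 cm" inclusion criterion. The criterion is
#' strictly in-plane: through-plane extent does not count.
#'
#' @param mask An `enhancement_mask` (or logical 3-D array).
#' @param voxel_size_mm Voxel spacing; taken from the mask object when
#'   available.
#' @param min_mm Required in-plane extent (mm) on both axes (default 10).
#' @return `TRUE` or `FALSE`.
#' @export
check_measurable <- function(mask, voxel_size_mm = NULL, min_mm = 10) {
  if (inherits(mask, "enhancement_mask")) {
    if (is.null(voxel_size_mm)) voxel_size_mm <- mask$voxel_size_mm
    mask <- mask$mask
  }
  vs <- check_voxel_size(voxel_size_mm %||% c(1, 1, 1))
  if (!any(mask)) return(FALSE)
  for (k in seq_len(dim(mask)[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    rows <- range(which(rowSums(sl) > 0))
    cols <- range(which(colSums(sl) > 0))
    if ((diff(rows) + 1) * vs[1] >= min_mm &&
        (diff(cols) + 1) * vs[2] >= min_mm) {
      return(TRUE)
    }
  }
  FALSE
}
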