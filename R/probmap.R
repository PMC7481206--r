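#' Gaussian component density
#'
#' Density of a single (untruncated) Gaussian mixture component at an ADC
#' value — the per-component PDF the probability index integrates.
#'
#' @param x ADC value(s) (um^2/ms).
#' @param mu Component mean (um^2/ms).
#' @param sigma Component SD (um^2/ms), strictly positive.
#' @return Density value(s).
#' @export
component_pdf <- function(x, mu, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0)) {
    rlang::abort("component_pdf: sigma must be > 0")
  }
  stats::dnorm(x, mu, sigma)
}

#' Voxel probability index for membership in the lower ADC distribution
#'
#' For a voxel with ADC value \eqn{x} and a fitted double-Gaussian model,
#' the index is
#' \deqn{I(x) = \frac{\int_x^\infty N(\mu_L,\sigma_L)\,dt -
#'                    \int_0^x N(\mu_H,\sigma_H)\,dt}
#'                   {\int_x^\infty N(\mu_L,\sigma_L)\,dt +
#'                    \int_0^x N(\mu_H,\sigma_H)\,dt} \in [-1, 1],}
#' with 1 meaning the voxel is certainly represented by the lower
#' distribution. The integrals are evaluated in closed form via the Gaussian
#' CDF; the component Gaussians are untruncated and the finite lower limit 0
#' of the higher-component integral is honored exactly. The mixture weight
#' `f` does not enter the index; setting `weighted = TRUE` multiplies the
#' tails by `f` and `1 - f` (an exploratory variant, off by default — the
#' index as defined is always the unweighted form).
#'
#' When both tail masses underflow (denominator below 1e-300) the
#' sign-consistent limit (+1 below the component means' midpoint, -1 above)
#' is returned with a warning.
#'
#' @param x ADC value(s), >= 0 (um^2/ms).
#' @param fit A `double_gaussian_fit`.
#' @param weighted Use the f-weighted variant (default `FALSE`).
#' @return Index value(s) in \[-1, 1\].
#' @examples
#' fit <- double_gaussian_fit(0.6, 1.0, 0.15, 1.9, 0.25)
#' probability_index(c(0.8, 1.4, 2.2), fit)
#' @export
probability_index <- function(x, fit, weighted = FALSE) {
  if (any(x < 0, na.rm = TRUE)) {
    rlang::abort("probability_index: ADC values must be >= 0")
  }
  upper_l <- stats::pnorm(x, fit$mu_L, fit$sigma_L, lower.tail = FALSE)
  lower_h <- stats::pnorm(x, fit$mu_H, fit$sigma_H) -
    stats::pnorm(0, fit$mu_H, fit$sigma_H)
  lower_h <- pmax(lower_h, 0)
  if (weighted) {
    upper_l <- fit$f * upper_l
    lower_h <- (1 - fit$f) * lower_h
  }
  den <- upper_l + lower_h
  out <- (upper_l - lower_h) / den
  bad <- is.finite(x) & den < 1e-300
  if (any(bad, na.rm = TRUE)) {
    rlang::warn("probability_index: tail masses underflowed; returning limit values")
    out[bad] <- ifelse(x[bad] < (fit$mu_L + fit$mu_H) / 2, 1, -1)
  }
  out
}

#' Compute the voxel-wise probability-index map
#'
#' Evaluates [probability_index()] at every ROI voxel of the ADC volume;
#' voxels outside the ROI are undefined and carry the sentinel `NaN` (also
#' how they are serialized to NIfTI).
#'
#' @param adc An [adc_volume()].
#' @param roi An `enhancement_mask` or logical array; shape must match.
#' @param fit A `double_gaussian_fit`.
#' @param weighted Passed to [probability_index()].
#' @return An object of class `probability_map`: a 3-D array in \[-1, 1\]
#'   (NaN outside the ROI) with the source `fit` and `voxel_size_mm`
#'   attached as attributes.
#' @export
make_probability_map <- function(adc, roi, fit, weighted = FALSE) {
  if (inherits(roi, "enhancement_mask")) roi <- roi$mask
  if (!identical(dim(roi), dim(adc))) {
    rlang::abort("make_probability_map: ROI shape does not match ADC volume")
  }
  vals <- array(NaN, dim(adc))
  inside <- which(as.logical(roi))
  x <- as.numeric(adc)[inside]
  x[x < 0] <- 0
  vals[inside] <- probability_index(x, fit, weighted = weighted)
  structure(vals, fit = fit, voxel_size_mm = voxel_size(adc),
            class = c("probability_map", "array"))
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x)
  defined <- sum(!is.nan(x))
  cat(sprintf(
    "<probability_map> %d x %d x %d, %d defined voxels, index range [%.3f, %.3f]\n",
    d[1], d[2], d[3], defined,
    suppressWarnings(min(x, na.rm = TRUE)),
    suppressWarnings(max(x, na.rm = TRUE))))
  invisible(x)
}

#' Select 5-mm biopsy targets from a probability map
#'
#' Greedy selection of paired cubic targets on the voxel grid. The cube edge
#' is `round(edge_mm / voxel_size)` voxels per axis (minimum 1). A cube is
#' admissible when it lies entirely inside the defined (ROI) region, is
#' disjoint from the exclusion mask (eloquent cortex, vasculature — caller
#' supplied), and does not overlap previously selected targets. Each pair
#' consists of the admissible cube maximizing the mean index (the
#' "low-ADC" target: highest probability of the lower distribution) and the
#' cube minimizing it (the "high-ADC" target). Ties are broken by the
#' lexicographically smallest cube start index, so selection is
#' deterministic.
#'
#' @param pmap A [make_probability_map()] result.
#' @param exclusion_mask Optional logical array of voxels that targets must
#'   avoid.
#' @param n_pairs Number of high/low pairs to select (default 1).
#' @param edge_mm Cube edge in mm (default 5).
#' @return A tibble with one row per target: `pair`, `label`
#'   (`"low-ADC"`/`"high-ADC"`), `mean_index`, cube start and center in
#'   0-based voxel indices, center in mm (voxel-center convention:
#'   mm = (index_0based + 0.5) x spacing), and `edge_vox`/`edge_mm`.
#' @export
select_targets <- function(pmap, exclusion_mask = NULL, n_pairs = 1,
                           edge_mm = 5) {
  vs <- voxel_size(pmap)
  dims <- dim(pmap)
  edge <- pmax(1L, as.integer(round(edge_mm / vs)))
  if (any(edge > dims)) {
    rlang::abort("ROI too small for 5 mm target: cube exceeds grid")
  }
  defined <- !is.nan(unclass(pmap))
  excl <- if (is.null(exclusion_mask)) array(FALSE, dims) else
    resolve_mask(exclusion_mask, dims)

  vals <- unclass(pmap)
  vals[!defined] <- 0
  sat_vals <- sat3d(vals)
  sat_def <- sat3d(array(as.numeric(defined), dims))
  sat_excl <- sat3d(array(as.numeric(excl), dims))
  cube_n <- prod(edge)

  starts <- expand.grid(i = seq_len(dims[1] - edge[1] + 1),
                        j = seq_len(dims[2] - edge[2] + 1),
                        k = seq_len(dims[3] - edge[3] + 1))
  cnt_def <- sat3d_sum(sat_def, starts, edge)
  cnt_excl <- sat3d_sum(sat_excl, starts, edge)
  admissible <- cnt_def == cube_n & cnt_excl == 0
  if (!any(admissible)) {
    rlang::abort(sprintf(
      "ROI too small for %g mm target: no admissible cube", edge_mm))
  }
  mean_idx <- sat3d_sum(sat_vals, starts, edge) / cube_n

  occupied <- array(FALSE, dims)
  out <- list()
  for (p in seq_len(n_pairs)) {
    for (label in c("low-ADC", "high-ADC")) {
      sat_occ <- sat3d(array(as.numeric(occupied), dims))
      free <- admissible & sat3d_sum(sat_occ, starts, edge) == 0
      if (!any(free)) {
        rlang::abort(sprintf(
          "ROI too small for %g mm target: no admissible cube left for pair %d",
          edge_mm, p))
      }
      score <- ifelse(free, mean_idx, NA_real_)
      pick <- if (label == "low-ADC") which(score == max(score, na.rm = TRUE))
              else which(score == min(score, na.rm = TRUE))
      # lexicographic tie-break on (i, j, k) start: expand.grid varies i
      # fastest, so the smallest row index is the lexicographic minimum
      # under (k, j, i); re-sort explicitly on (i, j, k)
      if (length(pick) > 1) {
        ord <- order(starts$i[pick], starts$j[pick], starts$k[pick])
        pick <- pick[ord]
      }
      pick <- pick[1]
      s0 <- c(starts$i[pick], starts$j[pick], starts$k[pick])
      occupied[s0[1]:(s0[1] + edge[1] - 1),
               s0[2]:(s0[2] + edge[2] - 1),
               s0[3]:(s0[3] + edge[3] - 1)] <- TRUE
      center0 <- (s0 - 1) + (edge - 1) / 2  # 0-based voxel coordinates
      out[[length(out) + 1]] <- tibble::tibble(
        pair = p, label = label, mean_index = mean_idx[pick],
        start_i = s0[1] - 1L, start_j = s0[2] - 1L, start_k = s0[3] - 1L,
        center_i = center0[1], center_j = center0[2], center_k = center0[3],
        center_x_mm = (center0[1] + 0.5) * vs[1],
        center_y_mm = (center0[2] + 0.5) * vs[2],
        center_z_mm = (center0[3] + 0.5) * vs[3],
        edge_vox_i = edge[1], edge_vox_j = edge[2], edge_vox_k = edge[3],
        edge_mm = edge_mm)
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("biopsy_targets", class(res))
  res
}

# 3-D summed-area table with a zero-padded leading border.
sat3d <- function(a) {
  d <- dim(a)
  s <- array(0, d + 1L)
  s[-1, -1, -1] <- a
  s <- apply(s, c(2, 3), cumsum)          # returns d1+1 x (d2+1)(d3+1)
  s <- array(s, d + 1L)
  s <- aperm(apply(s, c(1, 3), cumsum), c(2, 1, 3))
  s <- aperm(apply(s, c(1, 2), cumsum), c(2, 3, 1))
  s
}

# Sum of a over cubes of size `edge` starting at `starts` (1-based), via the
# inclusion-exclusion on the summed-area table.
sat3d_sum <- function(s, starts, edge) {
  i0 <- starts$i; j0 <- starts$j; k0 <- starts$k
  i1 <- i0 + edge[1]; j1 <- j0 + edge[2]; k1 <- k0 + edge[3]
  g <- function(i, j, k) s[cbind(i, j, k)]
  g(i1, j1, k1) - g(i0, j1, k1) - g(i1, j0, k1) - g(i1, j1, k0) +
    g(i0, j0, k1) + g(i0, j1, k0) + g(i1, j0, k0) - g(i0, j0, k0)
}

#' Write targets as CSV
#'
#' @param targets A [select_targets()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_targets_csv <- function(targets, path) {
  utils::write.csv(as.data.frame(targets), path, row.names = FALSE)
  invisible(path)
}
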