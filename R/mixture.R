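#' Two-component Gaussian mixture specification for ADC histograms
#'
#' The voxel-wise ADC distribution inside a contrast-enhancing tumor ROI is
#' modelled as a mixture of two Gaussians,
#' \deqn{p(ADC) = f \, N(\mu_L, \sigma_L) + (1 - f) \, N(\mu_H, \sigma_H),}
#' where `f` is the proportion of voxels in the lower component. The mean of
#' the lower component is the tumor's ADC_L; the mean of the higher component
#' is ADC_H. All ADC quantities are in um^2/ms (1 um^2/ms = 1e-3 mm^2/s).
#'
#' @param f Proportion of voxels in the lower component, strictly in (0, 1).
#' @param mu_L,mu_H Component means (um^2/ms); `mu_L < mu_H` is required.
#' @param sigma_L,sigma_H Component standard deviations (um^2/ms), positive.
#'
#' @return An object of class `mixture_spec`: a named list of the five
#'   parameters.
#' @examples
#' spec <- mixture_spec(f = 0.6, mu_L = 1.0, sigma_L = 0.15,
#'                      mu_H = 1.9, sigma_H = 0.25)
#' dmixture(seq(0, 3, by = 0.5), spec)
#' @export
mixture_spec <- function(f, mu_L, sigma_L, mu_H, sigma_H) {
  spec <- list(f = as.numeric(f), mu_L = as.numeric(mu_L),
               sigma_L = as.numeric(sigma_L), mu_H = as.numeric(mu_H),
               sigma_H = as.numeric(sigma_H))
  validate_mixture_spec(spec)
  structure(spec, class = "mixture_spec")
}

validate_mixture_spec <- function(spec) {
  nums <- unlist(spec[c("f", "mu_L", "sigma_L", "mu_H", "sigma_H")])
  if (any(!is.finite(nums))) {
    rlang::abort("mixture_spec: all parameters must be finite numbers")
  }
  if (spec$f <= 0 || spec$f >= 1) {
    rlang::abort("mixture_spec: invariant violated: 0 < f < 1")
  }
  if (spec$mu_L >= spec$mu_H) {
    rlang::abort("mixture_spec: invariant violated: mu_L < mu_H")
  }
  if (spec$sigma_L <= 0) {
    rlang::abort("mixture_spec: invariant violated: sigma_L > 0")
  }
  if (spec$sigma_H <= 0) {
    rlang::abort("mixture_spec: invariant violated: sigma_H > 0")
  }
  invisible(spec)
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf(
    "<mixture_spec> f = %.3f | lower N(%.3f, %.3f) | higher N(%.3f, %.3f) um^2/ms\n",
    x$f, x$mu_L, x$sigma_L, x$mu_H, x$sigma_H))
  invisible(x)
}

#' Mixture density, distribution function and random sampling
#'
#' `dmixture()` and `pmixture()` evaluate the two-component mixture density
#' and CDF in closed form; `sample_mixture()` draws voxel ADC values from the
#' generative model: each draw comes from the lower component with
#' probability `f`, otherwise from the higher component.
#'
#' @param x,q Numeric vector of ADC values (um^2/ms).
#' @param spec A [mixture_spec()].
#' @param n Number of draws (at least 1).
#' @param seed Integer seed; draws are reproducible for a fixed seed.
#'
#' @return `dmixture()`/`pmixture()` a numeric vector; `sample_mixture()` a
#'   numeric vector of `n` ADC values.
#' @export
dmixture <- function(x, spec) {
  validate_mixture_spec(spec)
  spec$f * stats::dnorm(x, spec$mu_L, spec$sigma_L) +
    (1 - spec$f) * stats::dnorm(x, spec$mu_H, spec$sigma_H)
}

#' @rdname dmixture
#' @export
pmixture <- function(q, spec) {
  validate_mixture_spec(spec)
  spec$f * stats::pnorm(q, spec$mu_L, spec$sigma_L) +
    (1 - spec$f) * stats::pnorm(q, spec$mu_H, spec$sigma_H)
}

#' @rdname dmixture
#' @export
sample_mixture <- function(spec, n, seed) {
  validate_mixture_spec(spec)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    rlang::abort("sample_mixture: n must be a single count >= 1")
  }
  n <- as.integer(n)
  with_local_seed(seed, {
    lower <- stats::runif(n) < spec$f
    x <- numeric(n)
    x[lower] <- stats::rnorm(sum(lower), spec$mu_L, spec$sigma_L)
    x[!lower] <- stats::rnorm(sum(!lower), spec$mu_H, spec$sigma_H)
    x
  })
}

# Run code under a local RNG state so callers' streams are untouched.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    rlang::abort("seed must be a single finite integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
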