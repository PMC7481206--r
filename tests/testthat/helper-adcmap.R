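# Shared fixtures and independent oracles used across test files.

default_spec <- function() {
  mixture_spec(f = 0.6, mu_L = 1.0, sigma_L = 0.15, mu_H = 1.9, sigma_H = 0.25)
}

# Analytic moments of a two-Gaussian mixture (independent of the package's
# density code paths).
mixture_mean <- function(s) s$f * s$mu_L + (1 - s$f) * s$mu_H
mixture_var <- function(s) {
  m <- mixture_mean(s)
  s$f * (s$sigma_L^2 + s$mu_L^2) + (1 - s$f) * (s$sigma_H^2 + s$mu_H^2) - m^2
}

# Exact (noise-free) density histogram for a mixture or single Gaussian:
# the model evaluated on bin midpoints, bypassing sampling entirely.
density_histogram <- function(dens_fun, n_bins = 200, range = c(0, 3),
                              n_voxels = 10000L) {
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(breaks = breaks, mids = mids, density = dens_fun(mids),
                 width = diff(range) / n_bins, n_voxels = n_voxels,
                 n_outside = 0L),
            class = "adc_histogram")
}

# Histogram built straight from a sample vector by wrapping it in a volume.
sample_histogram <- function(values, n_bins = 128, range = c(0, 4)) {
  n <- length(values)
  side <- ceiling(n^(1 / 3)) + 1
  arr <- array(1e6, rep(side, 3))  # filler far outside the histogram range
  roi <- array(FALSE, rep(side, 3))
  roi[seq_len(n)] <- TRUE
  arr[roi] <- values
  build_adc_histogram(adc_volume(arr), roi, n_bins = n_bins, range = range)
}

# Quadrature oracle for the probability index: the two printed integrals
# evaluated by adaptive numerical integration, never via pnorm.
quadrature_index <- function(x, fit) {
  up_l <- stats::integrate(function(t) stats::dnorm(t, fit$mu_L, fit$sigma_L),
                           x, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
  lo_h <- stats::integrate(function(t) stats::dnorm(t, fit$mu_H, fit$sigma_H),
                           0, x, rel.tol = 1e-12, abs.tol = 1e-14)$value
  (up_l - lo_h) / (up_l + lo_h)
}

# Hand-tabulated two-group log-rank statistic: walk the distinct event
# times, accumulate observed minus expected events in group 1 and the
# hypergeometric variance, and return chi2 = (O - E)^2 / V.
handrolled_logrank <- function(time, event, group) {
  g1 <- levels(as.factor(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Random valid fits for property sweeps (components well above zero).
random_fit <- function() {
  mu_l <- stats::runif(1, 0.5, 1.5)
  double_gaussian_fit(
    f = stats::runif(1, 0.2, 0.8),
    mu_L = mu_l, sigma_L = stats::runif(1, 0.05, 0.3),
    mu_H = mu_l + stats::runif(1, 0.3, 1.2),
    sigma_H = stats::runif(1, 0.05, 0.3))
}
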