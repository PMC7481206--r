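test_that("component density behaves like a Gaussian PDF", {
  expect_equal(component_pdf(1.0, 1.0, 0.2), 1 / (0.2 * sqrt(2 * pi)))
  expect_equal(component_pdf(1.2, 1.0, 0.2), component_pdf(0.8, 1.0, 0.2))
  expect_error(component_pdf(1, 1, 0), "sigma")
  # CDF-derivative oracle
  h <- 1e-6
  expect_equal(component_pdf(1.5, 1.0, 0.2),
               (pnorm(1.5 + h, 1.0, 0.2) - pnorm(1.5 - h, 1.0, 0.2)) / (2 * h),
               tolerance = 1e-6)
})

test_that("the index vanishes by symmetry at the midpoint of equal-sigma components", {
  fit <- double_gaussian_fit(0.5, 1.0, 0.1, 2.0, 0.1)
  expect_lt(abs(probability_index(1.5, fit)), 1e-9)
})

test_that("closed-form index matches adaptive quadrature of the printed integrals", {
  fit <- double_gaussian_fit(0.6, 1.0, 0.15, 1.9, 0.25)
  for (x in c(0.3, 0.8, 1.2, 1.45, 1.8, 2.5)) {
    expect_lt(abs(probability_index(x, fit) - quadrature_index(x, fit)), 1e-8)
  }
  set.seed(7)
  for (i in 1:25) {
    fit <- random_fit()
    x <- runif(1, 0.05, fit$mu_H + 3 * fit$sigma_H)
    expect_lt(abs(probability_index(x, fit) - quadrature_index(x, fit)), 1e-8)
  }
})

test_that("the index is monotone non-increasing in ADC and spans [-1, 1]", {
  set.seed(8)
  for (i in 1:10) {
    fit <- random_fit()
    x <- seq(1e-6, max(fit$mu_H + 8 * fit$sigma_H,
                       fit$mu_L + 12 * fit$sigma_L), length.out = 400)
    idx <- probability_index(x, fit)
    expect_true(all(diff(idx) <= 1e-12))
    expect_true(all(idx >= -1 & idx <= 1))
    expect_gt(idx[1], 1 - 1e-6)            # x -> 0+ limit
    expect_lt(idx[length(idx)], -1 + 1e-4) # large-x limit
  }
})

test_that("the mixture weight does not enter the index (printed form)", {
  a <- double_gaussian_fit(0.2, 1.0, 0.15, 1.9, 0.25)
  b <- double_gaussian_fit(0.8, 1.0, 0.15, 1.9, 0.25)
  x <- c(0.5, 1.2, 1.6, 2.2)
  expect_identical(probability_index(x, a), probability_index(x, b))
  # the exploratory weighted variant does depend on f
  expect_false(identical(probability_index(1.2, a, weighted = TRUE),
                         probability_index(1.2, b, weighted = TRUE)))
})

test_that("probability maps are defined exactly on the ROI with NaN outside", {
  subj <- make_subject_volume(default_spec(), seed = 4)
  fit <- double_gaussian_fit(0.6, 1.0, 0.15, 1.9, 0.25)
  pmap <- make_probability_map(subj$adc, subj$roi_mask, fit)
  expect_identical(!is.nan(unclass(pmap)), subj$roi_mask)
  vals <- pmap[subj$roi_mask]
  expect_true(all(vals >= -1 & vals <= 1))

  uni <- adc_volume(array(1.2, dim(subj$adc)))
  cmap <- make_probability_map(uni, subj$roi_mask, fit)
  expect_equal(length(unique(cmap[subj$roi_mask])), 1L)

  expect_error(make_probability_map(subj$adc, array(TRUE, c(4, 4, 4)), fit),
               "shape")
})

test_that("the positive-index fraction matches the analytic crossing point", {
  s <- default_spec()
  subj <- make_subject_volume(s, grid_shape = c(40, 40, 40),
                              lesion_radius_mm = 10, seed = 6)
  fit <- double_gaussian_fit(s$f, s$mu_L, s$sigma_L, s$mu_H, s$sigma_H)
  pmap <- make_probability_map(subj$adc, subj$roi_mask, fit)
  observed <- mean(pmap[subj$roi_mask] > 0)
  x_star <- uniroot(function(x) probability_index(x, fit),
                    c(s$mu_L, s$mu_H), tol = 1e-12)$root
  expected <- pmixture(x_star, s)  # P(draw below the zero crossing)
  expect_lt(abs(observed - expected), 0.05)
})

test_that("target selection refuses an ROI smaller than the cube", {
  arr <- array(NaN, c(12, 12, 12))
  arr[5:7, 5:7, 5:7] <- 0.5  # 3 mm pocket, cube needs 5
  pmap <- structure(arr, voxel_size_mm = c(1, 1, 1),
                    class = c("probability_map", "array"))
  expect_error(select_targets(pmap), "too small")
})

test_that("constant maps tie-break to the lexicographically smallest starts", {
  arr <- array(0.25, c(16, 16, 16))
  pmap <- structure(arr, voxel_size_mm = c(1, 1, 1),
                    class = c("probability_map", "array"))
  tg <- select_targets(pmap)
  expect_equal(tg$mean_index, c(0.25, 0.25))
  expect_identical(unlist(tg[1, c("start_i", "start_j", "start_k")],
                          use.names = FALSE), c(0L, 0L, 0L))
  # second target: smallest (i, j, k) start disjoint from the first cube
  expect_identical(unlist(tg[2, c("start_i", "start_j", "start_k")],
                          use.names = FALSE), c(0L, 0L, 5L))
})

test_that("a planted high-index block attracts the low-ADC target", {
  set.seed(9)
  arr <- array(runif(20^3, -0.6, -0.4), c(20, 20, 20))
  arr[9:13, 9:13, 9:13] <- 0.9
  pmap <- structure(arr, voxel_size_mm = c(1, 1, 1),
                    class = c("probability_map", "array"))
  tg <- select_targets(pmap)
  low <- tg[tg$label == "low-ADC", ]
  expect_true(all(low$center_i >= 8 & low$center_i <= 12))
  expect_true(all(low$center_j >= 8 & low$center_j <= 12))
  expect_true(all(low$center_k >= 8 & low$center_k <= 12))
  expect_equal(low$mean_index, 0.9, tolerance = 1e-12)
})

test_that("targets avoid the exclusion mask and never overlap", {
  arr <- array(0.5, c(20, 20, 20))
  arr[1:10, , ] <- 0.9
  excl <- array(FALSE, c(20, 20, 20))
  excl[1:12, , ] <- TRUE  # the best region is off limits
  pmap <- structure(arr, voxel_size_mm = c(1, 1, 1),
                    class = c("probability_map", "array"))
  tg <- select_targets(pmap, exclusion_mask = excl, n_pairs = 2)
  expect_true(all(tg$start_i >= 12))  # 0-based start, cube [13..17] 1-based
  # pairwise disjoint cubes
  occ <- array(0L, c(20, 20, 20))
  for (r in seq_len(nrow(tg))) {
    ii <- (tg$start_i[r] + 1):(tg$start_i[r] + tg$edge_vox_i[r])
    jj <- (tg$start_j[r] + 1):(tg$start_j[r] + tg$edge_vox_j[r])
    kk <- (tg$start_k[r] + 1):(tg$start_k[r] + tg$edge_vox_k[r])
    occ[ii, jj, kk] <- occ[ii, jj, kk] + 1L
  }
  expect_lte(max(occ), 1L)
})

test_that("cube edges snap to the voxel grid", {
  arr <- array(0.1, c(20, 20, 10))
  pmap <- structure(arr, voxel_size_mm = c(1, 1, 2.5),
                    class = c("probability_map", "array"))
  tg <- select_targets(pmap)
  expect_identical(tg$edge_vox_i[1], 5L)
  expect_identical(tg$edge_vox_k[1], 2L)  # round(5 / 2.5)
})
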