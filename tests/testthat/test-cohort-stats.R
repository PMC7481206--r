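test_that("pearson correlation matches the direct covariance formula", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  res <- pearson_correlation(d, x, y)
  # hand oracle: r = sum((x-xb)(y-yb)) / sqrt(sum((x-xb)^2) sum((y-yb)^2))
  r_hand <- sum((d$x - 2.5) * (d$y - 2.5)) /
    sqrt(sum((d$x - 2.5)^2) * sum((d$y - 2.5)^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$r_squared, r_hand^2, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)

  lin <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  expect_equal(pearson_correlation(lin, x, y)$r, 1, tolerance = 1e-12)

  expect_error(pearson_correlation(tibble::tibble(x = rep(1, 5), y = 1:5),
                                   x, y), "undefined correlation")
  expect_error(pearson_correlation(tibble::tibble(x = 1:2, y = 2:1), x, y),
               "at least 3")
})

test_that("unpaired t-test matches the hand-computed pooled formula", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6),
                      g = rep(c("a", "b"), each = 3))
  res <- group_ttest(d, v, g)
  sp2 <- (2 * 1 + 2 * 1) / 4  # pooled variance, both groups have var 1
  t_hand <- (2 - 5) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_equal(res$estimate, -3)
})

test_that("paired t-test works on differences and rejects zero variance", {
  d <- tibble::tibble(v = c(5, 7, 9, 4, 5, 6),
                      g = rep(c("post", "pre"), each = 3))
  res <- group_ttest(d, v, g, paired = TRUE)
  diffs <- c(1, 2, 3)
  t_hand <- mean(diffs) / (sd(diffs) / sqrt(3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)

  same <- tibble::tibble(v = c(1, 2, 3, 1, 2, 3),
                         g = rep(c("a", "b"), each = 3))
  expect_error(group_ttest(same, v, g, paired = TRUE), "zero variance")
})

test_that("within-group z-scoring has the documented convention and is idempotent", {
  d <- tibble::tibble(v = c(1, 3), g = c("t1", "t1"))
  z <- zscore_within(d, v, g)
  expect_equal(z$v_z, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(12)
  d2 <- tibble::tibble(v = rnorm(20), g = rep(c("t1", "t2"), each = 10))
  z2 <- zscore_within(d2, v, g)
  for (gg in c("t1", "t2")) {
    expect_lt(abs(mean(z2$v_z[z2$g == gg])), 1e-12)
    expect_equal(sd(z2$v_z[z2$g == gg]), 1, tolerance = 1e-12)
  }
  # idempotent
  z3 <- zscore_within(dplyr::mutate(z2, v = v_z), v, g)
  expect_equal(z3$v_z, z2$v_z, tolerance = 1e-12)
  # invariant to within-group ordering
  perm <- sample(nrow(d2))
  z4 <- zscore_within(d2[perm, ], v, g)
  expect_equal(z4$v_z, z2$v_z[perm], tolerance = 1e-12)

  expect_error(zscore_within(tibble::tibble(v = 1:3, g = c("a", "a", "b")),
                             v, g), "singleton group: b")
  expect_error(zscore_within(tibble::tibble(v = c(1, 1, 2, 3),
                                            g = c("a", "a", "b", "b")),
                             v, g), "constant group: a")
})

test_that("median split labels strictly-above-median as high", {
  expect_identical(as.character(median_split(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(median_split(c(1, 2, 3))),
                   c("low", "low", "high"))
  expect_warning(lab <- median_split(rep(2, 4)), "all values equal")
  expect_true(all(lab == "low"))
})

test_that("log-rank is null on identical groups and matches the hand-tabulated oracle", {
  d0 <- tibble::tibble(t = rep(c(1, 2, 3), 2), e = 1,
                       g = rep(c("a", "b"), each = 3))
  r0 <- km_logrank(d0, t, e, g)
  expect_equal(r0$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)

  d1 <- tibble::tibble(t = c(1, 2, 3, 4, 5, 6), e = 1,
                       g = rep(c("a", "b"), each = 3))
  r1 <- km_logrank(d1, t, e, g)
  chi2_hand <- handrolled_logrank(d1$t, d1$e, d1$g)
  expect_equal(r1$logrank_chi2, chi2_hand, tolerance = 1e-9)
  expect_equal(r1$p, pchisq(chi2_hand, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  expect_error(km_logrank(tibble::tibble(t = 1:3, e = 1, g = "a"), t, e, g),
               "two nonempty groups")
  expect_error(km_logrank(tibble::tibble(t = 1:4, e = 0,
                                         g = rep(c("a", "b"), 2)), t, e, g),
               "at least one event")
})

test_that("KM medians follow the first-time-below-half convention", {
  d <- tibble::tibble(t = c(1, 2, 3, 4, 10, 12, 14, 16), e = 1,
                      g = rep(c("a", "b"), each = 4))
  r <- km_logrank(d, t, e, g)
  expect_equal(r$per_group$median[r$per_group$group == "a"], 2)
  expect_equal(r$per_group$median[r$per_group$group == "b"], 12)
  # a group whose curve never reaches 0.5 has an undefined median
  d2 <- tibble::tibble(t = c(1, 2, 3, 4, 10, 12, 14, 16),
                       e = c(rep(1, 4), 1, 0, 0, 0),
                       g = rep(c("a", "b"), each = 4))
  r2 <- km_logrank(d2, t, e, g)
  expect_true(is.na(r2$per_group$median[r2$per_group$group == "b"]))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(13)
  d <- tibble::tibble(t = rexp(60, 0.2), e = 1,
                      g = rep(c("a", "b"), each = 30))
  r <- km_logrank(d, t, e, g)
  sf <- r$survfit
  strata <- rep(names(sf$strata), sf$strata)
  for (gg in c("a", "b")) {
    tg <- d$t[d$g == gg]
    sel <- strata == paste0("g=", gg)
    emp <- vapply(sf$time[sel], function(tt) mean(tg > tt), numeric(1))
    expect_equal(sf$surv[sel], emp, tolerance = 1e-12)
  }
})

test_that("log-rank is invariant to time-unit rescaling", {
  co <- make_cohort(n_subjects = 120, seed = 30)
  a <- km_logrank(co, surv_months, event, phenotype)
  co$surv_days <- co$surv_months * 30.44
  b <- km_logrank(co, surv_days, event, phenotype)
  expect_equal(a$logrank_chi2, b$logrank_chi2, tolerance = 1e-12)
})

test_that("the association suite detects planted structure and serializes", {
  co <- make_cohort(n_subjects = 60, expr_slope = 2, expr_intercept = 1,
                    expr_noise_sd = 0, seed = 14)
  names(co)[names(co) == "adcl_true"] <- "adcl"
  rep_ <- run_association_suite(co)
  expect_equal(rep_$correlation$r_squared, 1, tolerance = 1e-12)
  expect_lt(rep_$phenotype_ttest$p, 1e-6)
  td <- tidy(rep_)
  expect_true(all(c("expression_vs_adcl", "expression_by_phenotype",
                    "survival_by_phenotype", "survival_by_expression") %in%
                    td$analysis))
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep_, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$threshold, 1.24)
  expect_equal(back$n, 60)
})

test_that("the intratumoral branch z-scores within tumors and pairs extremes", {
  set.seed(15)
  n_tumors <- 6
  sites <- 4
  d <- tibble::tibble(
    tumor_id = rep(sprintf("T%d", 1:n_tumors), each = sites),
    site_id = rep(sprintf("s%d", 1:sites), n_tumors),
    adcl = runif(n_tumors * sites, 0.6, 2.0))
  # expression follows within-tumor ADC ranking, noiselessly
  d$expression <- unlist(lapply(split(d$adcl, d$tumor_id),
                                function(a) 3 * a), use.names = FALSE)
  d$expression <- 3 * d$adcl
  rep_ <- run_association_suite(d)
  expect_equal(rep_$intratumoral_correlation$r_squared, 1, tolerance = 1e-9)
  expect_gt(rep_$intratumoral_paired_ttest$statistic, 0)
  expect_lt(rep_$intratumoral_paired_ttest$p, 0.05)
})
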