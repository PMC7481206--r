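#' Pearson correlation between two cohort variables
#'
#' Pearson's r with R^2 and the two-sided p-value from the t transform with
#' n - 2 degrees of freedom — the linear-correlation analysis used to relate
#' expression to ADC_L.
#'
#' @param data A data frame.
#' @param x,y Columns to correlate (tidy-eval).
#' @return A one-row tibble: `r`, `r_squared`, `p`, `n`.
#' @examples
#' cohort <- make_cohort(n_subjects = 50, seed = 2)
#' pearson_correlation(cohort, adcl_true, expression)
#' @export
pearson_correlation <- function(data, x, y) {
  xv <- as.numeric(dplyr::pull(data, {{ x }}))
  yv <- as.numeric(dplyr::pull(data, {{ y }}))
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) {
    rlang::abort("pearson_correlation: need at least 3 complete pairs")
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    rlang::abort("pearson_correlation: undefined correlation (constant input)")
  }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(r = unname(ct$estimate),
                 r_squared = unname(ct$estimate)^2,
                 p = ct$p.value,
                 n = length(xv))
}

#' Two-sample or paired t-test on cohort groups
#'
#' Classic Student's pooled-variance t-test by default for the unpaired
#' comparison (Welch available via `welch = TRUE`); the paired test works on
#' within-pair differences. Two-sided p-values.
#'
#' @param data A data frame.
#' @param value Numeric column to compare (tidy-eval).
#' @param group Two-level grouping column (tidy-eval). For a paired test the
#'   data must contain both members of each pair in the same order within
#'   group.
#' @param paired Paired test on differences (default `FALSE`).
#' @param welch Use Welch's unequal-variance test (unpaired only).
#' @return A one-row tibble: `estimate` (mean difference, first level minus
#'   second), `statistic`, `df`, `p`, `n1`, `n2`, `method`.
#' @export
group_ttest <- function(data, value, group, paired = FALSE, welch = FALSE) {
  v <- as.numeric(dplyr::pull(data, {{ value }}))
  g <- dplyr::pull(data, {{ group }})
  g <- droplevels(as.factor(g))
  if (nlevels(g) != 2) {
    rlang::abort("group_ttest: grouping column must have exactly 2 levels")
  }
  a <- v[g == levels(g)[1]]
  b <- v[g == levels(g)[2]]
  if (paired) {
    if (length(a) != length(b)) {
      rlang::abort("group_ttest: paired test needs equal group sizes")
    }
    if (length(a) < 2) rlang::abort("group_ttest: need at least 2 pairs")
    d <- a - b
    if (stats::sd(d) == 0) {
      rlang::abort("group_ttest: zero variance in paired differences")
    }
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2 || length(b) < 2) {
      rlang::abort("group_ttest: each group needs at least 2 observations")
    }
    tt <- stats::t.test(a, b, var.equal = !welch)
  }
  tibble::tibble(
    estimate = mean(a) - mean(b),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    n1 = length(a), n2 = length(b),
    method = if (paired) "paired t" else if (welch) "Welch t" else "Student t")
}

#' Z-score a column within groups
#'
#' Within each group the values are centered and scaled to sample SD 1
#' (n - 1 denominator) — the normalization applied to multi-site
#' intratumoral measurements before cross-tumor comparison.
#'
#' @param data A data frame.
#' @param value Numeric column to normalize (tidy-eval).
#' @param group Grouping column (tidy-eval); each group needs >= 2 members
#'   and nonzero variance.
#' @param name Name of the new column (default `"<value>_z"`).
#' @return `data` with the z-scored column appended; row order preserved.
#' @export
zscore_within <- function(data, value, group, name = NULL) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  if (is.null(name)) name <- paste0(rlang::as_name(value), "_z")
  v <- as.numeric(dplyr::pull(data, !!value))
  g <- as.character(dplyr::pull(data, !!group))
  sizes <- table(g)
  if (any(sizes < 2)) {
    rlang::abort(paste0("zscore_within: singleton group: ",
                        names(sizes)[sizes < 2][1]))
  }
  sds <- tapply(v, g, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    rlang::abort(paste0("zscore_within: constant group: ",
                        names(sds)[sds == 0 | !is.finite(sds)][1]))
  }
  means <- tapply(v, g, mean)
  data[[name]] <- as.numeric((v - means[g]) / sds[g])
  data
}

#' Median split into high/low labels
#'
#' `"high"` iff the value strictly exceeds the median; values equal to the
#' median are labelled `"low"` (documented convention, keeping "high"
#' strictly above the median). An all-equal input yields all-"low" with a
#' warning.
#'
#' @param values Numeric vector (n >= 2).
#' @return Factor with levels low/high.
#' @examples
#' median_split(c(1, 2, 3, 4))
#' @export
median_split <- function(values) {
  if (length(values) < 2) rlang::abort("median_split: need at least 2 values")
  m <- stats::median(values)
  if (all(values == values[1])) {
    rlang::warn("median_split: all values equal; labelling everything 'low'")
  }
  factor(ifelse(values > m, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates per group with the two-group log-rank
#' test (chi-square, 1 df; p from the upper tail). The group median is the
#' earliest time at which the estimated survival step function falls to
#' <= 0.5, and is `NA` when the curve never does.
#'
#' @param data A data frame.
#' @param time,event Survival time and event-indicator (1 = event, 0 =
#'   censored) columns (tidy-eval).
#' @param group Two-level grouping column (tidy-eval).
#' @return An object of class `km_logrank_result` holding per-group medians,
#'   `logrank_chi2`, `p`, group sizes, and the underlying
#'   [survival::survfit()] object. `tidy()` returns the per-group summary;
#'   `glance()` the test.
#' @examples
#' cohort <- make_cohort(n_subjects = 100, seed = 4)
#' km_logrank(cohort, surv_months, event, phenotype)
#' @export
km_logrank <- function(data, time, event, group) {
  t_ <- as.numeric(dplyr::pull(data, {{ time }}))
  e_ <- as.integer(dplyr::pull(data, {{ event }}))
  g_ <- droplevels(as.factor(dplyr::pull(data, {{ group }})))
  if (nlevels(g_) < 2) rlang::abort("km_logrank: need two nonempty groups")
  if (nlevels(g_) > 2) rlang::abort("km_logrank: only two groups supported")
  if (!any(e_ == 1)) rlang::abort("km_logrank: need at least one event")
  df <- data.frame(t = t_, e = e_, g = g_)
  sf <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  sd_ <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
  chi2 <- unname(sd_$chisq)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  # median convention: the earliest time the step function falls to <= 0.5
  # (undefined, NA, when the curve never does)
  strata <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  groups <- levels(g_)
  per_group <- tibble::tibble(
    group = groups,
    n = vapply(groups, function(gr) sum(g_ == gr), numeric(1),
               USE.NAMES = FALSE),
    events = vapply(groups, function(gr) sum(e_[g_ == gr]), numeric(1),
                    USE.NAMES = FALSE),
    median = vapply(groups, function(gr) {
      sel <- strata == gr & sf$surv <= 0.5
      if (any(sel)) min(sf$time[sel]) else NA_real_
    }, numeric(1), USE.NAMES = FALSE))
  structure(list(
    per_group = per_group,
    logrank_chi2 = chi2,
    p = p,
    survfit = sf
  ), class = "km_logrank_result")
}

#' @export
print.km_logrank_result <- function(x, ...) {
  cat("<km_logrank_result>\n")
  print(as.data.frame(x$per_group))
  cat(sprintf("  log-rank chi2 = %.4g (1 df), p = %.4g\n",
              x$logrank_chi2, x$p))
  invisible(x)
}

#' @export
tidy.km_logrank_result <- function(x, ...) x$per_group

#' @export
glance.km_logrank_result <- function(x, ...) {
  tibble::tibble(logrank_chi2 = x$logrank_chi2, p = x$p, df = 1L)
}

#' Run the full cohort association suite
#'
#' Bundles the association analyses into one report: (1) Pearson correlation
#' of expression vs ADC_L across subjects; (2) unpaired Student's t-test of
#' expression between high and low ADC_L phenotypes (ADC_L > `threshold`);
#' (3) when a `site_id`/`tumor_id` pair is present, the intratumoral
#' analysis — ADC_L and expression z-scored within tumor, correlated across
#' sites, plus a paired t-test of expression between each tumor's highest-
#' and lowest-ADC_L sites; (4) Kaplan-Meier/log-rank survival by phenotype
#' and by median-split expression. No multiplicity correction is applied,
#' matching the source analysis style.
#'
#' @param data Cohort tibble with columns `adcl` (or `adcl_true`),
#'   `expression`, and optionally `surv_months` + `event` and
#'   `tumor_id` + `site_id`.
#' @param threshold ADC_L phenotype threshold (um^2/ms), default 1.24.
#' @return An object of class `adc_association_report` (a list of result
#'   tibbles); `tidy()` flattens it to one row per analysis.
#' @export
run_association_suite <- function(data, threshold = 1.24) {
  adcl_col <- if ("adcl" %in% names(data)) "adcl" else "adcl_true"
  if (!adcl_col %in% names(data)) {
    rlang::abort("run_association_suite: need an 'adcl' or 'adcl_true' column")
  }
  data$._adcl <- data[[adcl_col]]
  if (any(data$._adcl <= 0, na.rm = TRUE)) {
    rlang::abort("run_association_suite: adcl must be > 0")
  }
  data$phenotype <- factor(ifelse(data$._adcl > threshold, "high", "low"),
                           levels = c("low", "high"))
  report <- list(threshold = threshold,
                 n = nrow(data),
                 phenotype_counts = table(data$phenotype))

  report$correlation <- pearson_correlation(data, ._adcl, expression)
  if (nlevels(droplevels(data$phenotype)) == 2) {
    report$phenotype_ttest <- group_ttest(data, expression, phenotype)
  }

  if (all(c("tumor_id", "site_id") %in% names(data))) {
    z <- zscore_within(data, ._adcl, tumor_id, name = "adcl_z")
    z <- zscore_within(z, expression, tumor_id, name = "expression_z")
    report$intratumoral_correlation <-
      pearson_correlation(z, adcl_z, expression_z)
    extremes <- dplyr::bind_rows(lapply(split(z, z$tumor_id), function(d) {
      d <- d[order(d$._adcl), ]
      rbind(
        data.frame(which = "low_site", expression_z = d$expression_z[1]),
        data.frame(which = "high_site", expression_z = d$expression_z[nrow(d)]))
    }))
    extremes$which <- factor(extremes$which, levels = c("high_site", "low_site"))
    report$intratumoral_paired_ttest <-
      group_ttest(extremes, expression_z, which, paired = TRUE)
  }

  if (all(c("surv_months", "event") %in% names(data))) {
    if (nlevels(droplevels(data$phenotype)) == 2) {
      report$survival_by_phenotype <-
        km_logrank(data, surv_months, event, phenotype)
    }
    data$expression_group <- median_split(data$expression)
    if (nlevels(droplevels(data$expression_group)) == 2) {
      report$survival_by_expression <-
        km_logrank(data, surv_months, event, expression_group)
    }
  }
  structure(report, class = "adc_association_report")
}

#' @export
print.adc_association_report <- function(x, ...) {
  cat(sprintf("<adc_association_report> n = %d, threshold = %g um^2/ms\n",
              x$n, x$threshold))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.adc_association_report <- function(x, ...) {
  rows <- list()
  add <- function(analysis, statistic, value, p, n) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      analysis = analysis, statistic = statistic, value = value, p = p, n = n)
  }
  if (!is.null(x$correlation)) {
    add("expression_vs_adcl", "r_squared", x$correlation$r_squared,
        x$correlation$p, x$correlation$n)
  }
  if (!is.null(x$phenotype_ttest)) {
    add("expression_by_phenotype", "t", x$phenotype_ttest$statistic,
        x$phenotype_ttest$p, x$phenotype_ttest$n1 + x$phenotype_ttest$n2)
  }
  if (!is.null(x$intratumoral_correlation)) {
    add("intratumoral_expression_vs_adcl", "r_squared",
        x$intratumoral_correlation$r_squared, x$intratumoral_correlation$p,
        x$intratumoral_correlation$n)
  }
  if (!is.null(x$intratumoral_paired_ttest)) {
    add("intratumoral_paired", "t", x$intratumoral_paired_ttest$statistic,
        x$intratumoral_paired_ttest$p,
        x$intratumoral_paired_ttest$n1 + x$intratumoral_paired_ttest$n2)
  }
  if (!is.null(x$survival_by_phenotype)) {
    add("survival_by_phenotype", "logrank_chi2",
        x$survival_by_phenotype$logrank_chi2, x$survival_by_phenotype$p,
        sum(x$survival_by_phenotype$per_group$n))
  }
  if (!is.null(x$survival_by_expression)) {
    add("survival_by_expression", "logrank_chi2",
        x$survival_by_expression$logrank_chi2, x$survival_by_expression$p,
        sum(x$survival_by_expression$per_group$n))
  }
  dplyr::bind_rows(rows)
}

#' Serialize an association report as JSON
#'
#' @param report An [run_association_suite()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(threshold = report$threshold, n = report$n,
              results = tidy(report))
  if (!is.null(report$survival_by_phenotype)) {
    out$survival_by_phenotype <- report$survival_by_phenotype$per_group
  }
  if (!is.null(report$survival_by_expression)) {
    out$survival_by_expression <- report$survival_by_expression$per_group
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
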