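# Paired pre/post comparison and descriptive summaries.
#
# Continuous metrics (areas, percentages, distances) are compared with the
# paired t-test and summarized as mean +/- SD; ordinal scores (0-4) use the
# Wilcoxon matched-pairs signed-rank test and median [IQR]. No correction
# for multiple testing is applied across metrics (each comparison is
# reported marginally); this is recorded in the output metadata.

#' Descriptive summary of a metric vector
#'
#' Parametric: mean and sample standard deviation (denominator n - 1).
#' Nonparametric: median and interquartile range with quartiles by linear
#' interpolation between order statistics (`quantile()` type 7), formatted
#' as `"median [q1-q3]"`.
#'
#' @param x Numeric values (non-empty, finite).
#' @param kind `"parametric"` or `"nonparametric"`.
#' @return A list: `n`, `label`, and either `mean`/`sd` or `median`/`q1`/`q3`.
#'   A single value has `sd = NA` (flagged in the label).
#' @export
summarize_values <- function(x, kind = c("parametric", "nonparametric")) {
  kind <- arg_match(kind)
  if (length(x) == 0 || !is.numeric(x) || any(!is.finite(x))) {
    abort_invalid_input("`x` must be non-empty finite numeric values.")
  }
  if (kind == "parametric") {
    m <- mean(x)
    s <- if (length(x) > 1) sd(x) else NA_real_
    list(n = length(x), kind = kind, mean = m, sd = s,
         label = if (is.na(s)) sprintf("%.1f (SD undefined, n=1)", m)
                 else sprintf("%.1f ± %.1f", m, s))
  } else {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    list(n = length(x), kind = kind, median = q[2], q1 = q[1], q3 = q[3],
         label = sprintf("%g [%g–%g]", q[2], q[1], q[3]))
  }
}

#' Paired pre/post comparison of one metric
#'
#' Compares Accuracy Assessment 1 (post-MRI planning) with Accuracy
#' Assessment 2 (post-3D-model planning) for one metric over a cohort,
#' aligned by participant. `method = "auto"` picks the paired t-test for
#' continuous metrics and the Wilcoxon matched-pairs signed-rank test for
#' the ordinal 0-4 scores. The Wilcoxon test drops zero differences
#' (signed-rank convention; the count is reported), uses the exact
#' signed-rank distribution when 25 or fewer nonzero differences remain and
#' no ties, and otherwise the normal approximation with continuity and tie
#' correction. Degenerate samples (all differences zero) return p = 1 with
#' `degenerate = TRUE`.
#'
#' @param data A data frame with columns `participant_id`, `assessment`
#'   (values `"AA1"`/`"AA2"`) and the metric column.
#' @param metric Name of the metric column (string).
#' @param method `"auto"`, `"t"`, or `"wilcoxon"`.
#' @param alpha Significance level (default 0.05).
#' @return A `paired_comparison` object; see [tidy.paired_comparison()].
#' @export
paired_compare <- function(data, metric, method = c("auto", "t", "wilcoxon"),
                           alpha = 0.05) {
  method <- arg_match(method)
  stopifnot(is.data.frame(data))
  needed <- c("participant_id", "assessment", metric)
  if (!all(needed %in% names(data))) {
    abort_invalid_input(sprintf("`data` must contain columns %s.",
                                paste(needed, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(data, dplyr::all_of(needed)),
    names_from = "assessment", values_from = dplyr::all_of(metric))
  if (!all(c("AA1", "AA2") %in% names(wide))) {
    abort_invalid_input("`assessment` must contain both AA1 and AA2.")
  }
  if (anyNA(wide$AA1) || anyNA(wide$AA2)) {
    abort_invalid_input("Misaligned sample: some participants lack an AA1/AA2 pair.")
  }
  x <- wide$AA1; y <- wide$AA2
  n <- length(x)
  if (n < 2) abort_invalid_input("Need at least 2 complete pairs.")
  kind <- metric_kind(metric)
  if (method == "auto") method <- if (kind == "ordinal") "wilcoxon" else "t"
  d <- y - x
  degenerate <- all(d == 0)
  n_zero <- sum(d == 0)
  if (method == "t") {
    if (degenerate) {
      statistic <- 0; p <- 1
    } else {
      ht <- t.test(y, x, paired = TRUE)
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
    s1 <- summarize_values(x, "parametric")
    s2 <- summarize_values(y, "parametric")
    test_name <- "paired t-test"
  } else {
    if (degenerate) {
      statistic <- 0; p <- 1
    } else {
      # signed-rank convention: zero differences dropped before ranking
      dn <- d[d != 0]
      exact <- length(dn) <= 25 && !anyDuplicated(abs(dn))
      hw <- suppressWarnings(wilcox.test(dn, mu = 0, exact = exact, correct = TRUE))
      statistic <- unname(hw$statistic); p <- hw$p.value
    }
    s1 <- summarize_values(x, "nonparametric")
    s2 <- summarize_values(y, "nonparametric")
    test_name <- "Wilcoxon matched-pairs signed-rank test"
  }
  structure(list(
    metric = metric, n = n, method = method, test = test_name,
    statistic = statistic, p_value = p, significant = p < alpha, alpha = alpha,
    degenerate = degenerate, n_zero_diff = n_zero,
    mean_change = mean(d),
    summary_aa1 = s1, summary_aa2 = s2,
    multiplicity_correction = "none"
  ), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison of %s (n = %d)\n", x$metric, x$n))
  cat(sprintf("  AA1 %s | AA2 %s\n", x$summary_aa1$label, x$summary_aa2$label))
  cat(sprintf("  %s: statistic %.3f, p = %.4g%s%s\n", x$test, x$statistic, x$p_value,
              if (x$significant) " *" else "",
              if (x$degenerate) " (degenerate: all differences zero)" else ""))
  invisible(x)
}

#' Tidy a paired comparison
#'
#' @param x A `paired_comparison`.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with the metric name, per-assessment
#'   summaries, test, statistic, p-value and significance flag. `glance()`:
#'   a one-row model-level summary.
#' @method tidy paired_comparison
#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble(
    metric = x$metric, n = x$n,
    summary_aa1 = x$summary_aa1$label, summary_aa2 = x$summary_aa2$label,
    mean_change = x$mean_change,
    method = x$method, statistic = x$statistic, p_value = x$p_value,
    significant = x$significant, degenerate = x$degenerate,
    n_zero_diff = x$n_zero_diff)
}

#' @rdname tidy.paired_comparison
#' @method glance paired_comparison
#' @export
glance.paired_comparison <- function(x, ...) {
  tibble(n = x$n, method = x$method, statistic = x$statistic,
         p_value = x$p_value, significant = x$significant, alpha = x$alpha,
         multiplicity_correction = x$multiplicity_correction)
}

#' Compare all metrics between assessments, optionally per group
#'
#' Runs [paired_compare()] for each requested metric, optionally stratified
#' (independent comparisons per stratum, no pooling). Strata with fewer
#' than 2 complete pairs are skipped with a warning.
#'
#' @param data Metrics tibble from [assess_cohort()] or
#'   [simulate_cohort_metrics()].
#' @param metrics Metric column names; defaults to the seven standard ones
#'   present in `data`.
#' @param by Optional stratification column (e.g. `"group"`).
#' @param method Passed to [paired_compare()] (default `"auto"`).
#' @param alpha Significance level.
#' @return A tibble of tidied comparisons (class `planning_comparison`),
#'   one row per metric (and stratum).
#' @export
compare_metrics <- function(data, metrics = NULL, by = NULL,
                            method = "auto", alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if (is.null(metrics)) metrics <- intersect(metric_columns(), names(data))
  if (length(metrics) == 0) abort_invalid_input("No metric columns found.")
  strata <- if (is.null(by)) list(all = data) else split(data, data[[by]])
  rows <- purrr::imap(strata, function(dd, stratum) {
    purrr::map(metrics, function(m) {
      tab <- table(dd$assessment)
      n_pairs <- if (length(tab) == 0) 0 else min(tab)
      if (nrow(dd) == 0 || n_pairs < 2) {
        warn(sprintf("Stratum '%s' skipped: fewer than 2 complete pairs.", stratum))
        return(NULL)
      }
      out <- tidy(paired_compare(dd, m, method = method, alpha = alpha))
      if (!is.null(by)) out <- dplyr::mutate(out, "{by}" := stratum, .before = 1)
      out
    })
  })
  res <- dplyr::bind_rows(purrr::flatten(rows))
  class(res) <- c("planning_comparison", class(res))
  res
}

#' Stratified paired comparison of one metric
#'
#' @param data Metrics tibble.
#' @param metric Metric column name.
#' @param group Stratification column name (default `"group"`).
#' @param ... Passed to [compare_metrics()].
#' @return A `planning_comparison` tibble, one row per stratum.
#' @export
stratified_compare <- function(data, metric, group = "group", ...) {
  compare_metrics(data, metrics = metric, by = group, ...)
}

#' Likert feedback summary
#'
#' Summarizes 1-10 Likert responses per item as median and interquartile
#' range, formatted `"median [q1-q3]"` (quartiles by linear interpolation).
#'
#' @param feedback Data frame with columns `item` and `value` (one row per
#'   respondent and item); values must lie in `scale`.
#' @param scale Allowed response range.
#' @return A tibble: `item`, `n`, `median`, `q1`, `q3`, `label`.
#' @export
likert_summary <- function(feedback, scale = c(1, 10)) {
  stopifnot(is.data.frame(feedback))
  if (!all(c("item", "value") %in% names(feedback))) {
    abort_invalid_input("`feedback` must have columns `item` and `value`.")
  }
  v <- feedback$value
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < scale[1] | v > scale[2])) {
    abort_validation(sprintf("Likert values must lie in [%g, %g].", scale[1], scale[2]))
  }
  feedback |>
    dplyr::group_by(item = .data$item) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = unname(quantile(.data$value, 0.5, type = 7)),
      q1 = unname(quantile(.data$value, 0.25, type = 7)),
      q3 = unname(quantile(.data$value, 0.75, type = 7)),
      .groups = "drop") |>
    dplyr::mutate(label = sprintf("%g [%g–%g]", median, q1, q3))
}
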