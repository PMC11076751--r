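# Paired comparison and descriptive summaries.

make_paired <- function(aa1, aa2, metric = "value") {
  n <- length(aa1)
  out <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", seq_len(n)), 2),
    assessment = rep(c("AA1", "AA2"), each = n))
  out[[metric]] <- c(aa1, aa2)
  out
}

test_that("summaries match hand-computed values and Table-style formatting", {
  s <- summarize_values(c(1, 2, 3, 4, 5), "parametric")
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sd(c(1, 2, 3, 4, 5)))
  expect_equal(round(s$sd, 2), 1.58)

  np <- summarize_values(c(10, 9, 10, 10, 8), "nonparametric")
  expect_equal(np$median, 10)
  expect_equal(np$label, "10 [9–10]")

  one <- summarize_values(42, "parametric")
  expect_true(is.na(one$sd))
  expect_match(one$label, "SD undefined")

  # mirrored samples: mirrored means, identical SDs
  x <- rnorm(20)
  sp <- summarize_values(x, "parametric")
  sn <- summarize_values(-x, "parametric")
  expect_equal(sn$mean, -sp$mean)
  expect_equal(sn$sd, sp$sd)

  expect_error(summarize_values(numeric(0), "parametric"),
               class = "cranioplan_invalid_input")
})

test_that("degenerate and misaligned paired samples are handled", {
  d <- make_paired(c(1, 2, 3, 4), c(1, 2, 3, 4))
  r <- paired_compare(d, "value", method = "t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  rw <- paired_compare(d, "value", method = "wilcoxon")
  expect_equal(rw$p_value, 1)
  expect_true(rw$degenerate)

  bad <- make_paired(c(1, 2, 3), c(4, 5, 6))[-1, ]
  expect_error(paired_compare(bad, "value"), class = "cranioplan_invalid_input")
})

test_that("exact Wilcoxon p-values equal full sign enumeration for n <= 8", {
  # fixed integer toy sample (n = 6, distinct |differences|)
  x <- c(10, 12, 9, 15, 11, 8)
  y <- c(12, 11, 14, 12, 17, 12)
  r <- paired_compare(make_paired(x, y), "value", method = "wilcoxon")
  expect_equal(r$p_value, oracle_wilcoxon_exact(x, y))

  set.seed(88)
  for (n in 2:8) {
    for (rep in 1:5) {
      x <- sample(0:30, n)
      d <- sample(1:9, n) * sample(c(-1, 1), n, replace = TRUE)
      y <- x + d
      r <- paired_compare(make_paired(x, y), "value", method = "wilcoxon")
      expect_equal(r$p_value, oracle_wilcoxon_exact(x, y),
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("wilcoxon drops zero differences and reports the count", {
  x <- c(5, 5, 7, 9, 4)
  y <- c(5, 6, 10, 7, 4)  # two zeros, distinct |nonzero differences|
  r <- paired_compare(make_paired(x, y), "value", method = "wilcoxon")
  expect_equal(r$n_zero_diff, 2)
  expect_equal(r$p_value, oracle_wilcoxon_exact(x, y))
})

test_that("auto method follows metric type: t for continuous, wilcoxon for scores", {
  d1 <- make_paired(c(1.2, 3.4, 2.2, 5.5), c(2.2, 3.3, 4.1, 6.0), "percent_coverage")
  expect_equal(paired_compare(d1, "percent_coverage")$method, "t")
  d2 <- make_paired(c(1, 2, 3, 0), c(2, 3, 4, 1), "cran_score")
  expect_equal(paired_compare(d2, "cran_score")$method, "wilcoxon")
})

test_that("tidy and glance return one-row summaries", {
  d <- make_paired(c(1, 2, 3, 4, 7), c(2, 4, 5, 6, 9))
  r <- paired_compare(d, "value")
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("metric", "p_value", "significant", "summary_aa1") %in% names(td)))
  g <- glance(r)
  expect_equal(g$multiplicity_correction, "none")
})

test_that("stratified comparison finds the resident-only incision improvement", {
  profiles <- default_profiles()
  spec <- cohort_spec(n_residents = 40, n_interns = 40, profiles = profiles, seed = 101)
  m <- simulate_cohort_metrics(spec)
  out <- stratified_compare(m, "incision_deviation_mm")
  res <- out[out$group == "resident", ]
  int <- out[out$group == "intern", ]
  expect_true(res$significant)
  expect_false(int$significant)
  expect_lt(res$mean_change, 0)

  # an empty stratum is skipped with a warning, the other still reported
  m2 <- m[m$group == "resident", ]
  m2$group <- factor(m2$group, levels = c("resident", "intern"))
  expect_warning(out2 <- compare_metrics(m2, metrics = "incision_deviation_mm",
                                         by = "group"))
  expect_equal(nrow(out2), 1)
})

test_that("likert summaries follow the median [IQR] convention", {
  fb <- tibble::tibble(item = rep(c("realism", "utility"), each = 4),
                       value = c(10, 10, 10, 10, 1, 1, 2, 2))
  s <- likert_summary(fb)
  expect_equal(s$label[s$item == "realism"], "10 [10–10]")
  expect_equal(s$median[s$item == "utility"], 1.5)
  expect_equal(s$label[s$item == "utility"], "1.5 [1–2]")
  fb$value[1] <- 11
  expect_error(likert_summary(fb), class = "cranioplan_validation_error")
})
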