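# Cohort generator: inversion, determinism, substreams, calibration.

test_that("point-mass profiles invert exactly through the metrics", {
  prof12 <- skill_profile(paint_shift = dist_point(0),
                          paint_area_factor = dist_point(1),
                          incision_offset = dist_point(12),
                          edge_margin = dist_point(10))
  ann <- simulate_annotation(default_model, prof12, "AA1", seed = 21, lift = FALSE)
  r <- assess(ann, silhouette = default_silhouette)
  expect_equal(r$incision_deviation, 12, tolerance = 1e-9)
  expect_equal(r$percent_coverage, 100)
  expect_equal(r$margin_deviation_sum, 0, tolerance = 1e-9)

  prof218 <- skill_profile(paint_shift = dist_point(0),
                           paint_area_factor = dist_point(1),
                           incision_offset = dist_point(0),
                           edge_margin = dist_point(21.8))
  ann2 <- simulate_annotation(default_model, prof218, "AA2", seed = 21, lift = FALSE)
  r2 <- assess(ann2, silhouette = default_silhouette)
  expect_equal(r2$margin_deviation_sum, 4 * 11.8, tolerance = 1e-6)
  expect_equal(r2$cran_score, 0L)

  # coverage-targeted painting hits its target through the raster engine
  profc <- skill_profile(paint_coverage = dist_point(77.2),
                         paint_area_factor = dist_point(1),
                         incision_offset = dist_point(0),
                         edge_margin = dist_point(10))
  ann3 <- simulate_annotation(default_model, profc, "AA1", seed = 9, lift = FALSE)
  r3 <- assess(ann3, silhouette = default_silhouette)
  expect_equal(r3$percent_coverage, 77.2, tolerance = 0.005)
})

test_that("simulation is deterministic and requires a seed", {
  prof <- default_profiles()$resident$pre
  a1 <- simulate_annotation(default_model, prof, "AA1", seed = 33, lift = FALSE)
  a2 <- simulate_annotation(default_model, prof, "AA1", seed = 33, lift = FALSE)
  expect_identical(a1, a2)
  a3 <- simulate_annotation(default_model, prof, "AA1", seed = 34, lift = FALSE)
  expect_false(identical(a1$painted, a3$painted))
  expect_error(simulate_annotation(default_model, prof, "AA1"),
               class = "cranioplan_reproducibility_error")
})

test_that("cohorts have the study composition and per-participant substreams", {
  coh <- simulate_cohort(default_model, cohort_spec(seed = 2), lift = FALSE)
  expect_equal(nrow(coh), 76)
  expect_equal(sum(coh$group == "resident"), 28)
  expect_equal(sum(coh$group == "intern"), 48)
  expect_equal(length(unique(coh$participant_id)), 38)
  expect_equal(unique(coh$substream), bitwXor(2L, 1:38))

  tiny <- simulate_cohort(default_model,
                          cohort_spec(n_residents = 0, n_interns = 1, seed = 5),
                          lift = FALSE)
  expect_equal(nrow(tiny), 2)
  expect_equal(unique(tiny$group), "intern")
})

test_that("identical seeds give identical metric tables", {
  m1 <- simulate_cohort_metrics(cohort_spec(seed = 17))
  m2 <- simulate_cohort_metrics(cohort_spec(seed = 17))
  expect_identical(m1, m2)
  m3 <- simulate_cohort_metrics(cohort_spec(seed = 18))
  expect_false(identical(m1$percent_coverage, m3$percent_coverage))
})

test_that("substreams are independent and the pre/post copula couples them", {
  big <- cohort_spec(n_residents = 1000, n_interns = 0, seed = 3)
  p <- draw_skill_params(big)
  pre <- p[p$assessment == "AA1", ]
  post <- p[p$assessment == "AA2", ]
  # no cross-participant correlation beyond chance at n = 1000
  r_lag <- cor(pre$incision_offset_mm[-1], pre$incision_offset_mm[-1000])
  expect_lt(abs(r_lag), 0.08)
  # within-participant coupling (rho = 0.7 on the latent normal scale)
  expect_gt(cor(pre$incision_offset_mm, post$incision_offset_mm), 0.45)
})

test_that("the fast metric path matches geometry-level assessment", {
  spec <- cohort_spec(n_residents = 4, n_interns = 6, seed = 11)
  coh <- simulate_cohort(default_model, spec, lift = FALSE)
  met <- assess_cohort(coh, default_model)
  fast <- simulate_cohort_metrics(spec)
  expect_equal(met$incision_deviation_mm, fast$incision_deviation_mm, tolerance = 1e-9)
  expect_equal(met$percent_coverage, fast$percent_coverage, tolerance = 0.002)
  expect_equal(met$margin_deviation_sum_mm, fast$margin_deviation_sum_mm,
               tolerance = 0.005)
  expect_equal(met$painted_area_mm2, fast$painted_area_mm2, tolerance = 0.005)
  # ordinal scores agree exactly away from band boundaries
  expect_true(mean(met$cran_score == fast$cran_score) >= 0.9)
  expect_true(mean(met$u_score == fast$u_score) >= 0.9)
})

test_that("calibrated profiles reproduce the study-level metric moments", {
  big <- cohort_spec(n_residents = 3000, n_interns = 0, seed = 29)
  m <- simulate_cohort_metrics(big)
  pre <- m[m$assessment == "AA1", ]
  post <- m[m$assessment == "AA2", ]
  # coverage Beta targets 66.4 +/- 26.2 and 77.2 +/- 17.4 (clamping to the
  # feasible range shifts the mean by at most ~1.5 points)
  expect_equal(mean(pre$percent_coverage), 66.4, tolerance = 0.035)
  expect_equal(mean(post$percent_coverage), 77.2, tolerance = 0.025)
  expect_equal(sd(post$percent_coverage), 17.4, tolerance = 0.1)
  # incision offsets: Gamma(16.3, 9.6) pre
  expect_equal(mean(pre$incision_deviation_mm), 16.3, tolerance = 0.02)
  expect_equal(sd(pre$incision_deviation_mm), 9.6, tolerance = 0.05)
  # margin deviation sums target 57.3 and 47.2
  expect_equal(mean(pre$margin_deviation_sum_mm), 57.3, tolerance = 0.06)
  expect_equal(mean(post$margin_deviation_sum_mm), 47.2, tolerance = 0.06)
})
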