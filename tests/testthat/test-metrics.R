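# The seven accuracy metrics against constructed configurations.

test_that("coverage metrics reproduce identity, shifted-lens and union cases", {
  sil <- default_silhouette
  ident <- coverage_metrics(sil, sil)
  expect_equal(ident$percent_coverage, 100)
  expect_equal(ident$excess, 0)

  shifted <- rigid_transform(sil, translate = c(11.24, 0))
  cm <- coverage_metrics(shifted, sil)
  expect_equal(cm$percent_coverage, 100 * oracle_lens_fraction(11.24 / 31.2),
               tolerance = 0.005)
  expect_equal(cm$percent_coverage, 77.2, tolerance = 0.01)

  # shifted silhouette plus a disjoint 35.0 x 29.8 mm rectangle: painted
  # ~3760 mm^2, excess ~1662 mm^2
  painted <- region_combine(shifted, region_rectangle(35, 29.8, center = c(150, 0)))
  cm2 <- coverage_metrics(painted, sil)
  expect_equal(cm2$painted_area, 2717 + 35 * 29.8, tolerance = 0.01)
  expect_equal(cm2$excess, 3760 - 0.772 * 2717, tolerance = 0.015)
  expect_identical(cm2$painted_area, cm2$covered_area + cm2$excess)

  flat <- region2d(list(rbind(c(0, 0), c(5, 0), c(10, 0))), validate = FALSE)
  expect_error(coverage_metrics(sil, flat), class = "cranioplan_configuration_error")
})

test_that("incision deviation is the epicenter-to-polyline minimum distance", {
  sil <- default_silhouette
  through <- polyline2d(rbind(c(-40, 0), c(40, 0)))
  expect_equal(incision_deviation(through, sil), 0, tolerance = 1e-9)
  tangent <- polyline2d(rbind(c(-40, 12), c(40, 12)))
  expect_equal(incision_deviation(tangent, sil), 12, tolerance = 1e-9)
})

test_that("craniotomy scoring follows the closed 5-15 mm band rule", {
  circ <- region_circle(25, n = 512)
  cen <- c(0, 0)
  expect_equal(craniotomy_score(square_quad(35), circ, centre = cen), 4L)
  # three edges at 10 mm, one pushed to ~25 mm
  q3 <- quad2d(rbind(c(50, 35), c(-35, 35), c(-35, -35), c(50, -35)))
  scores <- craniotomy_edge_scores(q3, circ, centre = cen)
  expect_equal(sum(scores), 3L)
  expect_equal(craniotomy_score(square_quad(27), circ, centre = cen), 0L) # 2 mm margins
  # closed band: margins exactly 5 and exactly 15 both score (use a square
  # silhouette so the boundary distance is exact, no polygon epsilon)
  sq_sil <- region_rectangle(50, 50)
  expect_equal(craniotomy_score(square_quad(30), sq_sil, centre = cen), 4L)
  expect_equal(craniotomy_score(square_quad(40), sq_sil, centre = cen), 4L)
  expect_equal(craniotomy_score(square_quad(40.001), sq_sil, centre = cen), 0L)
})

test_that("craniotomy score is monotone as one edge leaves the band", {
  circ <- region_circle(25, n = 512)
  cen <- c(0, 0)
  mk <- function(right) quad2d(rbind(c(right, 35), c(-35, 35), c(-35, -35), c(right, -35)))
  s <- sapply(c(35, 41, 50, 70), function(r) craniotomy_score(mk(r), circ, centre = cen))
  expect_true(all(diff(s) <= 0))
  expect_equal(s[1], 4L)
  expect_equal(s[4], 3L)
})

test_that("U-incision scores three limbs plus the imaginary base", {
  circ <- region_circle(25, n = 512)
  cen <- c(0, 0)
  u10 <- polyline2d(square_quad(35)$coords)  # congruent to an all-10 craniotomy
  expect_equal(u_incision_score(u10, circ, centre = cen), 4L)
  # limbs fine, imaginary base (vertices 4 -> 1) at ~30 mm
  ubase <- polyline2d(rbind(c(55, 35), c(-35, 35), c(-35, -35), c(55, -35)))
  expect_equal(u_incision_score(ubase, circ, centre = cen), 3L)
  # limbs on the tumor border: margins 0, only the base can score
  utight <- polyline2d(square_quad(25)$coords)
  expect_lte(u_incision_score(utight, circ, centre = cen), 1L)
  expect_error(u_incision_score(polyline2d(rbind(c(0, 0), c(1, 1))), circ, centre = cen),
               class = "cranioplan_invalid_input")
})

test_that("margin deviation sum measures distance from the 10 mm standard", {
  circ <- region_circle(25, n = 512)
  cen <- c(0, 0)
  expect_equal(margin_deviation_sum(square_quad(35), circ, centre = cen), 0,
               tolerance = 0.02)
  expect_equal(margin_deviation_sum(square_quad(46.8), circ, centre = cen), 47.2,
               tolerance = 0.02)
  # margins {5, 15, 5, 15}: 80 x 60 rectangle, midpoints on the axes
  q <- quad2d(rbind(c(40, 30), c(-40, 30), c(-40, -30), c(40, -30)))
  expect_equal(margin_deviation_sum(q, circ, centre = cen), 20, tolerance = 0.002)
})

test_that("margin deviation sum and craniotomy score are not equivalent", {
  circ <- region_circle(25, n = 512)
  cen <- c(0, 0)
  # all margins exactly 10: sum 0 and score 4
  expect_equal(margin_deviation_sum(square_quad(35), circ, centre = cen), 0,
               tolerance = 0.02)
  expect_equal(craniotomy_score(square_quad(35), circ, centre = cen), 4L)
  # a small deviation sum (< 20 mm) does not imply a perfect score: one
  # edge at ~26 mm already drops the score to 3
  q <- quad2d(rbind(c(51, 35), c(-35, 35), c(-35, -35), c(51, -35)))
  expect_lt(margin_deviation_sum(q, circ, centre = cen), 20)
  expect_equal(craniotomy_score(q, circ, centre = cen), 3L)
})

test_that("assess is deterministic and exact for the zero-error annotation", {
  ann <- simulate_annotation(default_model, zero_error_profile(), "AA1", seed = 1)
  r <- assess(ann, silhouette = default_silhouette)
  expect_equal(r$percent_coverage, 100)
  expect_equal(r$excess, 0)
  expect_equal(r$incision_deviation, 0, tolerance = 1e-9)
  expect_equal(r$u_score, 4L)
  expect_equal(r$cran_score, 4L)
  expect_equal(r$margin_deviation_sum, 0, tolerance = 1e-9)
  r2 <- assess(ann, silhouette = default_silhouette)
  expect_identical(as_tibble(r), as_tibble(r2))
})
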