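# Planar region engine: constructors, raster areas, overlaps, centroids.

test_that("region and polyline constructors validate their inputs", {
  expect_s3_class(region_ellipse(31.2, 27.72), "region2d")
  expect_error(region_ellipse(0, 5), class = "cranioplan_invalid_input")
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(region2d(list(bowtie)), class = "cranioplan_geometry_error")
  expect_error(polyline2d(rbind(c(0, 0))), class = "cranioplan_invalid_input")
  expect_error(quad2d(bowtie), class = "cranioplan_geometry_error")
  # repeated closing vertex is tolerated
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(nrow(region2d(list(sq))$rings[[1]]), 4)
})

test_that("raster area matches closed forms", {
  expect_equal(area(region_rectangle(10, 10)), 100, tolerance = 1e-12)
  ell <- region_ellipse(31.2, 27.72)
  expect_equal(area(ell), pi * 31.2 * 27.72, tolerance = 0.005)
  # degenerate (collinear) ring has zero area
  flat <- region2d(list(rbind(c(0, 0), c(5, 0), c(10, 0))), validate = FALSE)
  expect_equal(area(flat), 0)
})

test_that("intersection area is symmetric, bounded, and matches the lens oracle", {
  a <- region_ellipse(31.2, 27.72)
  expect_equal(intersection_area(a, a), area(a))
  far <- region_rectangle(10, 10, center = c(200, 0))
  expect_equal(intersection_area(a, far), 0)
  for (off in c(0, 5, 11.24, 16.67, 40)) {
    b <- rigid_transform(a, translate = c(off, 0))
    got <- intersection_area(a, b)
    want <- oracle_lens_fraction(off / 31.2) * pi * 31.2 * 27.72
    expect_equal(got, want, tolerance = 0.005)
    expect_equal(intersection_area(b, a), got)
    expect_lte(got, min(area(a), area(b)) + 1e-9)
  }
})

test_that("painted = covered + excess holds raster-exactly for random region pairs", {
  set.seed(401)
  for (i in 1:200) {
    a <- region_ellipse(runif(1, 5, 30), runif(1, 5, 30),
                        center = runif(2, -10, 10), angle = runif(1, 0, pi))
    b <- if (i %% 2 == 0) {
      region_rectangle(runif(1, 5, 40), runif(1, 5, 40), center = runif(2, -20, 20))
    } else {
      region_ellipse(runif(1, 5, 30), runif(1, 5, 30), center = runif(2, -25, 25))
    }
    cm <- coverage_metrics(a, b, pitch = 0.5)
    expect_identical(cm$painted_area, cm$covered_area + cm$excess)
    expect_gte(cm$excess, 0)
    expect_true(cm$percent_coverage >= 0 && cm$percent_coverage <= 100)
  }
})

test_that("areas and distances are invariant under rigid in-plane motion", {
  ell <- region_ellipse(20, 12, center = c(3, -4))
  quad <- square_quad(30)
  line <- polyline2d(rbind(c(-15, 6), c(25, 6)))
  ang <- 0.7; tr <- c(12.3, -7.9)
  ell2 <- rigid_transform(ell, ang, tr)
  quad2 <- rigid_transform(quad, ang, tr)
  line2 <- rigid_transform(line, ang, tr)
  expect_equal(area(ell2), area(ell), tolerance = 0.003)
  c1 <- centroid(ell); c2 <- centroid(ell2)
  expect_equal(min_distance(c2, line2), min_distance(c1, line), tolerance = 0.02)
  m1 <- sapply(1:4, function(i) edge_margin(quad, i, ell, centre = c1))
  m2 <- sapply(1:4, function(i) edge_margin(quad2, i, ell2, centre = c2))
  expect_equal(m2, m1, tolerance = 0.02)
})

test_that("raster error shrinks as the pitch is halved", {
  ell <- region_ellipse(31.2, 27.72)
  truth <- pi * 31.2 * 27.72
  errs <- sapply(c(1, 0.5, 0.25), function(p) abs(area(ell, pitch = p) - truth))
  expect_true(all(diff(errs) < 0))
})

test_that("centroid matches symmetry and decomposition oracles", {
  expect_equal(centroid(region_ellipse(31.2, 27.72)), c(0, 0), tolerance = 1e-9)
  sh <- centroid(region_ellipse(20, 10, center = c(7.3, -2.1)))
  expect_equal(sh, c(7.3, -2.1), tolerance = 0.05)
  # L-shape = 20x10 rectangle at (10,5) plus 10x10 square at (5,15)
  L <- region2d(list(rbind(c(0, 0), c(20, 0), c(20, 10), c(10, 10), c(10, 20), c(0, 20))))
  want <- (200 * c(10, 5) + 100 * c(5, 15)) / 300
  expect_equal(centroid(L), want, tolerance = 0.05)
  flat <- region2d(list(rbind(c(0, 0), c(5, 0), c(10, 0))), validate = FALSE)
  expect_error(centroid(flat), class = "cranioplan_geometry_error")
})

test_that("min_distance agrees with the dense-sampling oracle", {
  seg <- rbind(c(-10, 0), c(10, 0))
  expect_equal(min_distance(c(0, 0), polyline2d(seg)), 0)
  expect_equal(min_distance(c(0, 5), polyline2d(seg)), 5)
  # beyond an endpoint: distance to the endpoint
  expect_equal(min_distance(c(14, 3), polyline2d(seg)), 5)
  set.seed(7)
  for (i in 1:5) {
    pl <- matrix(runif(8, -20, 20), ncol = 2)
    p <- runif(2, -30, 30)
    expect_equal(min_distance(p, polyline2d(pl)),
                 oracle_polyline_distance(p, pl, n = 50000), tolerance = 1e-6)
  }
})
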