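# Orthographic projection: silhouettes, on-surface drawings, edge margins.

test_that("assessment plane basis is orthonormal and right-handed", {
  for (axis in list(c(0, 0, 1), c(1, 1, 1), c(0, 1, 0))) {
    pl <- assessment_plane(c(1, 2, 3), axis)
    expect_equal(sum(pl$b1 * pl$b2), 0, tolerance = 1e-12)
    expect_equal(sum(pl$b1 * pl$axis), 0, tolerance = 1e-12)
    expect_equal(sqrt(sum(pl$b1^2)), 1, tolerance = 1e-12)
    cr <- c(pl$b1[2] * pl$b2[3] - pl$b1[3] * pl$b2[2],
            pl$b1[3] * pl$b2[1] - pl$b1[1] * pl$b2[3],
            pl$b1[1] * pl$b2[2] - pl$b1[2] * pl$b2[1])
    expect_equal(cr, pl$axis, tolerance = 1e-12)
  }
})

test_that("ellipsoid silhouettes reproduce closed-form areas", {
  expect_equal(area(default_silhouette), pi * 31.2 * 27.72, tolerance = 0.01)
  pl <- assessment_plane()
  s <- project_silhouette(ellipsoid_mesh(c(10, 10, 10)), pl)
  expect_equal(area(s), pi * 100, tolerance = 0.01)
  s2 <- project_silhouette(ellipsoid_mesh(c(20, 20, 20)), pl)
  expect_equal(area(s2) / area(s), 4, tolerance = 0.01)
})

test_that("raster silhouette path handles non-convex meshes", {
  # L-shaped prism: 20x20 slab minus a 10x10 quadrant, thickness 4
  L2d <- rbind(c(0, 0), c(20, 0), c(20, 10), c(10, 10), c(10, 20), c(0, 20))
  n <- nrow(L2d)
  v <- rbind(cbind(L2d, 0), cbind(L2d, 4))
  # wall faces
  fw <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- i %% n + 1
    rbind(c(i, j, n + j), c(i, n + j, n + i))
  }))
  # cap faces: fan from an interior-ish corner works for this L (vertex 4 sees all)
  caps <- do.call(rbind, lapply(c(1, 2, 5, 6), function(i) {
    j <- i %% n + 1
    rbind(c(4, i, j), c(n + 4, n + j, n + i))
  }))
  mesh <- trimesh(v, rbind(fw, caps))
  s <- project_silhouette(mesh, assessment_plane(), method = "raster", pitch = 0.25)
  expect_equal(area(s), 300, tolerance = 0.02)
})

test_that("drawings round-trip scalp lift and projection, and off-surface points fail", {
  model <- default_model
  lifted <- lapply(default_silhouette$rings, cranioplan:::lift_to_surface,
                   plane = model$plane, mesh = model$scalp_mesh)
  back <- project_drawing(lifted, model$plane, model$scalp_mesh, type = "region")
  expect_equal(area(back), area(default_silhouette), tolerance = 1e-6)
  off <- lifted[[1]]
  off[1, ] <- off[1, ] + c(0, 0, 25)
  expect_error(project_drawing(list(off), model$plane, model$scalp_mesh, type = "region"),
               class = "cranioplan_off_surface")
  bow3 <- cbind(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10)), 0)
  expect_error(project_drawing(bow3, assessment_plane(), type = "region"),
               class = "cranioplan_geometry_error")
  expect_error(project_drawing(cbind(1, 2, 3), assessment_plane(), type = "polyline"),
               class = "cranioplan_invalid_input")
})

test_that("edge margins follow the midpoint-ray convention and sign rules", {
  circ <- region_circle(25, n = 512)
  cen <- c(0, 0)
  sq35 <- square_quad(35)
  m <- sapply(1:4, function(i) edge_margin(sq35, i, circ, centre = cen))
  expect_equal(m, rep(10, 4), tolerance = 0.01)
  # edge line at 46.8 mm from the center of a 25 mm circle
  m468 <- edge_margin(square_quad(46.8), 1, circ, centre = cen)
  expect_equal(m468, 21.8, tolerance = 0.01)
  # an edge running through the centroid has a negative margin
  through <- quad2d(rbind(c(0, 40), c(0, -40), c(40, -40), c(40, 40)))
  expect_lt(edge_margin(through, 1, circ, centre = cen), 0)
  # segment-min convention: same value for a tangent-offset square edge
  ms <- edge_margin(sq35, 1, circ, centre = cen, convention = "segment-min")
  expect_equal(ms, 10, tolerance = 0.01)
  inside <- quad2d(rbind(c(5, 5), c(-5, 5), c(-5, -5), c(5, -5)))
  expect_lt(edge_margin(inside, 1, circ, centre = cen, convention = "segment-min"), 0)
})
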