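# Triangle meshes: closed-form areas/volumes, watertightness, queries.

test_that("icosphere area and volume converge to the closed forms", {
  m <- cranioplan:::unit_sphere_mesh(3)
  expect_true(mesh_is_watertight(m))
  expect_equal(mesh_area(m), 4 * pi, tolerance = 0.01)
  expect_equal(mesh_volume(m), 4 / 3 * pi, tolerance = 0.01)
  # inscribed: always from below
  expect_lt(mesh_area(m), 4 * pi)
  m4 <- cranioplan:::unit_sphere_mesh(4)
  expect_lt(abs(mesh_area(m4) - 4 * pi), abs(mesh_area(m) - 4 * pi))
})

test_that("ellipsoid meshes scale areas and volumes correctly", {
  e <- ellipsoid_mesh(c(31.2, 27.72, 20), subdivisions = 3)
  expect_true(mesh_is_watertight(e))
  expect_equal(mesh_volume(e), 4 / 3 * pi * 31.2 * 27.72 * 20, tolerance = 0.01)
  e2 <- ellipsoid_mesh(2 * c(31.2, 27.72, 20), subdivisions = 3)
  expect_equal(mesh_volume(e2) / mesh_volume(e), 8, tolerance = 1e-9)
  expect_error(ellipsoid_mesh(c(1, 0, 1)), class = "cranioplan_invalid_spec")
})

test_that("point-to-mesh distance is exact for spheres", {
  s <- ellipsoid_mesh(c(10, 10, 10), subdivisions = 3)
  d <- point_mesh_distance(rbind(c(0, 0, 0), c(0, 0, 10), c(0, 0, 15)), s)
  expect_equal(d[1], 10, tolerance = 0.01)
  expect_equal(d[2], 0, tolerance = 0.01)
  expect_equal(d[3], 5, tolerance = 0.01)
})

test_that("welding merges coincident vertices and drops degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1e-9, 1e-9, 0))
  f <- rbind(c(1, 2, 3), c(4, 2, 3))
  w <- mesh_weld(trimesh(v, f), digits = 6)
  expect_equal(nrow(w$vertices), 3)
  expect_equal(nrow(w$faces), 2)
})
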