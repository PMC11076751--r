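# Phantom generator: spec validation, meshes, voxelization, isosurfaces.

test_that("phantom spec enforces its invariants", {
  expect_error(phantom_spec(tumor_semiaxes = c(31.2, 0, 20)),
               class = "cranioplan_invalid_spec")
  expect_error(phantom_spec(tumor_semiaxes = c(-1, 5, 5)),
               class = "cranioplan_invalid_spec")
  # tumor poking through the skull inner surface
  expect_error(phantom_spec(tumor_center = c(0, 0, 60)),
               class = "cranioplan_invalid_spec")
  expect_error(phantom_spec(skull_offset = 50, skull_thickness = 50),
               class = "cranioplan_invalid_spec")
  expect_equal(sqrt(sum(phantom_spec(projection_axis = c(0, 0, 3))$projection_axis^2)), 1)
})

test_that("default phantom reproduces the calibrated tumor silhouette area", {
  expect_true(mesh_is_watertight(default_model$scalp_mesh))
  expect_true(mesh_is_watertight(default_model$tumor_mesh))
  expect_equal(area(default_silhouette), 2717, tolerance = 0.01)
  # tumor strictly inside the scalp
  expect_true(all(point_mesh_distance(
    default_model$tumor_mesh$vertices[seq(1, 2562, by = 100), ],
    default_model$scalp_mesh) > 1))
  # spherical tumor: silhouette is a circle
  sph <- build_phantom(phantom_spec(tumor_semiaxes = c(20, 20, 20)))
  expect_equal(area(tumor_silhouette(sph)), pi * 400, tolerance = 0.01)
})

test_that("voxelization recovers the tumor volume and labels shells correctly", {
  spec <- phantom_spec()
  vol <- voxelize(spec, pitch = 1)
  vt <- sum(vol$labels == 4) * 1^3
  expect_equal(vt, 4 / 3 * pi * prod(spec$tumor_semiaxes), tolerance = 0.05)
  expect_setequal(sort(unique(as.vector(vol$labels))), 0:4)
  # label priority: the tumor center voxel is tumor, not brain space
  ijk <- round((spec$tumor_center - vol$origin) / vol$pitch) + 1
  expect_equal(vol$labels[ijk[1], ijk[2], ijk[3]], 4L)
  expect_error(voxelize(spec, pitch = 6), class = "cranioplan_resolution_error")
})

test_that("halving the voxel pitch shrinks the tumor volume error", {
  spec <- small_sphere_spec(r = 16)
  truth <- 4 / 3 * pi * 16^3
  errs <- sapply(c(2, 1, 0.5), function(p) {
    abs(sum(voxelize(spec, pitch = p)$labels == 4) * p^3 - truth)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("extracted isosurfaces converge to analytic sphere area and volume", {
  spec <- small_sphere_spec(r = 20)
  vol <- voxelize(spec, pitch = 0.5)
  m <- extract_surface(vol, 4)
  expect_true(mesh_is_watertight(m))
  expect_equal(mesh_area(m), 4 * pi * 400, tolerance = 0.02)
  expect_equal(mesh_volume(m), 4 / 3 * pi * 8000, tolerance = 0.02)
  expect_error(extract_surface(vol, 9), class = "cranioplan_not_found")
  # area error decreases monotonically over pitch halvings
  errs <- sapply(c(2, 1, 0.5), function(p) {
    mp <- extract_surface(voxelize(spec, pitch = p), 4)
    abs(mesh_area(mp) - 4 * pi * 400)
  })
  expect_true(all(diff(errs) < 0))
  # extracted mesh lives in mm coordinates: centroid near the tumor center
  expect_equal(colMeans(m$vertices), spec$tumor_center, tolerance = 0.1)
})
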