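# Shared fixtures, built once per test run.

default_model <- build_phantom()
default_silhouette <- tumor_silhouette(default_model)
default_centre <- centroid(default_silhouette)

# a small phantom for voxel-heavy tests
small_sphere_spec <- function(r = 20) {
  phantom_spec(scalp_semiaxes = c(40, 40, 40), skull_offset = 4, skull_thickness = 4,
               tumor_semiaxes = c(r, r, r), tumor_center = c(0, 0, 0),
               voxel_pitch = 1)
}

# square craniotomy with all four edge lines at distance `half` from origin
square_quad <- function(half) {
  quad2d(rbind(c(half, half), c(-half, half), c(-half, -half), c(half, -half)))
}
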