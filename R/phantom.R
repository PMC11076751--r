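# Synthetic layered head phantom: nested ellipsoidal scalp and skull shells
# with an ellipsoidal tumor under a gently curved superior scalp patch.
#
# The default geometry is calibrated so the tumor's orthographic silhouette
# on the assessment plane has area pi * 31.2 * 27.72 ~= 2717 mm^2, matching
# the reference parasagittal tumor's scalp-projected area.

#' Phantom specification
#'
#' Defines a layered head phantom: an ellipsoidal scalp, a skull shell
#' starting `skull_offset` mm inside the scalp with thickness
#' `skull_thickness`, and an ellipsoidal tumor whose first two semi-axes lie
#' in the assessment plane (perpendicular to `projection_axis`).
#'
#' @param scalp_semiaxes Scalp ellipsoid semi-axes (mm).
#' @param skull_offset Inward distance from scalp to the outer skull surface (mm).
#' @param skull_thickness Skull shell thickness (mm).
#' @param tumor_semiaxes Tumor semi-axes (mm), in-plane pair first; the
#'   default (31.2, 27.72, 20) gives a silhouette area of ~2717 mm^2.
#' @param tumor_center Tumor center (mm) in world coordinates.
#' @param projection_axis Direction of orthographic projection (normalized).
#' @param voxel_pitch Default voxel size for [voxelize()] (mm).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(scalp_semiaxes = c(90, 75, 80),
                         skull_offset = 6,
                         skull_thickness = 6,
                         tumor_semiaxes = c(31.2, 27.72, 20),
                         tumor_center = c(0, 0, 35),
                         projection_axis = c(0, 0, 1),
                         voxel_pitch = 1) {
  if (!is_num(scalp_semiaxes, 3) || any(scalp_semiaxes <= 0)) {
    abort_invalid_spec("`scalp_semiaxes` must be three positive numbers (mm).")
  }
  if (!is_num(tumor_semiaxes, 3) || any(tumor_semiaxes <= 0)) {
    abort_invalid_spec("`tumor_semiaxes` must be three positive numbers (mm).")
  }
  if (!is_num(skull_offset, 1) || skull_offset <= 0 ||
      !is_num(skull_thickness, 1) || skull_thickness <= 0) {
    abort_invalid_spec("Skull offset and thickness must be positive (mm).")
  }
  if (!is_num(tumor_center, 3)) abort_invalid_spec("`tumor_center` must be finite (mm).")
  if (!is_num(projection_axis, 3) || sqrt(sum(projection_axis^2)) < 1e-12) {
    abort_invalid_spec("`projection_axis` must be a non-zero vector.")
  }
  if (!is_num(voxel_pitch, 1) || voxel_pitch <= 0) {
    abort_invalid_spec("`voxel_pitch` must be positive (mm).")
  }
  inner <- scalp_semiaxes - skull_offset - skull_thickness
  if (any(inner <= 0)) {
    abort_invalid_spec("Skull shell leaves no room: offset + thickness exceeds a scalp semi-axis.")
  }
  spec <- structure(list(
    scalp_semiaxes = as.numeric(scalp_semiaxes),
    skull_offset = as.numeric(skull_offset),
    skull_thickness = as.numeric(skull_thickness),
    tumor_semiaxes = as.numeric(tumor_semiaxes),
    tumor_center = as.numeric(tumor_center),
    projection_axis = as.numeric(projection_axis / sqrt(sum(projection_axis^2))),
    voxel_pitch = as.numeric(voxel_pitch)
  ), class = "phantom_spec")
  check_tumor_inside(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  scalp semi-axes : %s mm\n", paste(x$scalp_semiaxes, collapse = ", ")))
  cat(sprintf("  skull shell     : %g mm offset, %g mm thick\n", x$skull_offset, x$skull_thickness))
  cat(sprintf("  tumor semi-axes : %s mm at (%s)\n",
              paste(x$tumor_semiaxes, collapse = ", "),
              paste(x$tumor_center, collapse = ", ")))
  cat(sprintf("  silhouette area : %.1f mm^2 (closed form)\n",
              pi * x$tumor_semiaxes[1] * x$tumor_semiaxes[2]))
  invisible(x)
}

spec_plane <- function(spec) assessment_plane(spec$tumor_center, spec$projection_axis)

tumor_rotation <- function(spec) {
  pl <- spec_plane(spec)
  cbind(pl$b1, pl$b2, pl$axis)
}

check_tumor_inside <- function(spec) {
  inner <- spec$scalp_semiaxes - spec$skull_offset - spec$skull_thickness
  R <- tumor_rotation(spec)
  th <- seq(0, pi, length.out = 33)
  ph <- seq(0, 2 * pi, length.out = 65)[-65]
  g <- expand.grid(th = th, ph = ph)
  pts <- cbind(spec$tumor_semiaxes[1] * sin(g$th) * cos(g$ph),
               spec$tumor_semiaxes[2] * sin(g$th) * sin(g$ph),
               spec$tumor_semiaxes[3] * cos(g$th))
  world <- sweep(pts %*% t(R), 2, spec$tumor_center, "+")
  q <- rowSums(sweep(world, 2, inner, "/")^2)
  if (max(q) >= 1) {
    abort_invalid_spec(sprintf(
      "Tumor extends outside the inner skull surface (max quadratic form %.3f >= 1).", max(q)))
  }
  invisible(TRUE)
}

#' Build phantom meshes
#'
#' Produces watertight surface meshes for scalp, skull (outer surface) and
#' tumor, plus the shared assessment plane (origin at the tumor center,
#' normal along the projection axis).
#'
#' @param spec A [phantom_spec()].
#' @param tumor_subdivisions,shell_subdivisions Icosphere subdivision levels
#'   for the tumor and the scalp/skull layers.
#' @return A `phantom_model` with fields `scalp_mesh`, `skull_mesh`,
#'   `tumor_mesh`, `plane`, `spec`.
#' @export
build_phantom <- function(spec = phantom_spec(), tumor_subdivisions = 4L,
                          shell_subdivisions = 3L) {
  stopifnot(inherits(spec, "phantom_spec"))
  pl <- spec_plane(spec)
  model <- structure(list(
    scalp_mesh = ellipsoid_mesh(spec$scalp_semiaxes, subdivisions = shell_subdivisions),
    skull_mesh = ellipsoid_mesh(spec$scalp_semiaxes - spec$skull_offset,
                                subdivisions = shell_subdivisions),
    tumor_mesh = ellipsoid_mesh(spec$tumor_semiaxes, center = spec$tumor_center,
                                rotation = tumor_rotation(spec),
                                subdivisions = tumor_subdivisions),
    plane = pl,
    spec = spec
  ), class = "phantom_model")
  model
}

#' @export
print.phantom_model <- function(x, ...) {
  cat("<phantom_model>\n  layers: scalp, skull, tumor\n")
  print(x$spec)
  invisible(x)
}

#' Tumor silhouette of a phantom
#'
#' Convenience wrapper: orthographic silhouette of the tumor mesh on the
#' model's assessment plane.
#'
#' @param model A `phantom_model`.
#' @param ... Passed to [project_silhouette()].
#' @return A [region2d()].
#' @export
tumor_silhouette <- function(model, ...) {
  stopifnot(inherits(model, "phantom_model"))
  project_silhouette(model$tumor_mesh, model$plane, ...)
}

# label volume -----------------------------------------------------------

#' Voxel label volume
#'
#' @param labels Integer 3D array with labels 0 (background), 1 (scalp),
#'   2 (skull), 3 (brain space), 4 (tumor).
#' @param pitch Voxel size (mm, isotropic).
#' @param origin World coordinates (mm) of the center of voxel (1, 1, 1).
#' @return A `label_volume`.
#' @export
label_volume <- function(labels, pitch, origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3) {
    abort_invalid_input("`labels` must be a 3D array.")
  }
  if (!all(labels %in% 0:4)) abort_invalid_input("Labels must be integers in 0..4.")
  if (!is_num(pitch, 1) || pitch <= 0) abort_invalid_input("`pitch` must be positive.")
  structure(list(labels = labels, pitch = pitch, origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume: %s voxels at %g mm, labels {%s}>\n",
              paste(dim(x$labels), collapse = " x "), x$pitch,
              paste(sort(unique(as.vector(x$labels))), collapse = ",")))
  invisible(x)
}

#' Voxelize a phantom into a label volume
#'
#' Samples the phantom's analytic geometry on a regular grid of voxel
#' centers. Label priority at overlapping shells is tumor > skull > scalp;
#' voxels inside the inner skull surface but outside the tumor are brain
#' space (3) and everything outside the scalp is background (0).
#'
#' @param spec A [phantom_spec()].
#' @param pitch Voxel size (mm); defaults to the spec's `voxel_pitch`. Must
#'   be fine enough that the tumor spans at least 8 voxels per axis.
#' @return A [label_volume()].
#' @export
voxelize <- function(spec = phantom_spec(), pitch = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(pitch)) pitch <- spec$voxel_pitch
  if (!is_num(pitch, 1) || pitch <= 0) abort_invalid_input("`pitch` must be positive.")
  if (2 * min(spec$tumor_semiaxes) / pitch < 8) {
    abort_resolution(sprintf(
      "Voxel pitch %g mm too coarse: tumor must span >= 8 voxels per axis.", pitch))
  }
  s <- spec$scalp_semiaxes
  xs <- seq(-s[1] - pitch, s[1] + pitch, by = pitch)
  ys <- seq(-s[2] - pitch, s[2] + pitch, by = pitch)
  zs <- seq(-s[3] - pitch, s[3] + pitch, by = pitch)
  inner <- s - spec$skull_offset - spec$skull_thickness
  outer_sk <- s - spec$skull_offset
  ell <- function(ax) {
    ex <- (xs / ax[1])^2; ey <- (ys / ax[2])^2; ez <- (zs / ax[3])^2
    outer(outer(ex, ey, "+"), ez, "+")
  }
  q_scalp <- ell(s)
  lab <- array(0L, dim = c(length(xs), length(ys), length(zs)))
  lab[q_scalp <= 1] <- 1L
  q_sk <- ell(outer_sk)
  lab[q_sk <= 1] <- 2L
  q_in <- ell(inner)
  lab[q_in <= 1] <- 3L
  # tumor in its rotated frame, slice by slice to bound memory
  R <- tumor_rotation(spec)
  a <- spec$tumor_semiaxes
  gxy <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  for (k in seq_along(zs)) {
    d <- cbind(gxy[, 1] - spec$tumor_center[1],
               gxy[, 2] - spec$tumor_center[2],
               zs[k] - spec$tumor_center[3])
    loc <- d %*% R
    qt <- (loc[, 1] / a[1])^2 + (loc[, 2] / a[2])^2 + (loc[, 3] / a[3])^2
    sl <- lab[, , k]
    sl[qt <= 1] <- 4L
    lab[, , k] <- sl
  }
  if (!any(lab == 4L)) {
    abort_resolution("No tumor voxels at this pitch; refine the grid.")
  }
  label_volume(lab, pitch, origin = c(xs[1], ys[1], zs[1]))
}
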