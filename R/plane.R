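# The assessment plane: a single orthographic projection plane shared by the
# tumor silhouette and all participant drawings. Its normal is the phantom's
# projection axis and its origin the tumor centroid, so every area, overlap
# and distance metric is computed in one common 2D coordinate system.

#' Assessment plane
#'
#' @param origin Point on the plane (mm).
#' @param axis Plane normal (projection direction); normalized internally.
#' @return An `assessment_plane` with orthonormal in-plane basis `b1`, `b2`.
#' @export
assessment_plane <- function(origin = c(0, 0, 0), axis = c(0, 0, 1)) {
  if (!is_num(origin, 3) || !is_num(axis, 3)) {
    abort_invalid_input("`origin` and `axis` must be finite length-3 vectors.")
  }
  nz <- sqrt(sum(axis^2))
  if (nz < 1e-12) abort_invalid_input("`axis` must be non-zero.")
  axis <- axis / nz
  up <- if (abs(axis[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
  b1 <- c(up[2] * axis[3] - up[3] * axis[2],
          up[3] * axis[1] - up[1] * axis[3],
          up[1] * axis[2] - up[2] * axis[1])
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(axis[2] * b1[3] - axis[3] * b1[2],
          axis[3] * b1[1] - axis[1] * b1[3],
          axis[1] * b1[2] - axis[2] * b1[1])
  structure(list(origin = origin, axis = axis, b1 = b1, b2 = b2),
            class = "assessment_plane")
}

#' @export
print.assessment_plane <- function(x, ...) {
  cat(sprintf("<assessment_plane: origin (%g, %g, %g), axis (%g, %g, %g)>\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Convert between 3D and in-plane coordinates
#'
#' `to_plane()` orthographically projects 3D points into (u, v) plane
#' coordinates; `from_plane()` lifts (u, v) back to 3D, optionally offset
#' along the plane normal.
#'
#' @param points Coordinate matrix (n x 3 for `to_plane`, n x 2 for
#'   `from_plane`).
#' @param plane An [assessment_plane()].
#' @param offset Signed offset along the plane normal (mm).
#' @return Coordinate matrix.
#' @export
to_plane <- function(points, plane) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- sweep(points, 2, plane$origin, "-")
  cbind(d %*% plane$b1, d %*% plane$b2)
}

#' @rdname to_plane
#' @export
from_plane <- function(points, plane, offset = 0) {
  points <- matrix(as.numeric(points), ncol = 2)
  base <- outer(points[, 1], plane$b1) + outer(points[, 2], plane$b2)
  sweep(base, 2, plane$origin + offset * plane$axis, "+")
}

#' Orthographic silhouette of a mesh
#'
#' The outline of the mesh's shadow on the assessment plane. For convex
#' meshes (the analytic phantom layers) the silhouette is the convex hull of
#' the projected vertices, which is exact up to mesh resolution. For general
#' meshes the triangle shadows are rasterized and the outline is extracted by
#' marching-squares contouring.
#'
#' @param mesh A watertight [trimesh()].
#' @param plane An [assessment_plane()].
#' @param method `"auto"` (hull when the mesh is marked convex), `"hull"`,
#'   or `"raster"`.
#' @param pitch Raster pitch (mm) for the raster path.
#' @return A [region2d()].
#' @export
project_silhouette <- function(mesh, plane, method = c("auto", "hull", "raster"),
                               pitch = NULL) {
  stopifnot(inherits(mesh, "trimesh"), inherits(plane, "assessment_plane"))
  method <- arg_match(method)
  if (nrow(mesh$faces) < 4) abort_geometry("Mesh is degenerate (fewer than 4 faces).")
  if (method == "auto") method <- if (isTRUE(attr(mesh, "convex"))) "hull" else "raster"
  p2 <- to_plane(mesh$vertices, plane)
  if (method == "hull") {
    h <- grDevices::chull(p2)
    if (length(h) < 3) abort_geometry("Projected mesh is degenerate.")
    return(region2d(list(p2[rev(h), , drop = FALSE]), validate = FALSE))
  }
  pitch <- resolve_pitch(pitch)
  tri <- cbind(p2[mesh$faces[, 1], , drop = FALSE],
               p2[mesh$faces[, 2], , drop = FALSE],
               p2[mesh$faces[, 3], , drop = FALSE])
  g <- raster_grid(c(xmin = min(p2[, 1]), xmax = max(p2[, 1]),
                     ymin = min(p2[, 2]), ymax = max(p2[, 2])), pitch)
  mask <- matrix(FALSE, length(g$xs), length(g$ys))
  x0 <- g$xs[1]; y0 <- g$ys[1]
  nx <- length(g$xs); ny <- length(g$ys)
  for (i in seq_len(nrow(tri))) {
    tx <- tri[i, c(1, 3, 5)]; ty <- tri[i, c(2, 4, 6)]
    jlo <- max(1L, ceiling((min(ty) - y0) / pitch) + 1L)
    jhi <- min(ny, floor((max(ty) - y0) / pitch) + 1L)
    if (jlo > jhi) next
    for (j in jlo:jhi) {
      yc <- g$ys[j]
      xs <- numeric(0)
      for (k in 1:3) {
        k2 <- k %% 3 + 1
        y1 <- ty[k]; y2 <- ty[k2]
        if ((y1 <= yc) != (y2 <= yc)) {
          xs <- c(xs, tx[k] + (yc - y1) / (y2 - y1) * (tx[k2] - tx[k]))
        }
      }
      if (length(xs) < 2) next
      ilo <- max(1L, ceiling((min(xs) - x0) / pitch) + 1L)
      ihi <- min(nx, floor((max(xs) - x0) / pitch) + 1L)
      if (ilo <= ihi) mask[ilo:ihi, j] <- TRUE
    }
  }
  if (!any(mask)) abort_geometry("Projected mesh has empty shadow at this pitch.")
  mask_to_region(mask, g)
}

#' Project a drawing made on a model layer into the assessment plane
#'
#' Participant drawings live on the scalp or bone surface as 3D points. This
#' checks that every point lies on (or within `tolerance` of) the named
#' layer's mesh and then projects orthographically into the plane, preserving
#' the drawing's type: painted regions stay closed regions, incisions stay
#' open polylines, craniotomies stay quadrilaterals.
#'
#' @param points Numeric n x 3 matrix of on-surface coordinates (mm), or a
#'   list of such matrices for a multi-ring painted region.
#' @param plane An [assessment_plane()].
#' @param mesh The layer mesh the points must lie on.
#' @param type `"region"`, `"polyline"`, `"quad"`, or `"points"`.
#' @param tolerance Maximum allowed distance from the layer surface (mm).
#' @return A [region2d()], [polyline2d()], [quad2d()], or coordinate matrix.
#' @export
project_drawing <- function(points, plane, mesh = NULL,
                            type = c("region", "polyline", "quad", "points"),
                            tolerance = 1.5) {
  type <- arg_match(type)
  pts_list <- if (is.list(points) && !is.matrix(points)) points else list(points)
  pts_list <- lapply(pts_list, function(p) matrix(as.numeric(p), ncol = 3))
  if (!is.null(mesh)) {
    for (p in pts_list) {
      d <- point_mesh_distance(p, mesh)
      if (any(d > tolerance)) {
        abort_off_surface(sprintf(
          "%d point(s) lie farther than %.2f mm from the layer surface (max %.2f mm).",
          sum(d > tolerance), tolerance, max(d)))
      }
    }
  }
  proj <- lapply(pts_list, to_plane, plane = plane)
  switch(type,
    region = region2d(proj),
    polyline = {
      if (nrow(proj[[1]]) < 2) abort_invalid_input("A polyline needs >= 2 vertices.")
      polyline2d(proj[[1]])
    },
    quad = quad2d(proj[[1]]),
    points = proj[[1]])
}

# Lift in-plane points onto a mesh surface by casting rays along the plane
# normal; points whose ray misses the mesh fall back to their closest point
# on the surface.
lift_to_surface <- function(points2d, plane, mesh) {
  points2d <- matrix(as.numeric(points2d), ncol = 2)
  fc <- face_corners(mesh)
  start <- from_plane(points2d, plane, offset = 0)
  out <- matrix(NA_real_, nrow(points2d), 3)
  for (i in seq_len(nrow(points2d))) {
    t <- ray_mesh_hits(start[i, ], plane$axis, fc)
    if (all(is.na(t))) {
      out[i, ] <- closest_point_on_mesh(start[i, ], fc)
    } else {
      out[i, ] <- start[i, ] + max(t, na.rm = TRUE) * plane$axis
    }
  }
  out
}

closest_point_on_mesh <- function(p, fc) {
  # brute-force: evaluate the closest point on every face, keep the best
  best <- NULL; bestd <- Inf
  n <- nrow(fc$p1)
  u <- fc$p2 - fc$p1; v <- fc$p3 - fc$p1
  w <- cbind(p[1] - fc$p1[, 1], p[2] - fc$p1[, 2], p[3] - fc$p1[, 3])
  uu <- rowSums(u * u); vv <- rowSums(v * v); uv <- rowSums(u * v)
  wu <- rowSums(w * u); wv <- rowSums(w * v)
  den <- pmax(uu * vv - uv^2, .Machine$double.eps)
  s <- pmin(pmax((vv * wu - uv * wv) / den, 0), 1)
  t <- pmin(pmax((uu * wv - uv * wu) / den, 0), 1)
  over <- s + t > 1
  sc <- ifelse(over, s / (s + t), s)
  tc <- ifelse(over, t / (s + t), t)
  cand <- fc$p1 + sc * u + tc * v
  d <- rowSums(sweep(cand, 2, p, "-")^2)
  cand[which.min(d), ]
}
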