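# Planar geometry types: region2d (closed rings, even-odd), polyline2d, quad2d.
# All coordinates are millimetres in the assessment plane.

#' Planar region with even-odd ring semantics
#'
#' A `region2d` is one or more closed, non-self-intersecting rings in the
#' assessment plane. Even-odd semantics apply: a point is inside the region
#' if a ray from it crosses the combined boundary an odd number of times, so
#' disjoint rings form a union and nested rings punch holes.
#'
#' @param rings A list of numeric matrices (one per ring), each with two
#'   columns (x, y in mm) and at least three vertices. Rings may be given
#'   open or explicitly closed; a repeated final vertex is dropped.
#' @param validate Check ring simplicity (no self-intersections). Disable
#'   only for rings produced by transforms of already-validated regions.
#' @return A `region2d` object.
#' @export
region2d <- function(rings, validate = TRUE) {
  if (is.matrix(rings)) rings <- list(rings)
  if (!is.list(rings) || length(rings) == 0) {
    abort_invalid_input("`rings` must be a non-empty list of coordinate matrices.")
  }
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || !is_num(r)) {
      abort_invalid_input("Each ring must be a finite numeric matrix with columns x, y.")
    }
    if (nrow(r) > 1 && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3) abort_invalid_input("Each ring needs at least 3 distinct vertices.")
    dimnames(r) <- NULL
    r
  })
  if (validate) {
    for (r in rings) {
      if (ring_self_intersects(r)) {
        abort_geometry("Ring is self-intersecting; regions must be simple.")
      }
    }
  }
  structure(list(rings = rings), class = "region2d")
}

#' @export
print.region2d <- function(x, ...) {
  nv <- vapply(x$rings, nrow, integer(1))
  cat(sprintf("<region2d: %d ring(s), %s vertices>\n",
              length(x$rings), paste(nv, collapse = "+")))
  invisible(x)
}

#' Elliptical and circular regions
#'
#' Polygonal approximations (regular in parameter angle) of an ellipse or
#' circle, the basic building blocks for tumor silhouettes and painted areas.
#'
#' @param a,b Semi-axes in mm (`a` along x before rotation).
#' @param r Circle radius in mm.
#' @param center Center (x, y) in mm.
#' @param angle Rotation of the major axis, radians counterclockwise.
#' @param n Number of boundary vertices.
#' @return A `region2d`.
#' @export
region_ellipse <- function(a, b, center = c(0, 0), angle = 0, n = 256L) {
  if (!is_num(a, 1) || !is_num(b, 1) || a <= 0 || b <= 0) {
    abort_invalid_input("Ellipse semi-axes must be positive and finite.")
  }
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  p <- cbind(a * cos(th), b * sin(th))
  if (angle != 0) {
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
    p <- p %*% t(R)
  }
  p <- sweep(p, 2, center, "+")
  region2d(list(p), validate = FALSE)
}

#' @rdname region_ellipse
#' @export
region_circle <- function(r, center = c(0, 0), n = 256L) {
  region_ellipse(r, r, center = center, n = n)
}

#' Rectangular region
#'
#' @param width,height Side lengths in mm.
#' @param center Center (x, y) in mm.
#' @return A `region2d`.
#' @export
region_rectangle <- function(width, height, center = c(0, 0)) {
  if (!is_num(width, 1) || !is_num(height, 1) || width <= 0 || height <= 0) {
    abort_invalid_input("Rectangle sides must be positive.")
  }
  hw <- width / 2; hh <- height / 2
  p <- cbind(c(-hw, hw, hw, -hw), c(-hh, -hh, hh, hh))
  region2d(list(sweep(p, 2, center, "+")), validate = FALSE)
}

#' Combine regions under even-odd semantics
#'
#' Concatenates the rings of several regions. For disjoint regions this is a
#' union; overlapping rings cancel where they overlap (even-odd rule).
#'
#' @param ... `region2d` objects.
#' @return A `region2d`.
#' @export
region_combine <- function(...) {
  regs <- list(...)
  stopifnot(length(regs) > 0)
  for (r in regs) if (!inherits(r, "region2d")) {
    abort_invalid_input("All arguments must be region2d objects.")
  }
  region2d(do.call(c, lapply(regs, `[[`, "rings")), validate = FALSE)
}

#' Open polyline in the assessment plane
#'
#' @param coords Numeric matrix (n x 2) of vertices in mm, n >= 2. The
#'   polyline is open: no segment joins last to first vertex.
#' @return A `polyline2d` object.
#' @export
polyline2d <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2 || !is_num(coords) || nrow(coords) < 2) {
    abort_invalid_input("A polyline needs >= 2 finite (x, y) vertices.")
  }
  dimnames(coords) <- NULL
  structure(list(coords = coords), class = "polyline2d")
}

#' @export
print.polyline2d <- function(x, ...) {
  cat(sprintf("<polyline2d: %d vertices>\n", nrow(x$coords)))
  invisible(x)
}

#' Simple quadrilateral (craniotomy outline)
#'
#' Four vertices in order; edges are indexed 1-4 with edge i joining vertex i
#' to vertex i+1 (edge 4 closes the loop). The quad must be simple (no edge
#' crossings) with positive area.
#'
#' @param coords Numeric 4 x 2 matrix of vertices in mm.
#' @return A `quad2d` object.
#' @export
quad2d <- function(coords) {
  coords <- as.matrix(coords)
  if (!identical(dim(coords), c(4L, 2L)) || !is_num(coords)) {
    abort_invalid_input("A quad needs exactly 4 finite (x, y) vertices.")
  }
  dimnames(coords) <- NULL
  # non-adjacent edge pairs: (1,3) and (2,4)
  e <- function(i) list(a = coords[i, ], b = coords[i %% 4 + 1, ])
  if (segments_cross(e(1)$a, e(1)$b, e(3)$a, e(3)$b) ||
      segments_cross(e(2)$a, e(2)$b, e(4)$a, e(4)$b)) {
    abort_geometry("Quad edges cross; craniotomy outline must be simple.")
  }
  if (abs(polygon_signed_area(coords)) <= 0) {
    abort_geometry("Quad has zero area.")
  }
  structure(list(coords = coords), class = "quad2d")
}

#' @export
print.quad2d <- function(x, ...) {
  cat("<quad2d>\n")
  invisible(x)
}

#' Edge of a quadrilateral
#'
#' @param quad A `quad2d`.
#' @param i Edge index 1-4 (edge i joins vertex i to vertex i+1, cyclic).
#' @return A list with fields `a`, `b` (endpoints) and `midpoint`.
#' @export
quad_edge <- function(quad, i) {
  stopifnot(inherits(quad, "quad2d"))
  if (!i %in% 1:4) abort_invalid_input("Edge index must be 1, 2, 3 or 4.")
  a <- quad$coords[i, ]
  b <- quad$coords[i %% 4 + 1, ]
  list(a = a, b = b, midpoint = (a + b) / 2)
}

# rigid motions and scaling ----------------------------------------------

#' Apply an in-plane rigid motion (rotation then translation)
#'
#' @param x A `region2d`, `polyline2d`, `quad2d`, or coordinate matrix.
#' @param angle Rotation in radians, counterclockwise about `pivot`.
#' @param translate Translation vector (mm).
#' @param pivot Rotation pivot (mm).
#' @return Object of the same type.
#' @export
rigid_transform <- function(x, angle = 0, translate = c(0, 0), pivot = c(0, 0)) {
  UseMethod("rigid_transform")
}

apply_rigid <- function(m, angle, translate, pivot) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(sweep(m, 2, pivot, "-") %*% t(R), 2, pivot + translate, "+")
}

#' @export
rigid_transform.matrix <- function(x, angle = 0, translate = c(0, 0), pivot = c(0, 0)) {
  apply_rigid(x, angle, translate, pivot)
}

#' @export
rigid_transform.region2d <- function(x, angle = 0, translate = c(0, 0), pivot = c(0, 0)) {
  region2d(lapply(x$rings, apply_rigid, angle, translate, pivot), validate = FALSE)
}

#' @export
rigid_transform.polyline2d <- function(x, angle = 0, translate = c(0, 0), pivot = c(0, 0)) {
  polyline2d(apply_rigid(x$coords, angle, translate, pivot))
}

#' @export
rigid_transform.quad2d <- function(x, angle = 0, translate = c(0, 0), pivot = c(0, 0)) {
  quad2d(apply_rigid(x$coords, angle, translate, pivot))
}

#' Scale a region about a point
#'
#' Uniform scaling: scaling by `factor` multiplies areas by `factor^2`.
#'
#' @param region A `region2d`.
#' @param factor Positive linear scale factor.
#' @param center Fixed point of the scaling; defaults to the region centroid.
#' @param pitch Raster pitch for the centroid computation (mm).
#' @return A `region2d`.
#' @export
scale_region <- function(region, factor, center = NULL, pitch = NULL) {
  stopifnot(inherits(region, "region2d"))
  if (!is_num(factor, 1) || factor <= 0) abort_invalid_input("`factor` must be positive.")
  if (is.null(center)) center <- centroid(region, pitch = pitch)
  region2d(lapply(region$rings, function(r) {
    sweep(sweep(r, 2, center, "-") * factor, 2, center, "+")
  }), validate = FALSE)
}

# low-level predicates ---------------------------------------------------

cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])

segments_cross <- function(p1, p2, q1, q2) {
  d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
  d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

ring_self_intersects <- function(r) {
  n <- nrow(r)
  if (n < 4) return(FALSE)
  a <- r
  b <- r[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    # skip adjacent segments (shared vertex)
    js <- seq(i + 2, n)
    if (i == 1) js <- js[js != n]
    for (j in js) {
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

polygon_signed_area <- function(p) {
  n <- nrow(p)
  q <- p[c(2:n, 1), , drop = FALSE]
  sum(p[, 1] * q[, 2] - q[, 1] * p[, 2]) / 2
}

bbox_of <- function(coords_list) {
  m <- do.call(rbind, coords_list)
  c(xmin = min(m[, 1]), xmax = max(m[, 1]), ymin = min(m[, 2]), ymax = max(m[, 2]))
}
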