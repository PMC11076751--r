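# Distances and signed craniotomy edge margins.

point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}

# vectorized over segments: p (len 2), A, B (n x 2)
point_segments_dist <- function(p, A, B) {
  AB <- B - A
  len2 <- rowSums(AB^2)
  AP <- cbind(p[1] - A[, 1], p[2] - A[, 2])
  t <- rowSums(AP * AB) / pmax(len2, .Machine$double.eps)
  t[len2 == 0] <- 0
  t <- pmin(pmax(t, 0), 1)
  D <- AP - AB * t
  sqrt(rowSums(D^2))
}

#' Minimum distance from a point to a polyline
#'
#' Euclidean minimum over all segments of the polyline; used for the linear
#' incision's deviation from the tumor epicenter.
#'
#' @param point Numeric (x, y) in mm.
#' @param line A [polyline2d()].
#' @return Distance in mm (>= 0).
#' @export
min_distance <- function(point, line) {
  stopifnot(inherits(line, "polyline2d"))
  if (!is_num(point, 2)) abort_invalid_input("`point` must be finite (x, y).")
  cc <- line$coords
  n <- nrow(cc)
  min(point_segments_dist(point, cc[-n, , drop = FALSE], cc[-1, , drop = FALSE]))
}

# Distance along the ray origin + t * dir to the furthest boundary crossing
# of the region (t > 0). Returns NA if the ray never crosses the boundary.
ray_boundary_distance <- function(region, origin, dir) {
  best <- -Inf
  for (r in region$rings) {
    n <- nrow(r)
    A <- r
    B <- r[c(2:n, 1), , drop = FALSE]
    # solve origin + t d = A + s (B - A)
    ex <- B[, 1] - A[, 1]; ey <- B[, 2] - A[, 2]
    den <- dir[1] * (-ey) + dir[2] * ex
    ok <- abs(den) > 1e-12
    wx <- A[, 1] - origin[1]; wy <- A[, 2] - origin[2]
    t <- (wx * (-ey) + wy * ex) / den
    s <- (dir[1] * wy - dir[2] * wx) / den
    hit <- ok & t > 0 & s >= 0 & s < 1
    if (any(hit)) best <- max(best, max(t[hit]))
  }
  if (!is.finite(best)) return(NA_real_)
  best
}

point_in_region <- function(point, region) {
  as.logical(mgcv::in.out(region_boundary_matrix(region), matrix(point, 1, 2)))
}

#' Signed margin of a craniotomy edge relative to the tumor silhouette
#'
#' The reference convention (`"midpoint-ray"`) measures along the ray from
#' the silhouette centroid through the edge midpoint: the margin is the
#' distance from the silhouette boundary to the edge midpoint, positive when
#' the midpoint lies outside the silhouette and negative inside. The
#' alternative `"segment-min"` convention uses the unsigned minimum distance
#' between the edge segment and the silhouette boundary, signed by whether
#' the edge midpoint is outside the silhouette.
#'
#' @param quad A [quad2d()] craniotomy outline.
#' @param edge Edge index 1-4.
#' @param silhouette A [region2d()] tumor silhouette with positive area.
#' @param centre Optional precomputed silhouette centroid (mm); avoids
#'   re-rasterizing when scoring many edges against one silhouette.
#' @param convention `"midpoint-ray"` (reference) or `"segment-min"`.
#' @param pitch Raster pitch used if the centroid must be computed.
#' @return Signed margin in mm.
#' @export
edge_margin <- function(quad, edge, silhouette, centre = NULL,
                        convention = c("midpoint-ray", "segment-min"),
                        pitch = NULL) {
  stopifnot(inherits(quad, "quad2d"), inherits(silhouette, "region2d"))
  convention <- arg_match(convention)
  e <- quad_edge(quad, edge)
  if (is.null(centre)) centre <- centroid(silhouette, pitch = pitch)
  if (convention == "midpoint-ray") {
    v <- e$midpoint - centre
    len <- sqrt(sum(v^2))
    if (len < 1e-9) return(-ray_boundary_distance(silhouette, centre, c(1, 0)))
    tb <- ray_boundary_distance(silhouette, centre, v / len)
    if (is.na(tb)) {
      abort_undefined_margin("Centroid ray does not cross the silhouette boundary.")
    }
    len - tb
  } else {
    d <- min_boundary_segment_distance(silhouette, e$a, e$b)
    if (point_in_region(e$midpoint, silhouette)) -d else d
  }
}

min_boundary_segment_distance <- function(region, a, b) {
  best <- Inf
  for (r in region$rings) {
    n <- nrow(r)
    A <- r
    B <- r[c(2:n, 1), , drop = FALSE]
    for (i in seq_len(n)) {
      if (segments_cross(A[i, ], B[i, ], a, b)) return(0)
    }
    best <- min(best,
                min(point_segments_dist(a, A, B)),
                min(point_segments_dist(b, A, B)),
                min(point_segments_dist(a, A, B)))
    # distances from boundary vertices to the edge segment
    best <- min(best, min(point_segments_dist2(A, a, b)))
  }
  best
}

# distance from many points (n x 2) to one segment a-b
point_segments_dist2 <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  AP <- cbind(P[, 1] - a[1], P[, 2] - a[2])
  if (len2 == 0) return(sqrt(rowSums(AP^2)))
  t <- pmin(pmax((AP %*% ab) / len2, 0), 1)
  D <- AP - cbind(t * ab[1], t * ab[2])
  sqrt(rowSums(D^2))
}
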