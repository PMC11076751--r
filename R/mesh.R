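# Lightweight triangle meshes in mm coordinates.

#' Triangle mesh
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices; faces are
#'   oriented counterclockwise seen from outside.
#' @param convex Mark the mesh as convex (enables the exact hull-based
#'   silhouette path in [project_silhouette()]).
#' @return A `trimesh` object.
#' @export
trimesh <- function(vertices, faces, convex = FALSE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3 || !is_num(vertices)) {
    abort_invalid_input("`vertices` must be a finite n x 3 matrix.")
  }
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    abort_invalid_input("Face indices out of range.")
  }
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, faces = faces),
            class = "trimesh", convex = convex)
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(attr(x, "convex"))) ", convex" else ""))
  invisible(x)
}

face_corners <- function(mesh) {
  list(p1 = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       p2 = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       p3 = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Surface area and enclosed volume of a mesh
#'
#' Volume uses the divergence theorem over oriented faces and reports the
#' absolute value, so it is robust to a globally flipped orientation.
#'
#' @param mesh A [trimesh()].
#' @return Area in mm^2 / volume in mm^3.
#' @export
mesh_area <- function(mesh) {
  fc <- face_corners(mesh)
  nv <- cross3(fc$p2 - fc$p1, fc$p3 - fc$p1)
  sum(sqrt(rowSums(nv^2))) / 2
}

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  nv <- cross3(fc$p2 - fc$p1, fc$p3 - fc$p1) / 2
  cen <- (fc$p1 + fc$p2 + fc$p3) / 3
  abs(sum(rowSums(cen * nv)) / 3)
}

#' Is a mesh watertight?
#'
#' Checks that every undirected edge is shared by exactly two faces and that
#' the two incident faces traverse it in opposite directions (consistent
#' orientation, closed surface).
#'
#' @param mesh A [trimesh()].
#' @return Logical.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  undirected <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  directed <- paste(ea[, 1], ea[, 2])
  all(table(undirected) == 2L) && !anyDuplicated(directed)
}

#' Merge coincident vertices
#'
#' Rounds coordinates to `digits` decimals and merges duplicates, remapping
#' faces; degenerate faces produced by merging are dropped.
#'
#' @param mesh A [trimesh()].
#' @param digits Decimal digits used for coincidence.
#' @return A `trimesh`.
#' @export
mesh_weld <- function(mesh, digits = 6) {
  key <- apply(round(mesh$vertices, digits), 1, paste, collapse = ",")
  map <- match(key, unique(key))
  keep <- !duplicated(key)
  v <- mesh$vertices[keep, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)
  good <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  trimesh(v, f[good, , drop = FALSE], convex = isTRUE(attr(mesh, "convex")))
}

# icosphere --------------------------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  trimesh(v, f, convex = TRUE)
}

subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- c(edge_key(f[, 1], f[, 2]), edge_key(f[, 2], f[, 3]), edge_key(f[, 3], f[, 1]))
  uk <- unique(ek)
  pairs <- do.call(rbind, strsplit(uk, " "))
  a <- as.integer(pairs[, 1]); b <- as.integer(pairs[, 2])
  mid <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
  mid_idx <- nrow(v) + seq_along(uk)
  names(mid_idx) <- uk
  m12 <- mid_idx[edge_key(f[, 1], f[, 2])]
  m23 <- mid_idx[edge_key(f[, 2], f[, 3])]
  m31 <- mid_idx[edge_key(f[, 3], f[, 1])]
  nf <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  trimesh(rbind(v, mid), nf, convex = isTRUE(attr(mesh, "convex")))
}

unit_sphere_mesh <- function(subdivisions = 3L) {
  m <- icosahedron()
  for (i in seq_len(subdivisions)) m <- subdivide_mesh(m)
  v <- m$vertices / sqrt(rowSums(m$vertices^2))
  trimesh(v, m$faces, convex = TRUE)
}

#' Ellipsoid surface mesh
#'
#' Subdivided-icosahedron sphere scaled to the given semi-axes, optionally
#' rotated and translated. Watertight and convex by construction; vertices
#' lie exactly on the ellipsoid (the mesh is inscribed, so area and silhouette
#' slightly underestimate the analytic surface, vanishing with subdivision).
#'
#' @param semiaxes Positive semi-axes (mm) along the (possibly rotated)
#'   x, y, z directions.
#' @param center Center in mm.
#' @param rotation 3 x 3 rotation matrix mapping local to world axes.
#' @param subdivisions Icosahedron subdivision level (4 gives 5120 faces).
#' @return A [trimesh()].
#' @export
ellipsoid_mesh <- function(semiaxes, center = c(0, 0, 0), rotation = diag(3),
                           subdivisions = 4L) {
  if (!is_num(semiaxes, 3) || any(semiaxes <= 0)) {
    abort_invalid_spec("Ellipsoid semi-axes must be three positive numbers.")
  }
  m <- unit_sphere_mesh(subdivisions)
  v <- sweep(m$vertices, 2, semiaxes, "*") %*% t(rotation)
  v <- sweep(v, 2, center, "+")
  trimesh(v, m$faces, convex = TRUE)
}

# point-to-mesh distance -------------------------------------------------

# distance from one point to every face; returns min
point_triangles_dist <- function(p, P1, P2, P3) {
  # closest point on each triangle's plane, clamped to the triangle by
  # falling back to edge distances when the foot is outside
  u <- P2 - P1; v <- P3 - P1
  w <- cbind(p[1] - P1[, 1], p[2] - P1[, 2], p[3] - P1[, 3])
  uu <- rowSums(u * u); vv <- rowSums(v * v); uv <- rowSums(u * v)
  wu <- rowSums(w * u); wv <- rowSums(w * v)
  den <- uu * vv - uv^2
  den <- pmax(den, .Machine$double.eps)
  s <- (vv * wu - uv * wv) / den
  t <- (uu * wv - uv * wu) / den
  inside <- s >= 0 & t >= 0 & s + t <= 1
  d <- rep(Inf, nrow(P1))
  if (any(inside)) {
    foot <- P1[inside, , drop = FALSE] +
      s[inside] * u[inside, , drop = FALSE] + t[inside] * v[inside, , drop = FALSE]
    d[inside] <- sqrt(rowSums(sweep(foot, 2, p, "-")^2))
  }
  out <- which(!inside)
  if (length(out)) {
    d[out] <- pmin(point_segments_dist3(p, P1[out, , drop = FALSE], P2[out, , drop = FALSE]),
                   point_segments_dist3(p, P2[out, , drop = FALSE], P3[out, , drop = FALSE]),
                   point_segments_dist3(p, P3[out, , drop = FALSE], P1[out, , drop = FALSE]))
  }
  min(d)
}

point_segments_dist3 <- function(p, A, B) {
  AB <- B - A
  len2 <- rowSums(AB^2)
  AP <- cbind(p[1] - A[, 1], p[2] - A[, 2], p[3] - A[, 3])
  t <- rowSums(AP * AB) / pmax(len2, .Machine$double.eps)
  t[len2 == 0] <- 0
  t <- pmin(pmax(t, 0), 1)
  D <- AP - AB * t
  sqrt(rowSums(D^2))
}

#' Distance from points to a mesh surface
#'
#' @param points Numeric n x 3 matrix (mm).
#' @param mesh A [trimesh()].
#' @return Numeric vector of unsigned distances (mm).
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  fc <- face_corners(mesh)
  apply(points, 1, point_triangles_dist, P1 = fc$p1, P2 = fc$p2, P3 = fc$p3)
}

# ray casting (Moller-Trumbore), one ray vs all faces
ray_mesh_hits <- function(origin, dir, fc) {
  e1 <- fc$p2 - fc$p1
  e2 <- fc$p3 - fc$p1
  dmat <- matrix(dir, nrow(e1), 3, byrow = TRUE)
  pv <- cross3(dmat, e2)
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  tv <- cbind(origin[1] - fc$p1[, 1], origin[2] - fc$p1[, 2], origin[3] - fc$p1[, 3])
  u <- rowSums(tv * pv) / det
  qv <- cross3(tv, e1)
  v <- rowSums(qv * dmat) / det
  t <- rowSums(e2 * qv) / det
  t[!(ok & u >= 0 & v >= 0 & u + v <= 1)] <- NA
  t
}
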