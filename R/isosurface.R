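# Surface rendering: label volume -> triangle mesh.
#
# The binary label indicator is smoothed with a separable 1-2-1 kernel and
# the 0.5 isosurface is extracted by marching tetrahedra on the Kuhn 6-tet
# decomposition of each grid cell. The Kuhn decomposition tiles consistently
# across the lattice, so the mesh is watertight by construction; smoothing
# removes the voxel staircase so that surface area converges to the analytic
# area as the pitch shrinks (a raw binary indicator would overestimate the
# area of smooth shapes by ~27% at any resolution).

smooth_field_121 <- function(F, passes = 2L) {
  for (p in seq_len(passes)) {
    for (d in 1:3) {
      n <- dim(F)[d]
      lo <- pmax(seq_len(n) - 1L, 1L)
      hi <- pmin(seq_len(n) + 1L, n)
      F <- switch(d,
        (F[lo, , , drop = FALSE] + 2 * F + F[hi, , , drop = FALSE]) / 4,
        (F[, lo, , drop = FALSE] + 2 * F + F[, hi, , drop = FALSE]) / 4,
        (F[, , lo, drop = FALSE] + 2 * F + F[, , hi, drop = FALSE]) / 4)
    }
  }
  F
}

#' Extract an isosurface mesh for one label of a volume
#'
#' @param volume A [label_volume()].
#' @param label The label value to surface; must be present in the volume.
#' @param smoothing Number of 1-2-1 smoothing passes applied to the binary
#'   indicator before contouring (default 2). Zero gives the raw blocky
#'   marching surface.
#' @param level Isolevel in the smoothed indicator (default 0.5).
#' @return A watertight [trimesh()] in mm coordinates.
#' @export
extract_surface <- function(volume, label, smoothing = 2L, level = 0.5) {
  stopifnot(inherits(volume, "label_volume"))
  mask <- volume$labels == label
  if (!any(mask)) {
    abort_not_found(sprintf("Label %s not present in volume.", format(label)))
  }
  # crop to the label's bounding box (with margin) and pad with background
  idx <- which(mask, arr.ind = TRUE)
  pad <- 2L + as.integer(smoothing)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dim(mask))
  Fg <- array(0, hi - lo + 3L)  # one guaranteed zero layer around the crop
  Fg[2:(hi[1] - lo[1] + 2), 2:(hi[2] - lo[2] + 2), 2:(hi[3] - lo[3] + 2)] <-
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + 0
  Fg <- smooth_field_121(Fg, passes = smoothing)
  origin <- volume$origin + (lo - 2) * volume$pitch
  tri <- marching_tetrahedra(Fg, level = level, origin = origin, pitch = volume$pitch)
  mesh_weld(trimesh(tri$vertices, tri$faces), digits = 7)
}

# Marching tetrahedra over the Kuhn decomposition. Returns triangle soup
# (vertices with one entry per corner; faces index consecutively) oriented
# with outward normals (away from field values above the level).
marching_tetrahedra <- function(F, level, origin, pitch) {
  dm <- dim(F)
  nx <- dm[1] - 1L; ny <- dm[2] - 1L; nz <- dm[3] - 1L
  corner <- function(o) F[(1:nx) + o[1], (1:ny) + o[2], (1:nz) + o[3], drop = FALSE]
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  vmin <- corner(offs[1, ]); vmax <- vmin
  for (r in 2:8) {
    v <- corner(offs[r, ])
    vmin <- pmin(vmin, v); vmax <- pmax(vmax, v)
  }
  cells <- which(vmin < level & vmax >= level, arr.ind = TRUE)
  if (nrow(cells) == 0) abort_geometry("No isosurface at this level.")

  cellval <- function(o) F[cbind(cells[, 1] + o[1], cells[, 2] + o[2], cells[, 3] + o[3])]
  cellpos <- function(o) cbind(origin[1] + (cells[, 1] - 1 + o[1]) * pitch,
                               origin[2] + (cells[, 2] - 1 + o[2]) * pitch,
                               origin[3] + (cells[, 3] - 1 + o[3]) * pitch)
  interp <- function(va, vb, pa, pb) pa + ((level - va) / (vb - va)) * (pb - pa)

  tris <- list(); ti <- 0L
  emit <- function(p1, p2, p3, inref) {
    nv <- cross3(p2 - p1, p3 - p1)
    cen <- (p1 + p2 + p3) / 3
    flip <- rowSums(nv * (cen - inref)) < 0
    if (any(flip)) {
      tmp <- p2[flip, , drop = FALSE]
      p2[flip, ] <- p3[flip, , drop = FALSE]
      p3[flip, ] <- tmp
    }
    ti <<- ti + 1L
    tris[[ti]] <<- cbind(p1, p2, p3)
  }

  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  e <- diag(3)
  for (k in 1:6) {
    o0 <- c(0, 0, 0)
    o1 <- o0 + e[perms[k, 1], ]
    o2 <- o1 + e[perms[k, 2], ]
    O <- list(o0, o1, o2, c(1, 1, 1))
    V <- sapply(O, cellval)
    if (is.null(dim(V))) V <- matrix(V, nrow = 1)
    P <- lapply(O, cellpos)
    ins <- V >= level
    s <- rowSums(ins)
    for (a in 1:4) {
      ob <- setdiff(1:4, a)
      m <- which(s == 1 & ins[, a])
      if (length(m)) {
        ps <- lapply(ob, function(b) interp(V[m, a], V[m, b],
                                            P[[a]][m, , drop = FALSE],
                                            P[[b]][m, , drop = FALSE]))
        emit(ps[[1]], ps[[2]], ps[[3]], P[[a]][m, , drop = FALSE])
      }
      m <- which(s == 3 & !ins[, a])
      if (length(m)) {
        inref <- (P[[ob[1]]][m, , drop = FALSE] + P[[ob[2]]][m, , drop = FALSE] +
                    P[[ob[3]]][m, , drop = FALSE]) / 3
        ps <- lapply(ob, function(b) interp(V[m, b], V[m, a],
                                            P[[b]][m, , drop = FALSE],
                                            P[[a]][m, , drop = FALSE]))
        emit(ps[[1]], ps[[2]], ps[[3]], inref)
      }
    }
    for (pr in list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
      a <- pr[1]; b <- pr[2]
      m <- which(s == 2 & ins[, a] & ins[, b])
      if (!length(m)) next
      cd <- setdiff(1:4, pr)
      pac <- interp(V[m, a], V[m, cd[1]], P[[a]][m, , drop = FALSE], P[[cd[1]]][m, , drop = FALSE])
      pad <- interp(V[m, a], V[m, cd[2]], P[[a]][m, , drop = FALSE], P[[cd[2]]][m, , drop = FALSE])
      pbc <- interp(V[m, b], V[m, cd[1]], P[[b]][m, , drop = FALSE], P[[cd[1]]][m, , drop = FALSE])
      pbd <- interp(V[m, b], V[m, cd[2]], P[[b]][m, , drop = FALSE], P[[cd[2]]][m, , drop = FALSE])
      inref <- (P[[a]][m, , drop = FALSE] + P[[b]][m, , drop = FALSE]) / 2
      emit(pac, pad, pbd, inref)
      emit(pac, pbd, pbc, inref)
    }
  }
  soup <- do.call(rbind, tris)
  p1 <- soup[, 1:3, drop = FALSE]
  p2 <- soup[, 4:6, drop = FALSE]
  p3 <- soup[, 7:9, drop = FALSE]
  nv <- cross3(p2 - p1, p3 - p1)
  keep <- sqrt(rowSums(nv^2)) > 1e-12
  p1 <- p1[keep, , drop = FALSE]; p2 <- p2[keep, , drop = FALSE]; p3 <- p3[keep, , drop = FALSE]
  n <- nrow(p1)
  list(vertices = rbind(p1, p2, p3),
       faces = cbind(seq_len(n), seq_len(n) + n, seq_len(n) + 2L * n))
}
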