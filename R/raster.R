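# Rasterized reference semantics for planar areas and overlaps.
#
# Areas are measured by counting grid-cell centers inside a region. The grid
# is anchored to the global mm lattice (cell centers at (k + 1/2) * pitch), so
# two regions rasterized over different bounding boxes still share cells, and
# painted = covered + excess holds exactly at the cell level.

raster_grid <- function(bbox, pitch) {
  kx <- seq(floor(bbox[["xmin"]] / pitch) - 1L, ceiling(bbox[["xmax"]] / pitch))
  ky <- seq(floor(bbox[["ymin"]] / pitch) - 1L, ceiling(bbox[["ymax"]] / pitch))
  list(xs = (kx + 0.5) * pitch, ys = (ky + 0.5) * pitch, pitch = pitch)
}

region_boundary_matrix <- function(region) {
  # NA-separated closed loops in the form mgcv::in.out expects
  do.call(rbind, lapply(seq_along(region$rings), function(i) {
    r <- region$rings[[i]]
    r <- rbind(r, r[1, ])
    if (i < length(region$rings)) rbind(r, c(NA, NA)) else r
  }))
}

region_mask <- function(region, grid) {
  pts <- cbind(rep(grid$xs, times = length(grid$ys)),
               rep(grid$ys, each = length(grid$xs)))
  inside <- mgcv::in.out(region_boundary_matrix(region), pts)
  matrix(inside, nrow = length(grid$xs))
}

region_bbox <- function(region) bbox_of(region$rings)

#' Area of a planar region
#'
#' Measured under the package's rasterized reference semantics: the number of
#' grid-cell centers inside the region times the cell area. The relative
#' error is bounded by roughly `pitch * perimeter / area`.
#'
#' @param region A [region2d()].
#' @param pitch Raster pitch in mm; `NULL` uses [default_raster_pitch()].
#' @return Area in mm^2.
#' @export
area <- function(region, pitch = NULL) {
  stopifnot(inherits(region, "region2d"))
  pitch <- resolve_pitch(pitch)
  g <- raster_grid(region_bbox(region), pitch)
  sum(region_mask(region, g)) * pitch^2
}

#' Overlap area of two regions
#'
#' Rasterizes both regions on a common grid and counts cells inside both.
#' Symmetric, and never exceeds either region's area on the same grid.
#'
#' @param a,b [region2d()] objects.
#' @param pitch Raster pitch in mm.
#' @return Intersection area in mm^2.
#' @export
intersection_area <- function(a, b, pitch = NULL) {
  stopifnot(inherits(a, "region2d"), inherits(b, "region2d"))
  pitch <- resolve_pitch(pitch)
  ba <- region_bbox(a); bb <- region_bbox(b)
  if (ba[["xmin"]] > bb[["xmax"]] || bb[["xmin"]] > ba[["xmax"]] ||
      ba[["ymin"]] > bb[["ymax"]] || bb[["ymin"]] > ba[["ymax"]]) {
    return(0)
  }
  bbox <- c(xmin = max(ba[["xmin"]], bb[["xmin"]]), xmax = min(ba[["xmax"]], bb[["xmax"]]),
            ymin = max(ba[["ymin"]], bb[["ymin"]]), ymax = min(ba[["ymax"]], bb[["ymax"]]))
  g <- raster_grid(bbox, pitch)
  sum(region_mask(a, g) & region_mask(b, g)) * pitch^2
}

#' Area centroid of a region
#'
#' The mean position of raster cells inside the region (the "tumor epicenter"
#' when applied to the projected tumor silhouette).
#'
#' @param region A [region2d()].
#' @param pitch Raster pitch in mm.
#' @return Numeric (x, y) in mm.
#' @export
centroid <- function(region, pitch = NULL) {
  stopifnot(inherits(region, "region2d"))
  pitch <- resolve_pitch(pitch)
  g <- raster_grid(region_bbox(region), pitch)
  m <- region_mask(region, g)
  if (!any(m)) abort_geometry("Region has zero raster area; centroid undefined.")
  idx <- which(m, arr.ind = TRUE)
  c(mean(g$xs[idx[, 1]]), mean(g$ys[idx[, 2]]))
}

# Extract closed rings from a logical mask via marching-squares contouring.
mask_to_region <- function(mask, grid) {
  cl <- grDevices::contourLines(grid$xs, grid$ys, mask + 0, levels = 0.5)
  if (length(cl) == 0) abort_geometry("Empty mask: no boundary to extract.")
  rings <- lapply(cl, function(c1) cbind(c1$x, c1$y))
  rings <- rings[vapply(rings, nrow, integer(1)) >= 3]
  region2d(rings, validate = FALSE)
}
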