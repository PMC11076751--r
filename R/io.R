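# File formats: ASCII STL and PLY meshes, NIfTI label volumes, JSON
# annotation files (schema v1), CSV metric and comparison tables.

# STL --------------------------------------------------------------------

#' Read and write triangle meshes
#'
#' `write_stl()`/`read_stl()` use ASCII STL; `write_ply()`/`read_ply()` use
#' ASCII PLY. Vertex coordinates round-trip at full double precision (STL
#' stores one vertex per face corner; `read_stl()` welds coincident
#' corners to rebuild connectivity).
#'
#' @param mesh A [trimesh()].
#' @param path File path.
#' @param name Solid name written to the STL header.
#' @return `read_*` return a [trimesh()]; `write_*` return `path` invisibly.
#' @export
write_stl <- function(mesh, path, name = "cranioplan") {
  stopifnot(inherits(mesh, "trimesh"))
  fc <- face_corners(mesh)
  nv <- cross3(fc$p2 - fc$p1, fc$p3 - fc$p1)
  len <- pmax(sqrt(rowSums(nv^2)), .Machine$double.eps)
  nv <- nv / len
  fmt <- function(m) sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
  lines <- c(
    paste("solid", name),
    as.vector(rbind(
      paste("facet normal", fmt(nv)),
      "  outer loop",
      paste("    vertex", fmt(fc$p1)),
      paste("    vertex", fmt(fc$p2)),
      paste("    vertex", fmt(fc$p3)),
      "  endloop",
      "endfacet")),
    paste("endsolid", name))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^\\s*solid", lines[1])) {
    abort_parse(sprintf("%s: not an ASCII STL (missing 'solid' header).", path))
  }
  if (!any(grepl("^\\s*endsolid", lines))) {
    abort_parse(sprintf("%s: truncated STL (missing 'endsolid').", path))
  }
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0) {
    abort_parse(sprintf("%s: vertex count %d is not a multiple of 3.", path, length(vl)))
  }
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    v <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(v)) abort_parse(sprintf("%s: malformed vertex line '%s'.", path,
                                      paste(p, collapse = " ")))
    v
  }))
  n <- nrow(nums) / 3
  soup <- trimesh(nums, cbind(3 * seq_len(n) - 2, 3 * seq_len(n) - 1, 3 * seq_len(n)))
  mesh_weld(soup, digits = 9)
}

# PLY --------------------------------------------------------------------

#' @rdname write_stl
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "trimesh"))
  header <- c("ply", "format ascii 1.0", "comment cranioplan mesh",
              sprintf("element vertex %d", nrow(mesh$vertices)),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nrow(mesh$faces)),
              "property list uchar int vertex_indices", "end_header")
  vtx <- sprintf("%.17g %.17g %.17g", mesh$vertices[, 1], mesh$vertices[, 2],
                 mesh$vertices[, 3])
  fac <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                 mesh$faces[, 3] - 1L)
  writeLines(c(header, vtx, fac), path)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || lines[1] != "ply") abort_parse(sprintf("%s: not a PLY file.", path))
  endh <- match("end_header", lines)
  if (is.na(endh)) abort_parse(sprintf("%s: missing end_header.", path))
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1 || is.na(nv) || is.na(nf)) {
    abort_parse(sprintf("%s: malformed PLY element declarations.", path))
  }
  if (length(lines) < endh + nv + nf) abort_parse(sprintf("%s: truncated PLY body.", path))
  vtx <- do.call(rbind, lapply(strsplit(lines[endh + seq_len(nv)], "\\s+"),
                               function(p) as.numeric(p[1:3])))
  fac <- do.call(rbind, lapply(strsplit(lines[endh + nv + seq_len(nf)], "\\s+"),
                               function(p) as.integer(p[2:4]) + 1L))
  if (anyNA(vtx) || anyNA(fac)) abort_parse(sprintf("%s: malformed PLY body.", path))
  trimesh(vtx, fac)
}

# NIfTI ------------------------------------------------------------------

#' Read and write label volumes as NIfTI
#'
#' The voxel pitch is stored in the NIfTI pixdim and the volume origin in
#' the qform/sform translation, so mm geometry round-trips.
#'
#' @param volume A [label_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_label_volume()` returns a [label_volume()].
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  img <- RNifti::asNifti(volume$labels + 0L)
  RNifti::pixdim(img) <- rep(volume$pitch, 3)
  xform <- rbind(cbind(diag(volume$pitch, 3), volume$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xform, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  pitch <- unname(xf[1, 1])
  origin <- unname(xf[1:3, 4])
  arr <- array(as.integer(round(as.array(img))), dim = dim(img))
  label_volume(arr, pitch = pitch, origin = origin)
}

# annotation JSON (schema v1) --------------------------------------------

ANNOTATION_SCHEMA_VERSION <- 1L

#' Read and write annotation files (JSON, schema v1)
#'
#' An open JSON document per participant drawing set: schema version, units
#' (must be "mm"), assessment id, the drawing elements with their layer
#' provenance and in-plane coordinates, and the matching 3D on-surface
#' coordinates when available, plus the assessment plane so both metric and
#' visual reconstruction are possible.
#'
#' @param annotation An `annotation_set`.
#' @param path File path.
#' @return `read_annotation()` returns an `annotation_set`.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  doc <- list(
    schema_version = ANNOTATION_SCHEMA_VERSION,
    units = "mm",
    assessment = annotation$assessment,
    participant_id = annotation$meta$participant_id,
    group = annotation$meta$group,
    seed = annotation$meta$seed,
    plane = list(origin = annotation$plane$origin, axis = annotation$plane$axis,
                 b1 = annotation$plane$b1, b2 = annotation$plane$b2),
    layers = annotation$layers,
    painted = list(rings = lapply(annotation$painted$rings, identity)),
    linear_incision = annotation$linear_incision$coords,
    u_incision = annotation$u_incision$coords,
    burr_holes = annotation$burr_holes,
    craniotomy = annotation$craniotomy$coords,
    surface = annotation$surface)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

as_mat <- function(x, ncol = 2) {
  m <- if (is.list(x)) do.call(rbind, lapply(x, unlist)) else as.matrix(x)
  matrix(as.numeric(m), ncol = ncol)
}

# jsonlite simplifies a list of k equal-size n x 2 matrices to a k x n x 2
# array; normalize back to a list of matrices
as_ring_list <- function(x, ncol = 2) {
  if (is.array(x) && length(dim(x)) == 3) {
    lapply(seq_len(dim(x)[1]), function(i) matrix(x[i, , ], ncol = ncol))
  } else if (is.matrix(x)) {
    list(as_mat(x, ncol))
  } else {
    lapply(x, as_mat, ncol = ncol)
  }
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort_parse(sprintf("%s: %s", path, conditionMessage(e))))
  req <- c("schema_version", "units", "assessment", "plane", "painted",
           "linear_incision", "u_incision", "burr_holes", "craniotomy")
  missing_f <- setdiff(req, names(doc))
  if (length(missing_f)) {
    abort_parse(sprintf("%s: missing field(s) %s.", path, paste(missing_f, collapse = ", ")))
  }
  if (!identical(as.integer(doc$schema_version), ANNOTATION_SCHEMA_VERSION)) {
    abort_validation(sprintf("%s: unsupported schema version %s.", path, doc$schema_version))
  }
  if (!identical(doc$units, "mm")) {
    abort_validation(sprintf("%s: units must be \"mm\", got \"%s\".", path, doc$units))
  }
  if (!doc$assessment %in% c("AA1", "AA2")) {
    abort_validation(sprintf("%s: assessment must be AA1 or AA2.", path))
  }
  plane <- assessment_plane(unlist(doc$plane$origin), unlist(doc$plane$axis))
  surface <- doc$surface
  if (!is.null(surface) && !is.null(surface$painted)) {
    surface$painted <- as_ring_list(surface$painted, ncol = 3)
    for (nm in c("linear_incision", "u_incision", "burr_holes", "craniotomy")) {
      if (!is.null(surface[[nm]])) surface[[nm]] <- as_mat(surface[[nm]], ncol = 3)
    }
  }
  structure(list(
    assessment = doc$assessment,
    painted = region2d(as_ring_list(doc$painted$rings)),
    linear_incision = polyline2d(as_mat(doc$linear_incision)),
    u_incision = polyline2d(as_mat(doc$u_incision)),
    burr_holes = as_mat(doc$burr_holes),
    craniotomy = quad2d(as_mat(doc$craniotomy)),
    layers = doc$layers,
    surface = surface,
    plane = plane,
    meta = list(seed = doc$seed %||% NA_integer_,
                participant_id = doc$participant_id %||% NA_character_,
                group = doc$group %||% NA_character_,
                params = NULL)
  ), class = "annotation_set")
}

# CSV --------------------------------------------------------------------

#' Read and write metric and comparison tables
#'
#' Thin wrappers over readr with unit-bearing column names
#' (`*_mm2`, `*_mm`). `read_metrics_csv()` validates the expected columns.
#'
#' @param metrics,comparison Tibbles from [assess_cohort()] /
#'   [compare_metrics()].
#' @param path File path.
#' @return Readers return tibbles.
#' @export
write_metrics_csv <- function(metrics, path) {
  readr::write_csv(metrics, path)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "assessment", metric_columns())
  missing_f <- setdiff(need, names(m))
  if (length(missing_f)) {
    abort_parse(sprintf("%s: missing column(s) %s.", path, paste(missing_f, collapse = ", ")))
  }
  m
}

#' @rdname write_metrics_csv
#' @export
write_comparison_csv <- function(comparison, path) {
  readr::write_csv(comparison, path)
  invisible(path)
}
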