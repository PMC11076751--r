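# The seven planning-accuracy metrics, computed in the assessment plane
# against the projected tumor silhouette:
#
#   painted area (mm^2), percent tumor coverage (%), excess coverage (mm^2),
#   linear-incision deviation from the tumor epicenter (mm),
#   U-incision score (0-4), craniotomy score (0-4),
#   craniotomy margin deviation sum (mm).
#
# Coverage uses the rasterized overlap engine, so painted = covered + excess
# holds exactly at the raster-cell level. Scores follow the band rule: an
# edge earns 1 point when its signed margin lies in the closed 5-15 mm band;
# the margin deviation sum measures each edge's distance from the 10 mm
# band center (the "acceptable standard" craniotomy border).

#' Tumor-projection coverage metrics
#'
#' Rasterizes the painted region and tumor silhouette on one grid and
#' reports painted area, covered (overlapping) area, percent tumor coverage
#' (covered / silhouette area) and excess coverage (painted area outside the
#' silhouette).
#'
#' @param painted The participant's painted region ([region2d()]).
#' @param silhouette The tumor silhouette ([region2d()]), positive area.
#' @param pitch Raster pitch (mm).
#' @return A `coverage_result` list: `painted_area`, `covered_area`,
#'   `percent_coverage`, `excess`.
#' @export
coverage_metrics <- function(painted, silhouette, pitch = NULL) {
  stopifnot(inherits(painted, "region2d"), inherits(silhouette, "region2d"))
  pitch <- resolve_pitch(pitch)
  bp <- region_bbox(painted); bs <- region_bbox(silhouette)
  bbox <- c(xmin = min(bp[["xmin"]], bs[["xmin"]]), xmax = max(bp[["xmax"]], bs[["xmax"]]),
            ymin = min(bp[["ymin"]], bs[["ymin"]]), ymax = max(bp[["ymax"]], bs[["ymax"]]))
  g <- raster_grid(bbox, pitch)
  mp <- region_mask(painted, g)
  ms <- region_mask(silhouette, g)
  n_sil <- sum(ms)
  if (n_sil == 0) abort_configuration("Silhouette has zero raster area.")
  n_p <- sum(mp)
  n_cov <- sum(mp & ms)
  structure(list(
    painted_area = n_p * pitch^2,
    covered_area = n_cov * pitch^2,
    percent_coverage = 100 * n_cov / n_sil,
    excess = (n_p - n_cov) * pitch^2
  ), class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage %.1f%% | painted %.0f mm^2 | excess %.0f mm^2\n",
              x$percent_coverage, x$painted_area, x$excess))
  invisible(x)
}

#' Linear incision deviation from the tumor epicenter
#'
#' Minimum Euclidean distance from the silhouette's area centroid (the
#' tumor epicenter) to the drawn incision polyline.
#'
#' @param incision A [polyline2d()].
#' @param silhouette The tumor silhouette ([region2d()]).
#' @param centre Optional precomputed epicenter.
#' @param pitch Raster pitch for the centroid.
#' @return Deviation in mm.
#' @export
incision_deviation <- function(incision, silhouette, centre = NULL, pitch = NULL) {
  stopifnot(inherits(incision, "polyline2d"), inherits(silhouette, "region2d"))
  if (is.null(centre)) centre <- centroid(silhouette, pitch = pitch)
  min_distance(centre, incision)
}

# margin of an arbitrary segment under the midpoint-ray convention
edge_margin_points <- function(a, b, silhouette, centre) {
  m <- (a + b) / 2
  v <- m - centre
  len <- sqrt(sum(v^2))
  if (len < 1e-9) return(-ray_boundary_distance(silhouette, centre, c(1, 0)))
  tb <- ray_boundary_distance(silhouette, centre, v / len)
  if (is.na(tb)) abort_undefined_margin("Centroid ray does not cross the silhouette boundary.")
  len - tb
}

edge_in_band <- function(margin, band) {
  !is.na(margin) && margin >= band[1] && margin <= band[2]
}

#' Per-edge and composite craniotomy scores
#'
#' Each craniotomy edge scores 1 point when its signed margin relative to
#' the tumor border lies within the closed acceptance band (5-15 mm by
#' default); the composite score is the sum over the four edges (0-4). An
#' edge whose margin is undefined (its centroid ray misses the silhouette)
#' scores 0 with a warning.
#'
#' @param quad The craniotomy [quad2d()].
#' @param silhouette The tumor silhouette ([region2d()]).
#' @param band Closed acceptance band for the margin (mm).
#' @param centre Optional precomputed epicenter.
#' @param convention Margin convention, see [edge_margin()].
#' @param pitch Raster pitch for the centroid.
#' @return `craniotomy_score()`: integer 0-4. `craniotomy_edge_scores()`:
#'   integer vector of four 0/1 edge scores.
#' @export
craniotomy_score <- function(quad, silhouette, band = c(5, 15), centre = NULL,
                             convention = "midpoint-ray", pitch = NULL) {
  sum(craniotomy_edge_scores(quad, silhouette, band = band, centre = centre,
                             convention = convention, pitch = pitch))
}

#' @rdname craniotomy_score
#' @export
craniotomy_edge_scores <- function(quad, silhouette, band = c(5, 15), centre = NULL,
                                   convention = "midpoint-ray", pitch = NULL) {
  stopifnot(inherits(quad, "quad2d"))
  if (is.null(centre)) centre <- centroid(silhouette, pitch = pitch)
  vapply(1:4, function(i) {
    m <- tryCatch(
      edge_margin(quad, i, silhouette, centre = centre, convention = convention),
      cranioplan_undefined_margin = function(e) {
        warn(sprintf("Edge %d margin undefined; scored 0.", i))
        NA_real_
      })
    as.integer(edge_in_band(m, band))
  }, integer(1))
}

#' U-shaped incision score
#'
#' The U (horseshoe) incision is an open polyline with four corner vertices
#' and three limbs. Each limb is scored like a craniotomy edge (1 point for
#' a margin in the band) and the base of the skin flap earns an extra point
#' when the imaginary line connecting the two open corners is within the
#' band, for a total of 0-4.
#'
#' @param u A [polyline2d()] with exactly 4 vertices (3 limbs).
#' @inheritParams craniotomy_score
#' @return Integer score 0-4.
#' @export
u_incision_score <- function(u, silhouette, band = c(5, 15), centre = NULL,
                             pitch = NULL) {
  stopifnot(inherits(u, "polyline2d"))
  cc <- u$coords
  if (nrow(cc) != 4) {
    abort_invalid_input("U-incision must have exactly 4 vertices (3 limbs).")
  }
  if (is.null(centre)) centre <- centroid(silhouette, pitch = pitch)
  segs <- list(cc[1:2, ], cc[2:3, ], cc[3:4, ], cc[c(4, 1), ])  # 3 limbs + imaginary base
  sum(vapply(segs, function(s) {
    m <- tryCatch(edge_margin_points(s[1, ], s[2, ], silhouette, centre),
                  cranioplan_undefined_margin = function(e) NA_real_)
    as.integer(edge_in_band(m, band))
  }, integer(1)))
}

#' Craniotomy margin deviation sum
#'
#' Sum over the four edges of the absolute deviation of the signed margin
#' from the acceptable standard craniotomy border (10 mm, the center of the
#' 5-15 mm acceptance band). A continuous, more robust alternative to the
#' 0-4 craniotomy score.
#'
#' @inheritParams craniotomy_score
#' @param standard_margin The acceptable standard margin (mm).
#' @return Sum of deviations in mm.
#' @export
margin_deviation_sum <- function(quad, silhouette, standard_margin = 10,
                                 centre = NULL, convention = "midpoint-ray",
                                 pitch = NULL) {
  stopifnot(inherits(quad, "quad2d"))
  if (is.null(centre)) centre <- centroid(silhouette, pitch = pitch)
  ms <- vapply(1:4, function(i) {
    edge_margin(quad, i, silhouette, centre = centre, convention = convention)
  }, numeric(1))
  sum(abs(ms - standard_margin))
}

#' Score one annotation set against the phantom
#'
#' Computes all seven metrics for a participant's drawing set. The
#' annotation must already live in the model's assessment plane (as produced
#' by [simulate_annotation()] or [read_annotation()] + [project_drawing()]).
#'
#' @param annotation An `annotation_set`.
#' @param model A `phantom_model`, used to derive the tumor silhouette when
#'   `silhouette` is not supplied.
#' @param silhouette Optional precomputed silhouette ([region2d()]).
#' @param pitch Raster pitch (mm).
#' @param band Craniotomy acceptance band (mm).
#' @param standard_margin Standard margin for the deviation sum (mm).
#' @param convention Margin convention, see [edge_margin()].
#' @return An `assessment_result` (also convertible with `as_tibble()`).
#' @export
assess <- function(annotation, model = NULL, silhouette = NULL, pitch = NULL,
                   band = c(5, 15), standard_margin = 10,
                   convention = "midpoint-ray") {
  stopifnot(inherits(annotation, "annotation_set"))
  if (is.null(silhouette)) {
    if (is.null(model)) abort_invalid_input("Supply `model` or `silhouette`.")
    silhouette <- tumor_silhouette(model, pitch = pitch)
  }
  centre <- centroid(silhouette, pitch = pitch)
  cov <- coverage_metrics(annotation$painted, silhouette, pitch = pitch)
  structure(list(
    assessment = annotation$assessment,
    painted_area = cov$painted_area,
    covered_area = cov$covered_area,
    percent_coverage = cov$percent_coverage,
    excess = cov$excess,
    incision_deviation = incision_deviation(annotation$linear_incision, silhouette,
                                            centre = centre),
    u_score = u_incision_score(annotation$u_incision, silhouette, band = band,
                               centre = centre),
    cran_score = craniotomy_score(annotation$craniotomy, silhouette, band = band,
                                  centre = centre, convention = convention),
    margin_deviation_sum = margin_deviation_sum(annotation$craniotomy, silhouette,
                                                standard_margin = standard_margin,
                                                centre = centre,
                                                convention = convention)
  ), class = "assessment_result")
}

#' @export
print.assessment_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<assessment_result %s>\n",
    "  coverage %.1f%% | painted %.0f mm^2 | excess %.0f mm^2\n",
    "  incision deviation %.1f mm | U score %d | craniotomy score %d | margin dev sum %.1f mm\n"),
    x$assessment, x$percent_coverage, x$painted_area, x$excess,
    x$incision_deviation, x$u_score, x$cran_score, x$margin_deviation_sum))
  invisible(x)
}

#' @method as_tibble assessment_result
#' @export
as_tibble.assessment_result <- function(x, ...) {
  tibble(
    assessment = x$assessment,
    painted_area_mm2 = x$painted_area,
    covered_area_mm2 = x$covered_area,
    percent_coverage = x$percent_coverage,
    excess_mm2 = x$excess,
    incision_deviation_mm = x$incision_deviation,
    u_score = as.integer(x$u_score),
    cran_score = as.integer(x$cran_score),
    margin_deviation_sum_mm = x$margin_deviation_sum
  )
}

#' Score every annotation in a simulated cohort
#'
#' @param cohort A tibble from [simulate_cohort()] with an `annotation`
#'   list-column.
#' @param model The `phantom_model` the cohort was simulated on.
#' @param pitch Raster pitch (mm).
#' @param ... Passed to [assess()].
#' @return A tibble with one row per participant and assessment, the seven
#'   metric columns (units in the names), and `participant_id`, `group`.
#' @export
assess_cohort <- function(cohort, model, pitch = NULL, ...) {
  stopifnot(is.data.frame(cohort), inherits(model, "phantom_model"))
  silhouette <- tumor_silhouette(model, pitch = pitch)
  rows <- purrr::pmap(
    list(cohort$participant_id, cohort$group, cohort$annotation),
    function(pid, grp, ann) {
      res <- assess(ann, silhouette = silhouette, pitch = pitch, ...)
      dplyr::bind_cols(tibble(participant_id = pid, group = grp), as_tibble(res))
    })
  dplyr::bind_rows(rows)
}

# canonical metric columns, in reporting order
metric_columns <- function() {
  c("painted_area_mm2", "percent_coverage", "excess_mm2",
    "incision_deviation_mm", "u_score", "cran_score", "margin_deviation_sum_mm")
}

metric_kind <- function(metric) {
  ifelse(metric %in% c("u_score", "cran_score"), "ordinal", "continuous")
}
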