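# Simulated participant annotations and cohorts.
#
# The generator is built to be metrically invertible: every error parameter
# it samples is realized exactly (up to solver tolerance) in the geometry it
# draws, so point-mass profiles reproduce their parameters in the downstream
# metrics, and the distribution-level fast path (simulate_cohort_metrics)
# is equivalent to simulating geometry and then measuring it.

# circle-circle lens area, radii r1 and r2, center distance d
lens_area_circles <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  d1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  d2 <- d - d1
  r1^2 * acos(pmin(pmax(d1 / r1, -1), 1)) + r2^2 * acos(pmin(pmax(d2 / r2, -1), 1)) -
    0.5 * sqrt(pmax((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2), 0))
}

# percent coverage of the unit-circle silhouette by a circle of radius R
# whose center sits at normalized distance d
coverage_from_shift_norm <- function(d, R) 100 * lens_area_circles(1, R, d) / pi

# invert: normalized center distance giving the target percent coverage
shift_norm_for_coverage <- function(coverage_pct, R) {
  cov_max <- 100 * min(1, R^2)
  if (coverage_pct >= cov_max) return(max(0, R - 1))
  if (coverage_pct <= 0) return(1 + R)
  uniroot(function(d) coverage_from_shift_norm(d, R) - coverage_pct,
          lower = max(0, R - 1), upper = 1 + R, tol = 1e-12)$root
}

# displacement in mm along direction theta whose affine-normalized length
# (x/a, y/b) equals d_norm
shift_mm_from_norm <- function(d_norm, theta, a, b) {
  d_norm / sqrt(cos(theta)^2 / a^2 + sin(theta)^2 / b^2)
}

shift_norm_from_mm <- function(t, theta, a, b) {
  t * sqrt(cos(theta)^2 / a^2 + sin(theta)^2 / b^2)
}

# boundary distance from the center of an ellipse along direction theta
ellipse_ray <- function(a, b, theta) {
  1 / sqrt(cos(theta)^2 / a^2 + sin(theta)^2 / b^2)
}

# Edge midpoints of any quadrilateral satisfy M1 + M3 = M2 + M4, so four
# independently drawn margins are generally not jointly realizable. The
# generator therefore places midpoints on the four axis rays at
# (boundary + raw margin) -- edges facing +y, -x, -y, +x -- and
# redistributes the parallelogram defect D symmetrically across the two
# opposite pairs. The achieved margins (approximately
# 0.75 raw_i + 0.25 raw_opposite) are what the scoring functions will
# measure; they are returned in closed form for an elliptical silhouette
# so the distribution-level fast path agrees with the geometry.
adjust_margin_draws <- function(raw, a, b) {
  U <- rbind(c(0, 1), c(-1, 0), c(0, -1), c(1, 0))
  tb <- c(b, a, b, a)
  M <- U * (tb + raw)
  D <- c((raw[2] - raw[4]) / 2, (raw[1] - raw[3]) / 2)
  M[c(1, 3), ] <- sweep(M[c(1, 3), , drop = FALSE], 2, D / 2, "-")
  M[c(2, 4), ] <- sweep(M[c(2, 4), , drop = FALSE], 2, D / 2, "+")
  len <- sqrt(rowSums(M^2))
  achieved <- len - ellipse_ray(a, b, atan2(M[, 2], M[, 1]))
  list(margins = achieved, midpoints = M)
}

# Realize raw margin draws as a quadrilateral on the actual (polygonal)
# silhouette: midpoints from the silhouette's own boundary distances, then
# corners reconstructed from the adjusted midpoints.
quad_from_margin_draws <- function(silhouette, raw, centre) {
  U <- rbind(c(0, 1), c(-1, 0), c(0, -1), c(1, 0))
  tb <- vapply(1:4, function(i) ray_boundary_distance(silhouette, centre, U[i, ]),
               numeric(1))
  if (anyNA(tb)) abort_geometry("Silhouette centroid rays do not reach the boundary.")
  M <- U * (tb + raw)
  D <- (M[1, ] + M[3, ] - M[2, ] - M[4, ]) / 2
  M[c(1, 3), ] <- sweep(M[c(1, 3), , drop = FALSE], 2, D / 2, "-")
  M[c(2, 4), ] <- sweep(M[c(2, 4), , drop = FALSE], 2, D / 2, "+")
  S <- M[1, ] + M[3, ]
  P1 <- M[1, ] + M[4, ] - S / 2
  P2 <- 2 * M[1, ] - P1
  P3 <- 2 * M[2, ] - P2
  P4 <- 2 * M[3, ] - P3
  quad2d(sweep(rbind(P1, P2, P3, P4), 2, centre, "+"))
}

# Construct a quadrilateral whose four signed edge margins (midpoint-ray
# convention) equal `margins`. The corners sit on four fixed diagonal rays
# from the silhouette centroid (45, 135, 225, 315 degrees), so the quad is
# star-shaped about the centroid and always simple; the four corner radii
# are found by a damped Newton solve of margins(R) = target. Edge i joins
# corner i to corner i+1, so the edges face roughly 90, 180, 270 and 0
# degrees.
quad_for_margins <- function(silhouette, margins, centre = NULL, pitch = NULL,
                             tol = 1e-9, max_iter = 60) {
  stopifnot(inherits(silhouette, "region2d"), length(margins) == 4)
  if (is.null(centre)) centre <- centroid(silhouette, pitch = pitch)
  psi <- pi / 4 + (0:3) * pi / 2
  u <- cbind(cos(psi), sin(psi))
  r_corner <- vapply(1:4, function(i) ray_boundary_distance(silhouette, centre, u[i, ]),
                     numeric(1))
  if (anyNA(r_corner)) abort_geometry("Silhouette centroid rays do not reach the boundary.")
  r_edge <- vapply(1:4, function(i) {
    d <- (u[i, ] + u[i %% 4 + 1, ]) / sqrt(2)
    ray_boundary_distance(silhouette, centre, d)
  }, numeric(1))
  if (any(margins <= -0.95 * r_edge)) {
    abort_invalid_input("Requested margins place an edge midpoint at or behind the silhouette centroid.")
  }
  margins_of <- function(x) {
    P <- matrix(x, 4, 2)
    vapply(1:4, function(i) {
      edge_margin_points(P[i, ], P[i %% 4 + 1, ], silhouette, centre)
    }, numeric(1))
  }
  # star-shaped initial quad with corners on the diagonal rays, then a
  # least-norm Gauss-Newton on all eight corner coordinates (the margin
  # constraints leave a 4-dim family of quads; we take the one closest to
  # the initial shape)
  solve_from <- function(R0) {
    x <- as.vector(sweep(u * R0, 2, centre, "+"))
    f <- margins_of(x) - margins
    mu <- 1e-10
    for (it in seq_len(max_iter)) {
      if (max(abs(f)) < tol) break
      J <- matrix(0, 4, 8)
      for (j in 1:8) {
        h <- 1e-6 * max(1, abs(x[j]))
        xh <- x; xh[j] <- xh[j] + h
        J[, j] <- (margins_of(xh) - margins - f) / h
      }
      improved <- FALSE
      for (trial in 1:8) {
        step <- tryCatch(
          crossprod(J, solve(J %*% t(J) + mu * diag(4), -f)),
          error = function(e) NULL)
        if (!is.null(step)) {
          xn <- x + step
          fn <- margins_of(xn) - margins
          if (all(is.finite(fn)) && max(abs(fn)) < max(abs(f))) {
            x <- xn; f <- fn
            mu <- max(mu / 10, 1e-12)
            improved <- TRUE
            break
          }
        }
        mu <- mu * 100  # steeper damping: shorter, more gradient-like step
      }
      if (!improved) break
    }
    list(x = x, resid = max(abs(f)))
  }
  R_base <- pmax((r_edge + margins) * sqrt(2) * 0.95, 0.02 * min(r_corner))
  jitters <- list(rep(1, 4), c(1.3, 0.8, 1.3, 0.8), c(0.8, 1.3, 0.8, 1.3),
                  rep(1.5, 4), c(1.1, 1.1, 0.7, 0.7))
  best <- NULL
  for (jt in jitters) {
    sol <- solve_from(R_base * jt)
    if (is.null(best) || sol$resid < best$resid) best <- sol
    if (best$resid < tol) break
  }
  if (best$resid > 1e-5) {
    abort_geometry(sprintf(
      "Craniotomy margin solve did not converge (max residual %.3g mm).", best$resid))
  }
  quad2d(matrix(best$x, 4, 2))
}

# per-participant error draws ------------------------------------------------

participant_substream <- function(seed, index) bitwXor(as.integer(seed), as.integer(index))

# Draw every error parameter for one participant (both assessments) from the
# participant's substream. The draw order is fixed so that identical seeds
# give identical parameters regardless of profile composition.
draw_participant_params <- function(pre, post, rho, a, b, substream) {
  set.seed(substream)
  z1 <- rnorm(11)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(11)
  angles <- matrix(runif(4, 0, 2 * pi), 2, 2)  # [assessment, {shift, incision}]
  u <- cbind(pnorm(z1), pnorm(z2))             # [family, assessment]
  one <- function(profile, ass) {
    uu <- u[, ass]
    f <- quantile_skill_dist(profile$paint_area_factor, uu[2])
    f <- max(f, 1e-6)
    R <- sqrt(f)
    theta <- angles[ass, 1]
    if (!is.null(profile$paint_coverage)) {
      cov <- quantile_skill_dist(profile$paint_coverage, uu[1])
      cov <- min(max(cov, 0), 100 * min(1, f))
      d_norm <- shift_norm_for_coverage(cov, R)
      t_mm <- shift_mm_from_norm(d_norm, theta, a, b)
    } else {
      t_mm <- max(quantile_skill_dist(profile$paint_shift, uu[1]), 0)
      d_norm <- shift_norm_from_mm(t_mm, theta, a, b)
      cov <- coverage_from_shift_norm(d_norm, R)
    }
    offset <- max(quantile_skill_dist(profile$incision_offset, uu[3]), 0)
    tb <- c(b, a, b, a)  # boundary distance along the four edge-facing directions
    m_cran <- pmax(quantile_skill_dist(profile$edge_margin, uu[4:7]), -0.8 * tb)
    m_u <- pmax(quantile_skill_dist(profile$edge_margin, uu[8:11]), -0.8 * tb)
    ac <- adjust_margin_draws(m_cran, a, b)$margins
    au <- adjust_margin_draws(m_u, a, b)$margins
    tibble(
      coverage_pct = cov, shift_mm = t_mm, shift_angle = theta,
      area_factor = f,
      incision_offset_mm = offset, incision_angle = angles[ass, 2],
      m1 = ac[1], m2 = ac[2], m3 = ac[3], m4 = ac[4],
      u1 = au[1], u2 = au[2], u3 = au[3], u4 = au[4],
      m1_raw = m_cran[1], m2_raw = m_cran[2], m3_raw = m_cran[3], m4_raw = m_cran[4],
      u1_raw = m_u[1], u2_raw = m_u[2], u3_raw = m_u[3], u4_raw = m_u[4])
  }
  dplyr::bind_rows(
    dplyr::mutate(one(pre, 1), assessment = "AA1", .before = 1),
    dplyr::mutate(one(post, 2), assessment = "AA2", .before = 1))
}

#' Draw cohort error parameters
#'
#' Samples every participant's error parameters for both assessments from
#' per-participant substreams (`xor(seed, index)`), with pre/post coupling
#' through the cohort's Gaussian copula. This is the stochastic core shared
#' by [simulate_cohort()] (which realizes the parameters as geometry) and
#' [simulate_cohort_metrics()] (which maps them to metrics directly).
#'
#' @param cohort A [cohort_spec()].
#' @param tumor_semiaxes In-plane tumor silhouette semi-axes (mm), used to
#'   convert coverage targets to displacements.
#' @return A tibble with one row per participant and assessment.
#' @export
draw_skill_params <- function(cohort, tumor_semiaxes = c(31.2, 27.72)) {
  stopifnot(inherits(cohort, "cohort_spec"))
  a <- tumor_semiaxes[1]; b <- tumor_semiaxes[2]
  n <- cohort$n_residents + cohort$n_interns
  if (n == 0) {
    return(tibble(participant_id = character(), group = character(), assessment = character()))
  }
  groups <- c(rep("resident", cohort$n_residents), rep("intern", cohort$n_interns))
  rows <- purrr::map(seq_len(n), function(i) {
    g <- groups[i]
    sub <- participant_substream(cohort$seed, i)
    p <- draw_participant_params(cohort$profiles[[g]]$pre, cohort$profiles[[g]]$post,
                                 cohort$test_retest_rho, a, b, sub)
    dplyr::mutate(p, participant_id = sprintf("P%02d", i), group = g,
                  substream = sub, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Simulate one participant annotation set
#'
#' Realizes sampled error parameters as drawings in the assessment plane:
#' the painted region is the true silhouette scaled by `sqrt(area_factor)`
#' about its centroid and translated by the sampled displacement; the linear
#' incision is an 80 mm segment whose minimum distance to the silhouette
#' centroid equals the sampled offset; the craniotomy is a quadrilateral
#' whose four signed edge margins equal the sampled margins; the U-incision
#' is built the same way from its own margin draws with the base edge left
#' open ("imaginary line"); burr holes sit at the craniotomy corners. All
#' elements are also lifted onto the scalp/bone layer surfaces by ray
#' casting along the projection axis.
#'
#' @param model A `phantom_model`.
#' @param profile A [skill_profile()].
#' @param assessment `"AA1"` (post-MRI) or `"AA2"` (post-3D-model).
#' @param seed Substream seed; required unless `params` is supplied (an
#'   unseeded simulation would not be reproducible).
#' @param params Optional single row of [draw_skill_params()] output.
#' @param silhouette,centre Optional precomputed silhouette and centroid.
#' @param pitch Raster pitch (mm).
#' @param lift Also attach 3D on-surface coordinates (slower).
#' @return An `annotation_set`.
#' @export
simulate_annotation <- function(model, profile = zero_error_profile(),
                                assessment = c("AA1", "AA2"), seed = NULL,
                                params = NULL, silhouette = NULL, centre = NULL,
                                pitch = NULL, lift = TRUE) {
  stopifnot(inherits(model, "phantom_model"))
  assessment <- arg_match(assessment)
  a <- model$spec$tumor_semiaxes[1]; b <- model$spec$tumor_semiaxes[2]
  if (is.null(params)) {
    if (is.null(seed)) {
      abort_reproducibility("Simulation requires `seed` (or explicit `params`).")
    }
    stopifnot(inherits(profile, "skill_profile"))
    both <- draw_participant_params(profile, profile, 0, a, b,
                                    participant_substream(seed, 0L))
    params <- both[both$assessment == if (assessment == "AA1") "AA1" else "AA2", ]
  }
  if (is.null(silhouette)) silhouette <- tumor_silhouette(model, pitch = pitch)
  if (is.null(centre)) centre <- centroid(silhouette, pitch = pitch)

  shift <- params$shift_mm * c(cos(params$shift_angle), sin(params$shift_angle))
  painted <- scale_region(silhouette, sqrt(params$area_factor), center = centre)
  painted <- rigid_transform(painted, translate = shift)

  phi <- params$incision_angle
  nvec <- c(cos(phi), sin(phi))
  tvec <- c(-sin(phi), cos(phi))
  foot <- centre + params$incision_offset_mm * nvec
  incision <- polyline2d(rbind(foot - 40 * tvec, foot + 40 * tvec))

  cran <- quad_from_margin_draws(silhouette,
                                 unlist(params[c("m1_raw", "m2_raw", "m3_raw", "m4_raw")]),
                                 centre = centre)
  uq <- quad_from_margin_draws(silhouette,
                               unlist(params[c("u1_raw", "u2_raw", "u3_raw", "u4_raw")]),
                               centre = centre)
  u_inc <- polyline2d(uq$coords)  # vertices 1-4; edge 4 (base) left open
  burr <- cran$coords

  surface <- NULL
  if (lift) {
    surface <- list(
      painted = lapply(painted$rings, lift_to_surface, plane = model$plane,
                       mesh = model$scalp_mesh),
      linear_incision = lift_to_surface(incision$coords, model$plane, model$scalp_mesh),
      u_incision = lift_to_surface(u_inc$coords, model$plane, model$scalp_mesh),
      burr_holes = lift_to_surface(burr, model$plane, model$skull_mesh),
      craniotomy = lift_to_surface(cran$coords, model$plane, model$skull_mesh))
  }

  structure(list(
    assessment = assessment,
    painted = painted,
    linear_incision = incision,
    u_incision = u_inc,
    burr_holes = burr,
    craniotomy = cran,
    layers = list(painted = "skin", linear_incision = "skin", u_incision = "skin",
                  burr_holes = "bone", craniotomy = "bone"),
    surface = surface,
    plane = model$plane,
    meta = list(seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                participant_id = if ("participant_id" %in% names(params)) params$participant_id else NA_character_,
                group = if ("group" %in% names(params)) params$group else NA_character_,
                params = as.list(params))
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set %s: painted region, linear + U incision, %d burr holes, craniotomy>\n",
              x$assessment, nrow(x$burr_holes)))
  invisible(x)
}

#' Simulate a full assessment cohort
#'
#' One pre (AA1) and one post (AA2) annotation set per participant,
#' deterministic under the cohort seed with independent per-participant
#' substreams.
#'
#' @param model A `phantom_model`.
#' @param cohort A [cohort_spec()].
#' @param pitch Raster pitch (mm).
#' @param lift Attach 3D on-surface coordinates to each annotation.
#' @return A tibble: `participant_id`, `group`, `assessment`, `substream`,
#'   and an `annotation` list-column.
#' @export
simulate_cohort <- function(model, cohort = cohort_spec(), pitch = NULL, lift = TRUE) {
  stopifnot(inherits(model, "phantom_model"), inherits(cohort, "cohort_spec"))
  params <- draw_skill_params(cohort, model$spec$tumor_semiaxes[1:2])
  if (nrow(params) == 0) {
    return(tibble(participant_id = character(), group = character(),
                  assessment = character(), substream = integer(),
                  annotation = list()))
  }
  silhouette <- tumor_silhouette(model, pitch = pitch)
  centre <- centroid(silhouette, pitch = pitch)
  anns <- purrr::map(seq_len(nrow(params)), function(i) {
    simulate_annotation(model, assessment = params$assessment[i],
                        params = params[i, ], silhouette = silhouette,
                        centre = centre, pitch = pitch, lift = lift)
  })
  tibble(participant_id = params$participant_id, group = params$group,
         assessment = params$assessment, substream = params$substream,
         annotation = anns)
}

#' Cohort metrics without geometry
#'
#' Maps sampled error parameters straight to the seven metrics using the
#' generator's closed-form relationships (the generator/metric inversion:
#' the geometry path realizes each parameter exactly, so this fast path is
#' distributionally equivalent to [simulate_cohort()] + [assess_cohort()]).
#' Intended for replication studies (power, type-I error) where simulating
#' and rasterizing thousands of cohorts would be wasteful.
#'
#' @param cohort A [cohort_spec()].
#' @param tumor_semiaxes In-plane silhouette semi-axes (mm).
#' @param band Craniotomy acceptance band (mm).
#' @param standard_margin Standard margin for the deviation sum (mm).
#' @return A metrics tibble matching [assess_cohort()]'s columns.
#' @export
simulate_cohort_metrics <- function(cohort = cohort_spec(),
                                    tumor_semiaxes = c(31.2, 27.72),
                                    band = c(5, 15), standard_margin = 10) {
  params <- draw_skill_params(cohort, tumor_semiaxes)
  A <- pi * tumor_semiaxes[1] * tumor_semiaxes[2]
  in_band <- function(m) as.integer(m >= band[1] & m <= band[2])
  dplyr::transmute(params,
    participant_id = .data$participant_id,
    group = .data$group,
    assessment = .data$assessment,
    painted_area_mm2 = .data$area_factor * A,
    covered_area_mm2 = .data$coverage_pct / 100 * A,
    percent_coverage = .data$coverage_pct,
    excess_mm2 = .data$painted_area_mm2 - .data$covered_area_mm2,
    incision_deviation_mm = .data$incision_offset_mm,
    u_score = in_band(.data$u1) + in_band(.data$u2) + in_band(.data$u3) + in_band(.data$u4),
    cran_score = in_band(.data$m1) + in_band(.data$m2) + in_band(.data$m3) + in_band(.data$m4),
    margin_deviation_sum_mm = abs(.data$m1 - standard_margin) + abs(.data$m2 - standard_margin) +
      abs(.data$m3 - standard_margin) + abs(.data$m4 - standard_margin))
}
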