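# Skill profiles: the error structure of simulated participant drawings.
#
# Each profile component is a small distribution object sampled through its
# quantile function, so pre/post draws for one participant can be coupled
# through a Gaussian copula (see simulate.R). Calibrated defaults reproduce
# the study-level metric distributions:
#
#   percent coverage  Beta on [0, 100] matched to 66.4 +/- 26.2 (pre) and
#                     77.2 +/- 17.4 (post);
#   painted area      Gamma on the area factor painted / 2717, matched to
#                     4036 +/- 1611 (pre) and 3760 +/- 1081 (post);
#   incision offset   Gamma matched to 16.3 +/- 9.6 mm (pre) and, for
#                     residents, 8.3 +/- 7.9 mm (post). A truncated normal
#                     would inflate the mean (truncating N(8.3, 7.9) at zero
#                     gives mean 10.4), hence Gamma.
#   edge margins      Normal(10, s) per edge with s chosen so the expected
#                     margin deviation sum 4 s sqrt(2/pi) matches 57.3 mm
#                     (pre) and 47.2 mm (post).

#' Skill-profile component distributions
#'
#' Small distribution specifications sampled via their quantile functions.
#' `dist_point()` is a point mass (used by the zero-error profile);
#' `dist_gamma_ms()` and `dist_beta_ms()` are moment-matched to a mean and
#' standard deviation.
#'
#' @param value Point-mass location.
#' @param mean,sd Target mean and standard deviation.
#' @param lo,hi Support bounds for the scaled Beta.
#' @return A `skill_dist` object.
#' @export
dist_point <- function(value) {
  if (!is_num(value, 1)) abort_invalid_input("Point mass needs a finite value.")
  new_skill_dist("point", value = value)
}

#' @rdname dist_point
#' @export
dist_normal <- function(mean, sd) {
  if (!is_num(mean, 1) || !is_num(sd, 1) || sd < 0) {
    abort_invalid_input("Normal needs finite mean and sd >= 0.")
  }
  new_skill_dist("normal", mean = mean, sd = sd)
}

#' @rdname dist_point
#' @export
dist_gamma_ms <- function(mean, sd) {
  if (!is_num(mean, 1) || !is_num(sd, 1) || mean <= 0 || sd <= 0) {
    abort_invalid_input("Gamma needs positive mean and sd.")
  }
  new_skill_dist("gamma", shape = (mean / sd)^2, rate = mean / sd^2)
}

#' @rdname dist_point
#' @export
dist_beta_ms <- function(mean, sd, lo = 0, hi = 1) {
  if (!is_num(mean, 1) || !is_num(sd, 1) || mean <= lo || mean >= hi || sd <= 0) {
    abort_invalid_input("Scaled Beta needs lo < mean < hi and sd > 0.")
  }
  m <- (mean - lo) / (hi - lo)
  s <- sd / (hi - lo)
  k <- m * (1 - m) / s^2 - 1
  if (k <= 0) abort_invalid_input("sd too large for a Beta with this mean.")
  new_skill_dist("beta", shape1 = m * k, shape2 = (1 - m) * k, lo = lo, hi = hi)
}

new_skill_dist <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "skill_dist")
}

#' @export
print.skill_dist <- function(x, ...) {
  cat(sprintf("<skill_dist %s: %s>\n", x$kind,
              paste(sprintf("%s=%g", setdiff(names(x), "kind"),
                            unlist(x[setdiff(names(x), "kind")])), collapse = ", ")))
  invisible(x)
}

#' Quantile of a skill distribution
#'
#' @param d A `skill_dist`.
#' @param p Probabilities.
#' @return Quantiles; a point mass ignores `p`.
#' @export
quantile_skill_dist <- function(d, p) {
  stopifnot(inherits(d, "skill_dist"))
  switch(d$kind,
    point = rep(d$value, length(p)),
    normal = qnorm(p, d$mean, d$sd),
    gamma = qgamma(p, shape = d$shape, rate = d$rate),
    beta = d$lo + (d$hi - d$lo) * qbeta(p, d$shape1, d$shape2),
    abort_invalid_input(sprintf("Unknown distribution kind '%s'.", d$kind)))
}

dist_mean <- function(d) {
  switch(d$kind,
    point = d$value,
    normal = d$mean,
    gamma = d$shape / d$rate,
    beta = d$lo + (d$hi - d$lo) * d$shape1 / (d$shape1 + d$shape2))
}

#' Skill profile
#'
#' Describes the error structure of one group's drawings at one assessment.
#' The painted region is a translated, uniformly scaled copy of the true
#' silhouette: its displacement is controlled either directly
#' (`paint_shift`, mm) or through a target percent-coverage distribution
#' (`paint_coverage`, on 0-100) that is converted to a displacement with the
#' circle-lens closed form; supply exactly one of the two. `edge_margin` is
#' sampled independently for each craniotomy edge (and again for the three
#' U-incision limbs and base).
#'
#' @param paint_shift `skill_dist` over displacement (mm), or `NULL`.
#' @param paint_coverage `skill_dist` over percent coverage, or `NULL`.
#' @param paint_area_factor `skill_dist` over painted / silhouette area (>= 0).
#' @param incision_offset `skill_dist` over the incision's distance from the
#'   epicenter (mm, >= 0).
#' @param edge_margin `skill_dist` over per-edge signed margins (mm).
#' @return A `skill_profile`.
#' @export
skill_profile <- function(paint_shift = NULL, paint_coverage = NULL,
                          paint_area_factor = dist_point(1),
                          incision_offset = dist_point(0),
                          edge_margin = dist_point(10)) {
  if (is.null(paint_shift) == is.null(paint_coverage)) {
    abort_invalid_input("Supply exactly one of `paint_shift` or `paint_coverage`.")
  }
  for (d in list(paint_shift, paint_coverage, paint_area_factor,
                 incision_offset, edge_margin)) {
    if (!is.null(d) && !inherits(d, "skill_dist")) {
      abort_invalid_input("Profile components must be skill_dist objects.")
    }
  }
  structure(list(paint_shift = paint_shift, paint_coverage = paint_coverage,
                 paint_area_factor = paint_area_factor,
                 incision_offset = incision_offset,
                 edge_margin = edge_margin),
            class = "skill_profile")
}

#' @export
print.skill_profile <- function(x, ...) {
  cat("<skill_profile>\n")
  for (nm in names(x)) if (!is.null(x[[nm]])) {
    cat(sprintf("  %-17s %s: %s\n", nm, x[[nm]]$kind,
                paste(sprintf("%g", unlist(x[[nm]][setdiff(names(x[[nm]]), "kind")])),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Zero-error profile
#'
#' Point masses at the ideal drawing: displacement 0, area factor 1,
#' incision through the epicenter, all margins exactly 10 mm. Every metric
#' of an annotation simulated from this profile is at its optimum.
#'
#' @return A `skill_profile`.
#' @export
zero_error_profile <- function() {
  skill_profile(paint_shift = dist_point(0),
                paint_area_factor = dist_point(1),
                incision_offset = dist_point(0),
                edge_margin = dist_point(10))
}

# margin sd giving an expected |N(10,s) - 10| deviation sum of `target` over 4 edges
margin_sd_for_sum <- function(target) target / (4 * sqrt(2 / pi))

#' Calibrated default profiles
#'
#' Pre (AA1, post-MRI planning) and post (AA2, post-3D-model planning)
#' profiles per group, calibrated to the study-level metric means and SDs
#' (see the package vignette for the calibration). Interns carry the AA1
#' incision distribution at both assessments: the incision improvement was
#' reported only in residents.
#'
#' @return Nested list: `$resident$pre`, `$resident$post`, `$intern$pre`,
#'   `$intern$post`.
#' @export
default_profiles <- function() {
  sil <- pi * 31.2 * 27.72  # reference silhouette area, mm^2
  # raw margin draws are pooled across opposite edges by the quad midpoint
  # constraint (achieved = 0.75 raw + 0.25 raw_opposite), shrinking the sd
  # by sqrt(10)/4; inflate the draw sd to compensate
  raw_sd <- function(target) margin_sd_for_sum(target) * 4 / sqrt(10)
  pre_common <- list(
    paint_coverage = dist_beta_ms(66.4, 26.2, 0, 100),
    paint_area_factor = dist_gamma_ms(4036 / sil, 1611 / sil),
    edge_margin = dist_normal(10, raw_sd(57.3)))
  post_common <- list(
    paint_coverage = dist_beta_ms(77.2, 17.4, 0, 100),
    paint_area_factor = dist_gamma_ms(3760 / sil, 1081 / sil),
    edge_margin = dist_normal(10, raw_sd(47.2)))
  inc_pre <- dist_gamma_ms(16.3, 9.6)
  inc_post_resident <- dist_gamma_ms(8.3, 7.9)
  list(
    resident = list(
      pre = do.call(skill_profile, c(pre_common, list(incision_offset = inc_pre))),
      post = do.call(skill_profile, c(post_common, list(incision_offset = inc_post_resident)))),
    intern = list(
      pre = do.call(skill_profile, c(pre_common, list(incision_offset = inc_pre))),
      post = do.call(skill_profile, c(post_common, list(incision_offset = inc_pre)))))
}

#' Cohort specification
#'
#' Mirrors the study cohort: 38 participants (14 neurosurgical residents,
#' 24 interns), each assessed twice (AA1 after MRI-only planning, AA2 after
#' 3D-model planning). Each participant's pre and post draws of one error
#' component are coupled through a Gaussian copula with correlation
#' `test_retest_rho`, representing the stability of individual skill across
#' the two assessments.
#'
#' @param n_residents,n_interns Group sizes (>= 0).
#' @param profiles Profiles as returned by [default_profiles()].
#' @param seed Master seed; participant i uses substream `xor(seed, i)`.
#' @param test_retest_rho Latent pre/post correlation in [0, 1).
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_residents = 14, n_interns = 24,
                        profiles = default_profiles(), seed = 1L,
                        test_retest_rho = 0.7) {
  if (!is_num(n_residents, 1) || !is_num(n_interns, 1) ||
      n_residents < 0 || n_interns < 0 ||
      n_residents != round(n_residents) || n_interns != round(n_interns)) {
    abort_invalid_spec("Group sizes must be non-negative integers.")
  }
  for (g in c("resident", "intern")) {
    for (a in c("pre", "post")) {
      if (!inherits(profiles[[g]][[a]], "skill_profile")) {
        abort_invalid_spec("`profiles` must contain skill_profile objects at $resident/$intern x $pre/$post.")
      }
    }
  }
  if (!is_num(seed, 1) || seed != round(seed)) abort_invalid_spec("`seed` must be an integer.")
  if (!is_num(test_retest_rho, 1) || test_retest_rho < 0 || test_retest_rho >= 1) {
    abort_invalid_spec("`test_retest_rho` must be in [0, 1).")
  }
  structure(list(n_residents = as.integer(n_residents),
                 n_interns = as.integer(n_interns),
                 profiles = profiles, seed = as.integer(seed),
                 test_retest_rho = test_retest_rho),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec: %d residents + %d interns, seed %d, rho %.2f>\n",
              x$n_residents, x$n_interns, x$seed, x$test_retest_rho))
  invisible(x)
}
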