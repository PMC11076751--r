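# Independent oracles used to freeze expected values. These deliberately
# re-derive results from first principles (closed forms, enumeration, dense
# sampling) rather than calling the code paths they check.

# area of the lens of two unit-area-normalized circles: silhouette radius 1,
# painted radius R, centers d apart; returns the covered fraction of the
# silhouette
oracle_lens_fraction <- function(d, R = 1) {
  if (d >= 1 + R) return(0)
  if (d <= abs(R - 1)) return(min(1, R^2))
  x1 <- (d^2 + 1 - R^2) / (2 * d)
  x2 <- d - x1
  lens <- acos(max(-1, min(1, x1))) + R^2 * acos(max(-1, min(1, x2 / R))) -
    0.5 * sqrt(max(0, (-d + 1 + R) * (d + 1 - R) * (d - 1 + R) * (d + 1 + R)))
  lens / pi
}

# brute-force minimum point-to-polyline distance by dense sampling
oracle_polyline_distance <- function(point, coords, n = 200000) {
  best <- Inf
  for (i in seq_len(nrow(coords) - 1)) {
    t <- seq(0, 1, length.out = n)
    px <- coords[i, 1] + t * (coords[i + 1, 1] - coords[i, 1])
    py <- coords[i, 2] + t * (coords[i + 1, 2] - coords[i, 2])
    best <- min(best, sqrt(min((px - point[1])^2 + (py - point[2])^2)))
  }
  best
}

# exact two-sided Wilcoxon signed-rank p-value by full enumeration of all
# 2^n sign assignments (zeros dropped, mean ranks for ties)
oracle_wilcoxon_exact <- function(x, y) {
  d <- (y - x)
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}
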