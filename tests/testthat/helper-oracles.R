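# Independent oracles used by the tests. These deliberately use different
# algorithms / formulas from the package implementation.

Rx <- function(deg) rotation_about_axis(c(1, 0, 0), deg)
Ry <- function(deg) rotation_about_axis(c(0, 1, 0), deg)
Rz <- function(deg) rotation_about_axis(c(0, 0, 1), deg)

# Quaternion (Horn) absolute-orientation solver: eigen decomposition of the
# 4x4 N matrix. Independent of the package's SVD route.
horn_register <- function(fixed, moving) {
  cf <- colMeans(fixed)
  cm <- colMeans(moving)
  Fc <- sweep(fixed, 2, cf)
  Mc <- sweep(moving, 2, cm)
  S <- t(Mc) %*% Fc
  N <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  list(R = R, t = as.double(cf - R %*% cm))
}

# Exhaustive O(n^2) nearest-neighbour search.
brute_nearest <- function(query, ref) {
  idx <- apply(query, 1, function(p) which.min(colSums((t(ref) - p)^2)))
  d <- sqrt(rowSums((query - ref[idx, , drop = FALSE])^2))
  list(index = as.integer(idx), distance = d)
}

# arccos-of-trace geodesic rotation angle (the textbook formula; fine away
# from 0 where it is well-conditioned).
trace_angle_deg <- function(Ra, Rb) {
  ct <- (sum(diag(crossprod(Ra, Rb))) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

min_pairwise_dist <- function(pts) min(dist(pts))

# Brute-force best max-min 4-subset over all vertices of a point set.
brute_best_maxmin <- function(pts, k = 4) {
  combs <- utils::combn(nrow(pts), k)
  best <- -Inf
  for (j in seq_len(ncol(combs))) {
    best <- max(best, min_pairwise_dist(pts[combs[, j], , drop = FALSE]))
  }
  best
}

random_points <- function(n, sd = 40) matrix(stats::rnorm(3 * n, sd = sd), n, 3)

random_rigid <- function(max_deg = 180, max_t = 50) {
  rigid_transform(rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, max_deg)),
                  stats::runif(3, -max_t, max_t))
}
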