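#' Rigid transform (rotation + translation)
#'
#' Constructs a rigid-body transform `p -> R p + t` mapping model ("moving")
#' coordinates into physical ("fixed") coordinates. The rotation matrix must
#' be orthonormal with determinant +1; lengths are in millimetres.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector (mm).
#' @param tol tolerance for the orthonormality and determinant checks.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' T1 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(5, -2, 1))
#' apply_transform(T1, c(1, 0, 0))
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0), tol = 1e-9) {
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)) || !is.numeric(R)) {
    stop("`R` must be a 3x3 numeric matrix", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 3L) {
    stop("`t` must be a length-3 numeric vector", call. = FALSE)
  }
  if (!all(is.finite(R)) || !all(is.finite(t))) {
    stop("rigid transform components must be finite", call. = FALSE)
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("`R` is not orthonormal (R'R != I)", call. = FALSE)
  }
  if (abs(det(R) - 1) > tol) {
    stop("`R` must be a proper rotation (det(R) = +1); reflections are not rigid motions",
         call. = FALSE)
  }
  structure(list(R = unname(R), t = as.double(unname(t))),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @return A `rigid_transform` with `R = I`, `t = 0`.
#' @export
identity_transform <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_between(x$R, diag(3))
  cat(sprintf("<rigid_transform>  rotation %.4g deg, translation (%s) mm\n",
              ang, paste(sprintf("%.4g", x$t), collapse = ", ")))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

assert_transform <- function(x, arg = "transform") {
  if (!is_rigid_transform(x)) {
    stop(sprintf("`%s` must be a rigid_transform", arg), call. = FALSE)
  }
  # revalidate: objects may have been built by hand
  rigid_transform(x$R, x$t)
}

#' Rotation matrix about an axis
#'
#' Axis-angle (Rodrigues) rotation matrix; a convenience for building poses
#' and test cases.
#'
#' @param axis length-3 axis (need not be unit length; must be non-zero).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  n <- vnorm(axis)
  if (n < 1e-12) stop("rotation axis must be non-zero", call. = FALSE)
  a <- axis / n
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Compose two rigid transforms
#'
#' `compose(outer, inner)` is the transform that applies `inner` first and
#' then `outer`: `p -> R_o (R_i p + t_i) + t_o`.
#'
#' @param outer,inner `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose <- function(outer, inner) {
  outer <- assert_transform(outer, "outer")
  inner <- assert_transform(inner, "inner")
  rigid_transform(outer$R %*% inner$R,
                  as.double(outer$R %*% inner$t) + outer$t,
                  tol = 1e-8)
}

#' Invert a rigid transform
#'
#' @param transform a `rigid_transform`.
#' @return The inverse transform `(R', -R' t)`.
#' @export
invert <- function(transform) {
  transform <- assert_transform(transform)
  Rt <- t(transform$R)
  rigid_transform(Rt, as.double(-Rt %*% transform$t), tol = 1e-8)
}

#' Apply a rigid transform to a point cloud
#'
#' Maps every point `p` to `R p + t`. The pairing convention throughout the
#' package is that transforms map model/"moving" points (the virtual bone,
#' p') onto real-object/"fixed" points (p).
#'
#' @param transform a `rigid_transform`.
#' @param points n x 3 numeric matrix of points (mm); a length-3 vector is
#'   treated as a single point. Rownames (labels) are preserved.
#' @return Transformed points, same dimensions, order and labels.
#' @export
apply_transform <- function(transform, points) {
  transform <- assert_transform(transform)
  pts <- as_points(points)
  out <- pts %*% t(transform$R)
  out <- sweep(out, 2L, -transform$t)
  colnames(out) <- c("x", "y", "z")
  rownames(out) <- rownames(pts)
  out
}

#' Geodesic angle between two rotations
#'
#' Angle (degrees, in \\[0, 180\\]) of the relative rotation `Ra' Rb`. The
#' angle is computed from the Frobenius norm of `Ra' Rb - I`
#' (`theta = 2 asin(||.||_F / (2 sqrt(2)))`), which is exact for rotations and
#' numerically accurate near 0 where the arccos-of-trace form loses precision.
#'
#' @param Ra,Rb 3x3 rotation matrices.
#' @return Angle in degrees.
#' @export
rotation_angle_between <- function(Ra, Rb) {
  Ta <- rigid_transform(Ra)   # validates rotation
  Tb <- rigid_transform(Rb)
  D <- crossprod(Ta$R, Tb$R) - diag(3)
  s <- sqrt(sum(D * D)) / (2 * sqrt(2))
  rad2deg(2 * asin(min(1, s)))
}

#' Per-pair registration residuals
#'
#' For index-paired clouds, the i-th residual is
#' `e_i = fixed_i - (R moving_i + t)`: the real-object point minus the
#' transformed model point.
#'
#' @param transform a `rigid_transform`.
#' @param fixed n x 3 real-object points p (mm).
#' @param moving n x 3 model points p' (mm), paired with `fixed` by row index.
#' @return n x 3 matrix of residual vectors (mm).
#' @export
residual_errors <- function(transform, fixed, moving) {
  fixed <- as_points(fixed, "fixed")
  moving <- as_points(moving, "moving")
  if (nrow(fixed) != nrow(moving)) {
    stop("`fixed` and `moving` must contain the same number of points",
         call. = FALSE)
  }
  fixed - apply_transform(transform, moving)
}

#' Least-squares overlay objective
#'
#' The registration cost `J = 1/2 * sum_i ||fixed_i - (R moving_i + t)||^2`
#' (mm^2) that the paired-point solver minimises.
#'
#' @inheritParams residual_errors
#' @return Non-negative scalar (mm^2); zero iff every residual is zero.
#' @export
registration_objective <- function(transform, fixed, moving) {
  e <- residual_errors(transform, fixed, moving)
  0.5 * sum(e * e)
}
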