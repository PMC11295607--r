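# Overlay solvers. `paired_point_register` is the closed-form SVD (Kabsch)
# minimiser of J = 1/2 sum ||p_i - (R p_i' + t)||^2 over index-paired points;
# `icp_register` alternates nearest-neighbour correspondence with that solver;
# `two_stage_register` chains a 3-7 landmark coarse match with ICP surface
# refinement. FRE/TRE are the standard registration-quality metrics.

new_registration_result <- function(transform, fre_mm, n_pairs,
                                    iterations = NA_integer_,
                                    cost_history = numeric(0),
                                    coarse = NULL) {
  structure(list(transform = transform, fre_mm = fre_mm,
                 n_pairs = as.integer(n_pairs), iterations = iterations,
                 cost_history = cost_history, coarse = coarse),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result>  FRE %.4g mm over %d pairs", x$fre_mm,
              x$n_pairs))
  if (!is.na(x$iterations)) cat(sprintf(", %d ICP iterations", x$iterations))
  cat("\n")
  print(x$transform)
  invisible(x)
}

#' Closed-form paired-point registration (SVD / Kabsch)
#'
#' Finds the rigid transform `(R, t)` minimising the overlay objective
#' `J = 1/2 sum_i ||fixed_i - (R moving_i + t)||^2` for index-paired clouds.
#' Solved via SVD of the cross-covariance with the standard sign correction of
#' the smallest singular vector, so the result is always a proper rotation
#' (`det(R) = +1`), including for planar point configurations.
#'
#' @param fixed n x 3 real-object points p (mm).
#' @param moving n x 3 model points p' (mm), paired with `fixed` by row.
#' @return A `registration_result` (transform, `fre_mm` = RMS residual,
#'   `n_pairs`).
#' @export
paired_point_register <- function(fixed, moving) {
  fixed <- as_points(fixed, "fixed")
  moving <- as_points(moving, "moving")
  n <- nrow(fixed)
  if (nrow(moving) != n) {
    stop("`fixed` and `moving` must contain the same number of points",
         call. = FALSE)
  }
  if (n < 3L) {
    stop_degenerate("paired-point registration needs at least 3 point pairs (got %d)", n)
  }
  cf <- colMeans(fixed)
  cm <- colMeans(moving)
  Fc <- sweep(fixed, 2L, cf)
  Mc <- sweep(moving, 2L, cm)
  H <- crossprod(Mc, Fc)          # sum_i m_i f_i'
  sv <- svd(H)
  scale <- max(sv$d[1L], sqrt(sum(Fc^2) * sum(Mc^2)) / n, .Machine$double.xmin)
  if (sv$d[2L] / scale < 1e-12) {
    stop_degenerate(
      "degenerate (collinear) point configuration: rotation about the point axis is unobservable")
  }
  s <- sign(det(sv$v %*% t(sv$u)))
  if (s == 0) s <- 1
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  t <- as.double(cf - R %*% cm)
  tr <- rigid_transform(R, t, tol = 1e-8)
  fre <- sqrt(mean(rowSums(residual_errors(tr, fixed, moving)^2)))
  new_registration_result(tr, fre, n)
}

#' Nearest-neighbour correspondences
#'
#' Pairs every point of `moving_now` with its Euclidean-nearest point in
#' `fixed` (vectorised brute-force search, chunked to bound memory).
#'
#' @param moving_now n x 3 query points (typically the moving cloud under the
#'   current transform).
#' @param fixed m x 3 reference points.
#' @return List with integer vector `index` (rows of `fixed`) and numeric
#'   vector `distance` (mm), both of length n.
#' @export
nearest_correspondences <- function(moving_now, fixed) {
  q <- as_points(moving_now, "moving_now")
  f <- as_points(fixed, "fixed")
  nq <- nrow(q)
  nf <- nrow(f)
  f2 <- rowSums(f * f)
  idx <- integer(nq)
  d2 <- numeric(nq)
  chunk <- max(1L, floor(4e6 / nf))
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1L)
    qs <- q[s:e, , drop = FALSE]
    D <- matrix(f2, e - s + 1L, nf, byrow = TRUE) - 2 * tcrossprod(qs, f) +
      rowSums(qs * qs)
    ii <- max.col(-D, ties.method = "first")
    idx[s:e] <- ii
    d2[s:e] <- D[cbind(seq_len(e - s + 1L), ii)]
  }
  list(index = idx, distance = sqrt(pmax(d2, 0)))
}

#' Iterative closest point surface matching
#'
#' Refines an initial transform by alternating nearest-neighbour
#' correspondence (moving points, under the current transform, against the
#' fixed surface cloud) with the closed-form paired-point solver. The recorded
#' `cost_history` is the RMS correspondence distance after each update and is
#' mathematically non-increasing.
#'
#' @param fixed_surface m x 3 fixed (real-object) surface points.
#' @param moving n x 3 moving (model) points.
#' @param init initial `rigid_transform` (e.g. a coarse landmark match).
#' @param max_iter maximum number of iterations.
#' @param tol_mm stop when the RMS cost changes by less than this (mm).
#' @param trim fraction (0 to <1) of the worst correspondences dropped each
#'   iteration; 0 (default) disables trimming.
#' @return A `registration_result` with `iterations` and `cost_history`;
#'   `fre_mm` is the final RMS correspondence distance.
#' @export
icp_register <- function(fixed_surface, moving, init = identity_transform(),
                         max_iter = 100L, tol_mm = 1e-4, trim = 0) {
  fixed_surface <- as_points(fixed_surface, "fixed_surface")
  moving <- as_points(moving, "moving")
  init <- assert_transform(init, "init")
  if (tol_mm <= 0) stop("`tol_mm` must be positive", call. = FALSE)
  if (trim < 0 || trim >= 1) stop("`trim` must be in [0, 1)", call. = FALSE)
  cur <- init
  history <- numeric(0)
  n <- nrow(moving)
  keep_n <- max(3L, ceiling((1 - trim) * n))
  for (it in seq_len(max_iter)) {
    corr <- nearest_correspondences(apply_transform(cur, moving), fixed_surface)
    use <- seq_len(n)
    if (keep_n < n) use <- order(corr$distance)[seq_len(keep_n)]
    step <- tryCatch(
      paired_point_register(fixed_surface[corr$index[use], , drop = FALSE],
                            moving[use, , drop = FALSE]),
      osteonav_degeneracy = function(e) {
        stop_degenerate("ICP iteration %d: %s", it, conditionMessage(e))
      })
    cur <- step$transform
    resid <- residual_errors(cur, fixed_surface[corr$index[use], , drop = FALSE],
                             moving[use, , drop = FALSE])
    cost <- sqrt(mean(rowSums(resid^2)))
    history <- c(history, cost)
    if (it > 1L && abs(history[it - 1L] - cost) < tol_mm) break
  }
  new_registration_result(cur, history[length(history)], length(use),
                          iterations = length(history), cost_history = history)
}

#' Two-stage registration: point matching then surface matching
#'
#' Stage 1 solves a coarse transform from 3-7 labelled landmark pairs
#' (paired-point SVD); stage 2 refines it by ICP against a dense surface
#' cloud. Mirrors the point-matching + surface-matching workflow of
#' navigation systems, where a handful of probed anatomical points seed a
#' surface-based refinement.
#'
#' @param fixed_landmarks,moving_landmarks labelled point matrices (rownames
#'   are labels); pairs are matched by shared label. 3 to 7 shared labels are
#'   required.
#' @param fixed_surface,moving_surface surface clouds for the ICP stage.
#' @param config list of options: `max_iter`, `tol_mm`, `trim` (passed to
#'   [icp_register()]) and `min_surface_points` (default 20).
#' @return A `registration_result` for the refined transform; the coarse
#'   stage-1 result is attached as `$coarse`.
#' @export
two_stage_register <- function(fixed_landmarks, moving_landmarks,
                               fixed_surface, moving_surface,
                               config = list()) {
  fixed_landmarks <- as_landmarks(fixed_landmarks, "fixed_landmarks")
  moving_landmarks <- as_landmarks(moving_landmarks, "moving_landmarks")
  lf <- rownames(fixed_landmarks)
  lm <- rownames(moving_landmarks)
  shared <- intersect(lf, lm)
  if (length(shared) < 3L) {
    only_f <- setdiff(lf, lm)
    only_m <- setdiff(lm, lf)
    stop_degenerate(
      "only %d landmark label(s) shared (%s); need 3-7. Unmatched fixed: %s; unmatched moving: %s",
      length(shared), paste(shared, collapse = ", ") %||% "none",
      if (length(only_f)) paste(only_f, collapse = ", ") else "none",
      if (length(only_m)) paste(only_m, collapse = ", ") else "none")
  }
  if (length(shared) > 7L) {
    stop_usage("point matching uses 3-7 landmark pairs; got %d shared labels",
               length(shared))
  }
  cfg <- utils::modifyList(list(max_iter = 100L, tol_mm = 1e-4, trim = 0,
                                min_surface_points = 20L), config)
  fixed_surface <- as_points(fixed_surface, "fixed_surface")
  moving_surface <- as_points(moving_surface, "moving_surface")
  if (nrow(fixed_surface) < cfg$min_surface_points ||
      nrow(moving_surface) < cfg$min_surface_points) {
    stop_usage("surface clouds must contain at least %d points for surface matching",
               cfg$min_surface_points)
  }
  coarse <- paired_point_register(fixed_landmarks[shared, , drop = FALSE],
                                  moving_landmarks[shared, , drop = FALSE])
  refined <- icp_register(fixed_surface, moving_surface,
                          init = coarse$transform, max_iter = cfg$max_iter,
                          tol_mm = cfg$tol_mm, trim = cfg$trim)
  refined$coarse <- coarse
  refined
}

#' Fiducial registration error
#'
#' RMS residual distance of the landmark pairs under a transform:
#' `sqrt(mean ||e_i||^2)`, equivalently `sqrt(2 J / n)` with `J` the overlay
#' objective evaluated on the landmarks.
#'
#' @param transform a `rigid_transform`.
#' @param fixed_landmarks,moving_landmarks index-paired landmark matrices.
#' @return FRE in mm.
#' @export
fiducial_registration_error <- function(transform, fixed_landmarks,
                                        moving_landmarks) {
  e <- residual_errors(transform, fixed_landmarks, moving_landmarks)
  sqrt(mean(rowSums(e * e)))
}

#' Target registration error (mean Euclidean deviation)
#'
#' Mean over target points of the distance between their positions under the
#' estimated and the true transform: the navigation-accuracy figure of merit
#' at clinically relevant locations (e.g. the planned osteotomy region).
#'
#' @param transform_est,transform_true estimated and ground-truth
#'   `rigid_transform`s.
#' @param targets n x 3 target points in the moving (model) frame.
#' @return TRE in mm.
#' @export
target_registration_error <- function(transform_est, transform_true, targets) {
  targets <- as_points(targets, "targets")
  d <- apply_transform(transform_est, targets) -
    apply_transform(transform_true, targets)
  mean(row_norms(d))
}
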