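# Synthetic tibia-like meshes, the scan noise model, and random poses: the
# simulated stand-ins for the physical sawbones, the handheld-scanner point
# clouds and the unknown bone pose in the trial harness.

#' Patient shape parameters for the synthetic tibia
#'
#' @param shaft_radius_mm radius of the tibial shaft (mm).
#' @param flare condylar flare factor: proximal max radius relative to the
#'   shaft radius (>= 1).
#' @param shaft_length_mm length of the modelled proximal tibia segment (mm).
#' @param bump_amplitude_mm peak amplitude of the smooth, seeded surface
#'   bumps that individualise each "patient" (mm); must stay below half the
#'   shaft radius to guarantee a non-self-intersecting surface.
#' @param seed integer seed controlling the bump pattern.
#' @return Named list of validated shape parameters.
#' @export
patient_shape_params <- function(shaft_radius_mm = 15, flare = 1.8,
                                 shaft_length_mm = 120,
                                 bump_amplitude_mm = 1.2, seed = 1L) {
  if (shaft_radius_mm <= 0 || shaft_length_mm <= 0 || bump_amplitude_mm < 0) {
    stop("shape dimensions must be positive", call. = FALSE)
  }
  if (flare < 1) stop("`flare` must be >= 1", call. = FALSE)
  if (bump_amplitude_mm >= 0.5 * shaft_radius_mm) {
    stop("`bump_amplitude_mm` must be below half the shaft radius (self-intersection bound)",
         call. = FALSE)
  }
  list(shaft_radius_mm = shaft_radius_mm, flare = flare,
       shaft_length_mm = shaft_length_mm,
       bump_amplitude_mm = bump_amplitude_mm, seed = as.integer(seed))
}

#' Generate a synthetic tibia-like mesh
#'
#' A closed triangulated surface: a tubular shaft along +Z whose radius
#' flares smoothly (smoothstep over the proximal 20%) up to `flare` times the
#' shaft radius near the proximal end — the condylar region — modulated by a
#' low-order harmonic bump field (a few circumferential/axial modes with
#' seeded coefficients, rescaled so its peak equals `bump_amplitude_mm`).
#' Deterministic for a fixed parameter set.
#'
#' @param params shape parameters from [patient_shape_params()].
#' @param n_axial,n_theta grid resolution along the shaft and around it.
#' @return A `triangle_mesh` (watertight: capped at both ends).
#' @export
make_synthetic_tibia <- function(params = patient_shape_params(),
                                 n_axial = 40L, n_theta = 32L) {
  r0 <- params$shaft_radius_mm
  L <- params$shaft_length_mm
  z <- seq(0, L, length.out = n_axial)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  # condylar flare: smoothstep ramp over the proximal 20% of the shaft
  u <- pmin(1, pmax(0, (z / L - 0.8) / 0.2))
  flare_f <- 1 + (params$flare - 1) * u^2 * (3 - 2 * u)
  # seeded low-order harmonic bumps, peak-normalised to the requested amplitude
  grid_th <- matrix(th, n_axial, n_theta, byrow = TRUE)
  grid_z <- matrix(z, n_axial, n_theta)
  bump <- matrix(0, n_axial, n_theta)
  coef <- withr::with_seed(params$seed, {
    ks <- expand.grid(k = 1:3, m = 1:2)
    cbind(ks, a = stats::rnorm(nrow(ks)), phi = stats::runif(nrow(ks), 0, 2 * pi),
          psi = stats::runif(nrow(ks), 0, 2 * pi))
  })
  for (j in seq_len(nrow(coef))) {
    bump <- bump + coef$a[j] *
      cos(coef$k[j] * grid_th + coef$phi[j]) *
      sin(coef$m[j] * pi * grid_z / L + coef$psi[j])
  }
  peak <- max(abs(bump))
  if (peak > 0 && params$bump_amplitude_mm > 0) {
    bump <- bump * (params$bump_amplitude_mm / peak)
  } else {
    bump[] <- 0
  }
  radius <- r0 * flare_f + bump            # n_axial x n_theta radial field
  if (min(radius) <= 0.1 * r0) {
    stop("shape parameters collapse the surface (radial field near zero): self-intersecting mesh rejected",
         call. = FALSE)
  }
  vx <- radius * cos(grid_th)
  vy <- radius * sin(grid_th)
  verts <- cbind(as.vector(t(vx)), as.vector(t(vy)),
                 rep(z, each = n_theta))
  vid <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- vector("list", n_axial - 1L)
  for (i in seq_len(n_axial - 1L)) {
    j <- seq_len(n_theta)
    faces[[i]] <- rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j)),
                        cbind(vid(i, j + 1L), vid(i + 1L, j + 1L), vid(i + 1L, j)))
  }
  faces <- do.call(rbind, faces)
  # end caps: distal (z = 0) and proximal (z = L) fans around centre vertices
  n_side <- nrow(verts)
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, L))
  c0 <- n_side + 1L
  c1 <- n_side + 2L
  j <- seq_len(n_theta)
  cap0 <- cbind(vid(1L, j + 1L), vid(1L, j), c0)
  cap1 <- cbind(vid(n_axial, j), vid(n_axial, j + 1L), c1)
  triangle_mesh(verts, rbind(faces, cap0, cap1))
}

#' Perturb a point cloud like a partial noisy scan
#'
#' Emulates a handheld-scanner acquisition: keeps `ceiling(overlap_fraction *
#' n)` points on one side of a seeded random half-space cut (partial view),
#' adds isotropic Gaussian noise, and replaces a fraction of the kept points
#' with uniform outliers drawn in the doubled bounding box of the input.
#' Deterministic per seed.
#'
#' @param cloud n x 3 point matrix (mm).
#' @param sigma_mm Gaussian noise standard deviation per axis (mm).
#' @param outlier_fraction fraction in \\[0, 1) of retained points replaced by
#'   outliers.
#' @param overlap_fraction fraction in (0, 1\\] of points retained.
#' @param seed integer RNG seed.
#' @return Point matrix with `ceiling(overlap_fraction * n)` rows.
#' @export
perturb_point_cloud <- function(cloud, sigma_mm = 0, outlier_fraction = 0,
                                overlap_fraction = 1, seed = 1L) {
  pts <- as_points(cloud)
  if (sigma_mm < 0) stop("`sigma_mm` must be non-negative", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("`outlier_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (overlap_fraction <= 0 || overlap_fraction > 1) {
    stop("`overlap_fraction` must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(pts)
  withr::with_seed(as.integer(seed), {
    keep_n <- as.integer(ceiling(overlap_fraction * n))
    if (keep_n < n) {
      dir <- stats::rnorm(3)
      dir <- dir / vnorm(dir)
      proj <- as.vector(pts %*% dir)
      keep <- sort(order(proj, decreasing = TRUE)[seq_len(keep_n)])
      pts <- pts[keep, , drop = FALSE]
    }
    if (sigma_mm > 0) {
      pts <- pts + matrix(stats::rnorm(3L * keep_n, sd = sigma_mm), keep_n, 3L)
    }
    n_out <- as.integer(floor(outlier_fraction * keep_n))
    if (n_out > 0L) {
      lo <- apply(pts, 2L, min)
      hi <- apply(pts, 2L, max)
      centre <- (lo + hi) / 2
      half <- pmax(hi - lo, 1e-6)          # doubled box = 2x original extent
      which_out <- sample.int(keep_n, n_out)
      pts[which_out, ] <- matrix(stats::runif(3L * n_out), n_out, 3L) *
        matrix(2 * half, n_out, 3L, byrow = TRUE) +
        matrix(centre - half, n_out, 3L, byrow = TRUE)
    }
    colnames(pts) <- c("x", "y", "z")
    pts
  })
}

#' Random plausible bone pose
#'
#' Draws a ground-truth pose: a rotation of uniform random axis with angle
#' uniform in \\[0, `max_rotation_deg`\\] and a translation uniform in the cube
#' \\[-`max_translation_mm`, +`max_translation_mm`\\]^3 — tabletop-scale bounds
#' for a sawbone sitting in front of a scanner.
#'
#' @param seed integer RNG seed.
#' @param max_rotation_deg rotation bound (degrees).
#' @param max_translation_mm translation bound per axis (mm).
#' @return A `rigid_transform`.
#' @export
random_pose <- function(seed = 1L, max_rotation_deg = 30,
                        max_translation_mm = 50) {
  withr::with_seed(as.integer(seed), {
    ax <- stats::rnorm(3)
    ang <- stats::runif(1, 0, max_rotation_deg)
    t <- stats::runif(3, -max_translation_mm, max_translation_mm)
    rigid_transform(rotation_about_axis(ax, ang), t)
  })
}

#' Modality error model
#'
#' Abstracts the error sources of one guidance modality in the simulated
#' sawbone trial. The defaults bundled in [default_modality_models()] are
#' illustrative: they are chosen to reproduce the qualitative accuracy
#' ordering of guidance modalities (metal jig most accurate, tracker-less AR
#' least), not calibrated to any measured error magnitudes.
#'
#' @param name `"metal"`, `"conventional"` or `"ar"`.
#' @param landmark_sigma_mm Gaussian noise on probed landmark / matched
#'   feature positions (mm).
#' @param surface_sigma_mm Gaussian noise on scanned surface points (mm).
#' @param outlier_fraction fraction of surface points replaced by outliers.
#' @param overlap_fraction fraction of the surface visible to the scan.
#' @param tilt_sigma_deg direct cutting-plane tilt noise (degrees): hand/jig
#'   execution error applied to the achieved plane regardless of navigation.
#' @return Named list describing the modality.
#' @export
modality_error_model <- function(name, landmark_sigma_mm = 0,
                                 surface_sigma_mm = 0, outlier_fraction = 0,
                                 overlap_fraction = 1, tilt_sigma_deg = 0) {
  if (!name %in% c("metal", "conventional", "ar")) {
    stop("`name` must be one of 'metal', 'conventional', 'ar'", call. = FALSE)
  }
  if (landmark_sigma_mm < 0 || surface_sigma_mm < 0 || tilt_sigma_deg < 0) {
    stop("noise magnitudes must be non-negative", call. = FALSE)
  }
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("`outlier_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (overlap_fraction <= 0 || overlap_fraction > 1) {
    stop("`overlap_fraction` must be in (0, 1]", call. = FALSE)
  }
  list(name = name, landmark_sigma_mm = landmark_sigma_mm,
       surface_sigma_mm = surface_sigma_mm,
       outlier_fraction = outlier_fraction,
       overlap_fraction = overlap_fraction, tilt_sigma_deg = tilt_sigma_deg)
}

#' Default (illustrative) modality error models
#'
#' Three arms: a metal jig (no registration; only seating/execution tilt), a
#' conventional navigation system (5-landmark point matching + surface
#' matching on a clean scan) and a tracker-less AR system (feature matching +
#' surface matching on a noisier, partial, outlier-contaminated view). See
#' [modality_error_model()] for the illustrative-not-calibrated caveat.
#'
#' @return Named list of three modality error models.
#' @export
default_modality_models <- function() {
  list(
    metal = modality_error_model("metal", tilt_sigma_deg = 0.5),
    conventional = modality_error_model("conventional",
                                        landmark_sigma_mm = 2,
                                        surface_sigma_mm = 1,
                                        outlier_fraction = 0.02,
                                        overlap_fraction = 0.9,
                                        tilt_sigma_deg = 0.5),
    ar = modality_error_model("ar",
                              landmark_sigma_mm = 4,
                              surface_sigma_mm = 2.5,
                              outlier_fraction = 0.15,
                              overlap_fraction = 0.65,
                              tilt_sigma_deg = 0.5)
  )
}
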