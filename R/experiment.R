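# The simulated sawbone trial: one trial = draw a ground-truth pose, build
# modality-specific noisy measurements, register, and score the achieved
# cutting planes against the plan. An experiment is a cohort of synthetic
# patients x replicates x modalities, mirroring a 10-patient / 3-arm /
# 30-sawbone bench trial.

#' Trial simulation settings
#'
#' @param n_surface number of surface points sampled on the model for
#'   surface matching (the scanned counterpart is its transformed, perturbed
#'   image).
#' @param n_features number of featured points used by the AR (tracker-less)
#'   arm's paired-feature coarse match.
#' @param n_landmarks number of probed landmarks in the conventional arm
#'   (five-point matching).
#' @param max_rotation_deg,max_translation_mm ground-truth pose bounds.
#' @param icp list of ICP options (`max_iter`, `tol_mm`, `trim`).
#' @return Named list of settings for [simulate_trial()].
#' @export
trial_config <- function(n_surface = 250L, n_features = 200L,
                         n_landmarks = 5L, max_rotation_deg = 30,
                         max_translation_mm = 50,
                         icp = list(max_iter = 50L, tol_mm = 1e-4, trim = 0)) {
  list(n_surface = as.integer(n_surface), n_features = as.integer(n_features),
       n_landmarks = as.integer(n_landmarks),
       max_rotation_deg = max_rotation_deg,
       max_translation_mm = max_translation_mm, icp = icp)
}

# Small random tilt applied to an achieved plane about its own origin:
# execution (hand/jig seating) error, independent of navigation.
tilt_plane <- function(plane, sigma_deg, seed) {
  if (sigma_deg <= 0) return(plane)
  withr::with_seed(as.integer(seed), {
    ax <- stats::rnorm(3)
    ang <- stats::rnorm(1, sd = sigma_deg)
    cutting_plane(plane$origin,
                  as.double(rotation_about_axis(ax, ang) %*% plane$normal),
                  plane$role)
  })
}

#' Simulate one sawbone trial
#'
#' Draws a ground-truth pose for the bone, synthesises the modality's
#' measurements, estimates the registration the modality would achieve, and
#' scores the result:
#' * `metal` — the guide is physically seated on the bone, so no registration
#'   is involved (`T_est = T_true`); only direct plane-tilt noise applies.
#' * `conventional` — five-point landmark matching plus ICP surface matching
#'   (the two-stage procedure) on a scanned, perturbed surface cloud.
#' * `ar` — tracker-less paired-feature registration (featured points matched
#'   with noise) refined by ICP on a noisier, partial surface view.
#'
#' The achieved plane is the planned plane mapped through
#' `invert(T_est) o T_true` — the displacement a cut executed exactly on the
#' displayed virtual plane would inherit from registration error — plus the
#' modality's direct tilt noise. TRE is evaluated at the two plane origins.
#'
#' @param mesh the patient's `triangle_mesh` (model frame, shaft along +Z).
#' @param planes planned plane pair from [make_cutting_planes()].
#' @param model a [modality_error_model()].
#' @param seed integer seed; fixes the pose, all noise draws and the result.
#' @param config settings from [trial_config()].
#' @return A `trial_result`: modality, transforms, `tre_mm`, `fre_mm` and a
#'   4-row `angles` data frame (`role` x `projection`).
#' @export
simulate_trial <- function(mesh, planes, model, seed = 1L,
                           config = trial_config()) {
  mesh <- assert_mesh(mesh)
  cfg <- utils::modifyList(trial_config(), config)
  seeds <- derive_seeds(seed, 8L)
  t_true <- random_pose(seeds[1L], cfg$max_rotation_deg, cfg$max_translation_mm)

  est <- switch(
    model$name,
    metal = list(transform = t_true, fre_mm = 0, iterations = NA_integer_),
    conventional = {
      lm_mov <- extract_feature_points(mesh, cfg$n_landmarks, seed = seeds[2L])
      rownames(lm_mov) <- paste0("L", seq_len(nrow(lm_mov)))
      lm_fix <- apply_transform(t_true, lm_mov)
      if (model$landmark_sigma_mm > 0) {
        lm_fix <- lm_fix + withr::with_seed(seeds[3L], {
          matrix(stats::rnorm(3L * nrow(lm_fix), sd = model$landmark_sigma_mm),
                 nrow(lm_fix), 3L)
        })
      }
      surf_mov <- sample_surface_points(mesh, cfg$n_surface, seed = seeds[4L])
      surf_fix <- perturb_point_cloud(apply_transform(t_true, surf_mov),
                                      sigma_mm = model$surface_sigma_mm,
                                      outlier_fraction = model$outlier_fraction,
                                      overlap_fraction = model$overlap_fraction,
                                      seed = seeds[5L])
      two_stage_register(lm_fix, lm_mov, surf_fix, surf_mov, config = cfg$icp)
    },
    ar = {
      feat_mov <- extract_feature_points(mesh, cfg$n_features, seed = seeds[2L])
      feat_fix <- apply_transform(t_true, feat_mov)
      if (model$landmark_sigma_mm > 0) {
        feat_fix <- feat_fix + withr::with_seed(seeds[3L], {
          matrix(stats::rnorm(3L * nrow(feat_fix), sd = model$landmark_sigma_mm),
                 nrow(feat_fix), 3L)
        })
      }
      coarse <- paired_point_register(feat_fix, feat_mov)
      surf_mov <- sample_surface_points(mesh, cfg$n_surface, seed = seeds[4L])
      surf_fix <- perturb_point_cloud(apply_transform(t_true, surf_mov),
                                      sigma_mm = model$surface_sigma_mm,
                                      outlier_fraction = model$outlier_fraction,
                                      overlap_fraction = model$overlap_fraction,
                                      seed = seeds[5L])
      out <- icp_register(surf_fix, surf_mov, init = coarse$transform,
                          max_iter = cfg$icp$max_iter, tol_mm = cfg$icp$tol_mm,
                          trim = cfg$icp$trim)
      out$coarse <- coarse
      out
    },
    stop("unknown modality: ", model$name)
  )
  t_est <- if (is_rigid_transform(est$transform)) est$transform else t_true

  targets <- rbind(planes$main$origin, planes$side$origin)
  tre <- target_registration_error(t_est, t_true, targets)

  nav_err <- compose(invert(t_est), t_true)
  achieved_main <- tilt_plane(transform_plane(nav_err, planes$main),
                              model$tilt_sigma_deg, seeds[6L])
  achieved_side <- tilt_plane(transform_plane(nav_err, planes$side),
                              model$tilt_sigma_deg, seeds[7L])
  angles <- withCallingHandlers(
    expand_angles(planes, achieved_main, achieved_side),
    osteonav_degeneracy = function(e) {
      stop_degenerate("trial seed %d (%s): %s", seed, model$name,
                      conditionMessage(e))
    })
  structure(list(modality = model$name, seed = as.integer(seed),
                 transform_true = t_true, transform_est = t_est,
                 tre_mm = tre, fre_mm = est$fre_mm %||% 0,
                 iterations = est$iterations %||% NA_integer_,
                 angles = angles),
            class = "trial_result")
}

expand_angles <- function(planes, achieved_main, achieved_side) {
  grid <- expand.grid(role = c("main", "side"), projection = c("XZ", "YZ"),
                      stringsAsFactors = FALSE)
  grid$angle_deg <- mapply(function(role, proj) {
    planned <- if (role == "main") planes$main else planes$side
    achieved <- if (role == "main") achieved_main else achieved_side
    projected_angle_difference(planned, achieved, proj)
  }, grid$role, grid$projection)
  grid
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result %s>  TRE %.4g mm, FRE %.4g mm\n", x$modality,
              x$tre_mm, x$fre_mm))
  print(x$angles, row.names = FALSE)
  invisible(x)
}

#' Experiment configuration
#'
#' @param n_patients number of synthetic patients (distinct bone shapes).
#' @param replicates sawbone replicates per patient and modality.
#' @param models named list of [modality_error_model()]s; default
#'   [default_modality_models()].
#' @param shape base [patient_shape_params()]; each patient gets its own bump
#'   seed derived from the experiment seed.
#' @param plane [plane_config()] for the planned cuts.
#' @param trial [trial_config()] simulation settings.
#' @return Named list describing the experiment.
#' @export
experiment_config <- function(n_patients = 10L, replicates = 1L,
                              models = default_modality_models(),
                              shape = patient_shape_params(),
                              plane = plane_config(),
                              trial = trial_config()) {
  list(n_patients = as.integer(n_patients), replicates = as.integer(replicates),
       models = models, shape = shape, plane = plane, trial = trial)
}

#' Run a simulated multi-modality sawbone experiment
#'
#' Generates `n_patients` synthetic tibiae, plans cutting planes on each, and
#' simulates `replicates` trials per patient for every modality (default: 10
#' patients x 3 modalities x 1 replicate = 30 sawbones). All randomness
#' derives from `seed`.
#'
#' @param config an [experiment_config()].
#' @param seed integer master seed.
#' @return An `experiment_result`: `$results` (long data frame, one row per
#'   trial x plane role x projection), `$summary` (from
#'   [summarize_angle_differences()]) and `$provenance` (seed, config hash,
#'   package version).
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L) {
  cfg <- utils::modifyList(experiment_config(), config)
  if (cfg$n_patients * cfg$replicates < 1L) {
    stop("need at least one patient x replicate", call. = FALSE)
  }
  pat_seeds <- derive_seeds(seed, cfg$n_patients)
  rows <- list()
  trial_no <- 0L
  for (p in seq_len(cfg$n_patients)) {
    shape <- cfg$shape
    shape$seed <- pat_seeds[p]
    mesh <- make_synthetic_tibia(shape)
    planes <- make_cutting_planes(mesh, cfg$plane)
    trial_seeds <- derive_seeds(pat_seeds[p],
                                cfg$replicates * length(cfg$models))
    k <- 0L
    for (r in seq_len(cfg$replicates)) {
      for (m in names(cfg$models)) {
        k <- k + 1L
        trial_no <- trial_no + 1L
        tr <- simulate_trial(mesh, planes, cfg$models[[m]],
                             seed = trial_seeds[k], config = cfg$trial)
        a <- tr$angles
        rows[[trial_no]] <- data.frame(
          trial = trial_no, patient = p, replicate = r,
          modality = tr$modality, role = a$role, projection = a$projection,
          angle_deg = a$angle_deg, tre_mm = tr$tre_mm, fre_mm = tr$fre_mm)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  prov <- list(seed = as.integer(seed),
               config_hash = fnv1a_hash(paste(deparse(cfg), collapse = "")),
               package_version = as.character(utils::packageVersion("osteonav")),
               n_trials = trial_no)
  structure(list(results = results, summary = summarize_angle_differences(results),
                 provenance = prov),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result>  %d trials, seed %d, config %s\n",
              x$provenance$n_trials, x$provenance$seed,
              x$provenance$config_hash))
  pooled <- x$summary[x$summary$role == "all", ]
  print(pooled[, c("modality", "n", "mean_deg", "median_deg")],
        row.names = FALSE)
  invisible(x)
}

#' Pooled mean angle difference per modality
#'
#' @param experiment an `experiment_result` (or its `$results` data frame).
#' @return Named numeric vector of pooled mean angle differences (degrees).
#' @export
pooled_mean_angles <- function(experiment) {
  df <- if (inherits(experiment, "experiment_result")) experiment$results else experiment
  tapply(df$angle_deg, df$modality, mean)
}

#' Box-and-whisker plot of angle differences
#'
#' One panel per (plane role, projection), boxes per modality — the standard
#' visual summary of a guidance-accuracy bench trial.
#'
#' @param experiment an `experiment_result` (or its `$results` data frame).
#' @param path optional output file (`.png` or `.svg`); plots to the active
#'   device when `NULL`.
#' @return Invisibly, the path (or `NULL`).
#' @export
plot_angle_differences <- function(experiment, path = NULL) {
  df <- if (inherits(experiment, "experiment_result")) experiment$results else experiment
  if (!is.null(path)) {
    if (grepl("\\.svg$", path)) grDevices::svg(path, width = 8, height = 7)
    else grDevices::png(path, width = 900, height = 800)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, 2), mar = c(3.5, 4, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (role in c("main", "side")) {
    for (proj in c("XZ", "YZ")) {
      sub <- df[df$role == role & df$projection == proj, ]
      graphics::boxplot(angle_deg ~ modality, data = sub,
                        main = sprintf("%s cut, %s projection", role, proj),
                        ylab = "angle difference (deg)", xlab = "")
    }
  }
  invisible(path)
}
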