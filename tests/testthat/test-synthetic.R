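# Synthetic tibia generator, scan perturbation model and the trial harness.

test_that("degenerate shape limit is a straight cylinder", {
  params <- patient_shape_params(flare = 1, bump_amplitude_mm = 0)
  mesh <- make_synthetic_tibia(params)
  side <- mesh$vertices[seq_len(nrow(mesh$vertices) - 2L), ]  # drop cap centres
  radial <- sqrt(side[, 1]^2 + side[, 2]^2)
  expect_lt(max(abs(radial - params$shaft_radius_mm)), 1e-6)
})

test_that("generator is deterministic and the condylar flare is measurable", {
  p <- patient_shape_params(seed = 42)
  m1 <- make_synthetic_tibia(p)
  m2 <- make_synthetic_tibia(p)
  expect_identical(m1, m2)
  m3 <- make_synthetic_tibia(patient_shape_params(seed = 43))
  expect_false(isTRUE(all.equal(m1$vertices, m3$vertices)))

  pf <- patient_shape_params(flare = 1.8, seed = 7)
  mesh <- make_synthetic_tibia(pf)
  v <- mesh$vertices[seq_len(nrow(mesh$vertices) - 2L), ]
  zr <- range(v[, 3])
  proximal <- v[v[, 3] > zr[1] + 0.8 * diff(zr), ]
  max_r <- max(sqrt(proximal[, 1]^2 + proximal[, 2]^2))
  expect_gt(max_r, 0.95 * pf$flare * pf$shaft_radius_mm)
  expect_lt(max_r, 1.05 * pf$flare * pf$shaft_radius_mm)
})

test_that("invalid shape parameters are rejected", {
  expect_error(patient_shape_params(flare = 0.8), "flare")
  expect_error(patient_shape_params(shaft_radius_mm = -1), "positive")
  expect_error(patient_shape_params(bump_amplitude_mm = 10, shaft_radius_mm = 15),
               "self-intersection")
})

test_that("perturbation model: identity limit, noise RMS and overlap count", {
  withr::with_seed(2, {
    cloud <- random_points(1000, sd = 30)
  })
  expect_equal(perturb_point_cloud(cloud, 0, 0, 1, seed = 5), cloud,
               ignore_attr = TRUE)

  big <- make_synthetic_tibia()
  pts <- sample_surface_points(big, 1e4, seed = 3)
  noisy <- perturb_point_cloud(pts, sigma_mm = 1, seed = 9)
  rms <- sqrt(mean(rowSums((noisy - pts)^2)))
  # chi_3 distribution: RMS displacement = sigma * sqrt(3), within 3%
  expect_gt(rms, sqrt(3) * 0.97)
  expect_lt(rms, sqrt(3) * 1.03)

  half <- perturb_point_cloud(cloud, 0, 0, 0.5, seed = 1)
  expect_equal(nrow(half), 500)
  odd <- perturb_point_cloud(cloud[1:99, ], 0, 0, 0.5, seed = 1)
  expect_equal(nrow(odd), 50)   # ceiling(99/2)
  # retained points are an untouched subset (half-space cut)
  expect_true(all(half %in% cloud))

  out <- perturb_point_cloud(cloud, 0, 0.1, 1, seed = 4)
  moved <- rowSums(abs(out - cloud)) > 0
  expect_equal(sum(moved), 100)   # floor(0.1 * 1000) replaced outliers
})

test_that("zero-noise trials are exact for every modality", {
  mesh <- make_synthetic_tibia(n_axial = 24, n_theta = 20)
  planes <- make_cutting_planes(mesh)
  for (name in c("metal", "conventional", "ar")) {
    tr <- simulate_trial(mesh, planes, modality_error_model(name), seed = 11)
    expect_equal(tr$angles$angle_deg, rep(0, 4), tolerance = 1e-9)
    expect_equal(tr$tre_mm, 0, tolerance = 1e-9)
  }
})

test_that("trials are bit-reproducible for a fixed seed", {
  mesh <- make_synthetic_tibia(n_axial = 20, n_theta = 16)
  planes <- make_cutting_planes(mesh)
  model <- default_modality_models()$conventional
  t1 <- simulate_trial(mesh, planes, model, seed = 99)
  t2 <- simulate_trial(mesh, planes, model, seed = 99)
  expect_identical(t1, t2)
  t3 <- simulate_trial(mesh, planes, model, seed = 100)
  expect_false(identical(t3$angles, t1$angles))
})

test_that("accuracy degrades monotonically with its causal noise source", {
  mesh <- make_synthetic_tibia(n_axial = 24, n_theta = 20)
  planes <- make_cutting_planes(mesh)
  # final (surface-matched) accuracy is driven by surface noise
  mean_angle <- function(surf_sig, n = 60) {
    m <- modality_error_model("conventional", landmark_sigma_mm = 2,
                              surface_sigma_mm = surf_sig)
    mean(vapply(seq_len(n), function(i) {
      mean(simulate_trial(mesh, planes, m, seed = 1000 + i)$angles$angle_deg)
    }, 1))
  }
  grid <- vapply(c(0.2, 1, 2.5), mean_angle, 1)
  expect_true(all(diff(grid) > 0))

  # coarse (point-matching) accuracy is driven by landmark noise
  lm <- extract_feature_points(mesh, 5, seed = 3)
  rownames(lm) <- paste0("L", 1:5)
  coarse_tre <- function(sig, n = 100) {
    mean(vapply(seq_len(n), function(i) {
      Tt <- random_pose(i)
      fx <- apply_transform(Tt, lm) +
        withr::with_seed(i * 7 + round(sig * 100), matrix(rnorm(15, sd = sig), 5, 3))
      est <- paired_point_register(fx, lm)$transform
      target_registration_error(est, Tt, rbind(planes$main$origin,
                                               planes$side$origin))
    }, 1))
  }
  tres <- vapply(c(0.5, 2, 4), coarse_tre, 1)
  expect_true(all(diff(tres) > 0))
})

test_that("experiment layout mirrors the cohort design with provenance", {
  zero <- list(metal = modality_error_model("metal"),
               conventional = modality_error_model("conventional"),
               ar = modality_error_model("ar"))
  cfg <- experiment_config(n_patients = 1, replicates = 1, models = zero)
  exp1 <- run_experiment(cfg, seed = 5)
  expect_equal(nrow(exp1$results), 3 * 4)     # 3 modalities x 4 angle rows
  expect_equal(max(abs(exp1$results$angle_deg)), 0, tolerance = 1e-9)
  expect_equal(max(exp1$results$tre_mm), 0, tolerance = 1e-9)

  cfg10 <- experiment_config(n_patients = 10, replicates = 1, models = zero)
  exp10 <- run_experiment(cfg10, seed = 5)
  expect_equal(length(unique(exp10$results$trial)), 30)  # 30 sawbones
  expect_named(exp10$provenance,
               c("seed", "config_hash", "package_version", "n_trials"))
  # determinism end to end
  exp10b <- run_experiment(cfg10, seed = 5)
  expect_identical(exp10$results, exp10b$results)
})
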