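# Paired-point solver, ICP, two-stage registration and the FRE/TRE metrics.

test_that("paired-point registration solves the analytic cases", {
  withr::with_seed(1, {
    mv <- random_points(6)
    r <- paired_point_register(mv, mv)
    expect_transform_close(r$transform, identity_transform(), 1e-9, 1e-9)
    expect_equal(r$fre_mm, 0, tolerance = 1e-12)

    shifted <- sweep(mv, 2, c(-1, -2, -3))
    r2 <- paired_point_register(shifted, mv)
    expect_transform_close(r2$transform, rigid_transform(t = c(1, 2, 3)),
                           1e-10, 1e-10)

    Tt <- rigid_transform(Rz(30), c(5, -2, 1))
    r3 <- paired_point_register(apply_transform(Tt, mv), mv)
    expect_transform_close(r3$transform, Tt, 1e-9, 1e-9)
  })
})

test_that("paired-point registration rejects degenerate configurations", {
  expect_error(paired_point_register(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "osteonav_degeneracy")
  line <- cbind(1:5, 0, 0)
  expect_error(paired_point_register(line, line),
               class = "osteonav_degeneracy")
})

test_that("solver matches the Horn quaternion oracle and never returns a reflection", {
  withr::with_seed(21, {
    for (i in 1:40) {
      mv <- random_points(sample(4:12, 1))
      fx <- apply_transform(random_rigid(), mv) +
        matrix(rnorm(length(mv), sd = 0.5), nrow(mv), 3)
      got <- paired_point_register(fx, mv)
      ora <- horn_register(fx, mv)
      expect_lt(max(abs(got$transform$R - ora$R)), 1e-6)
      expect_lt(max(abs(got$transform$t - ora$t)), 1e-6)
      expect_equal(det(got$transform$R), 1, tolerance = 1e-9)
    }
    # adversarial planar configurations must still give det +1
    for (i in 1:20) {
      mv <- cbind(matrix(rnorm(20, sd = 30), 10, 2), 0)
      fx <- apply_transform(random_rigid(), mv) +
        matrix(rnorm(30, sd = 2), 10, 3)
      got <- paired_point_register(fx, mv)
      expect_equal(det(got$transform$R), 1, tolerance = 1e-9)
    }
  })
})

test_that("registration is equivariant: register(G fixed, moving) = G o T", {
  withr::with_seed(33, {
    for (i in 1:20) {
      mv <- random_points(8)
      fx <- apply_transform(random_rigid(), mv) +
        matrix(rnorm(24, sd = 1), 8, 3)
      G <- random_rigid()
      base <- paired_point_register(fx, mv)$transform
      moved <- paired_point_register(apply_transform(G, fx), mv)$transform
      expect_transform_close(moved, compose(G, base), 1e-8, 1e-7)
    }
  })
})

test_that("nearest correspondences match the exhaustive search", {
  withr::with_seed(14, {
    fx <- random_points(60)
    mv <- random_points(50)
    got <- nearest_correspondences(mv, fx)
    ora <- brute_nearest(mv, fx)
    expect_equal(got$index, ora$index)
    expect_equal(got$distance, ora$distance, tolerance = 1e-10)
  })
  one <- matrix(c(0, 0, 0), 1)
  got <- nearest_correspondences(matrix(rnorm(30), 10, 3), one)
  expect_equal(got$index, rep(1L, 10))
  sub <- matrix(c(1, 1, 1, 5, 5, 5), 2, 3, byrow = TRUE)
  full <- rbind(sub, matrix(c(9, 9, 9), 1))
  self <- nearest_correspondences(sub, full)
  expect_equal(self$index, 1:2)
  expect_equal(self$distance, c(0, 0))
})

test_that("ICP converges immediately from the truth and recovers a 5-degree offset", {
  mesh <- make_synthetic_tibia()
  mv <- sample_surface_points(mesh, 500, seed = 8)
  Tt <- random_pose(3)
  fx <- apply_transform(Tt, mv)
  r <- icp_register(fx, mv, init = Tt)
  expect_lte(r$iterations, 2)
  expect_lt(r$fre_mm, 1e-9)

  withr::with_seed(10, {
    off <- rigid_transform(rotation_about_axis(rnorm(3), 5))
    fx2 <- apply_transform(off, mv)
    r2 <- icp_register(fx2, mv, init = identity_transform())
    expect_lt(rotation_angle_between(r2$transform$R, off$R), 0.1)
    expect_true(all(diff(r2$cost_history) <= 1e-12))
  })
})

test_that("ICP cost history is non-increasing across random seeded trials", {
  withr::with_seed(55, {
    for (i in 1:30) {
      mv <- random_points(80, sd = 30)
      Tt <- random_rigid(max_deg = 20, max_t = 10)
      fx <- apply_transform(Tt, mv) + matrix(rnorm(240, sd = 1), 80, 3)
      r <- icp_register(fx, mv, init = identity_transform(), max_iter = 40)
      expect_true(all(diff(r$cost_history) <= 1e-12))
    }
  })
})

test_that("two-stage registration recovers noiseless ground truth in both stages", {
  mesh <- make_synthetic_tibia()
  Tt <- random_pose(17)
  lm <- extract_feature_points(mesh, 5, seed = 2)
  rownames(lm) <- paste0("L", 1:5)
  surf <- sample_surface_points(mesh, 300, seed = 4)
  res <- two_stage_register(apply_transform(Tt, lm), lm,
                            apply_transform(Tt, surf), surf)
  expect_transform_close(res$coarse$transform, Tt, 1e-9, 1e-9)
  expect_transform_close(res$transform, Tt, 1e-9, 1e-9)
})

test_that("two-stage registration enforces the 3-7 landmark range by label", {
  mesh <- make_synthetic_tibia(n_axial = 12, n_theta = 12)
  surf <- sample_surface_points(mesh, 100, seed = 1)
  lm8 <- random_landmarks(8)
  expect_error(two_stage_register(lm8, lm8, surf, surf),
               class = "osteonav_usage")
  a <- random_landmarks(5)
  b <- a
  rownames(b) <- c("lm1", "lm2", "x3", "x4", "x5")
  err <- expect_error(two_stage_register(a, b, surf, surf),
                      class = "osteonav_degeneracy")
  expect_match(conditionMessage(err), "lm3")   # unmatched labels are listed
  expect_match(conditionMessage(err), "x3")
})

test_that("FRE and TRE follow their closed forms", {
  I <- identity_transform()
  withr::with_seed(3, {
    lm <- random_landmarks(6)
    expect_equal(fiducial_registration_error(I, lm, lm), 0)
    shifted <- sweep(lm, 2, c(-1, 0, 0))
    expect_equal(fiducial_registration_error(I, shifted, lm), 1)
    Tr <- random_rigid()
    fx <- random_landmarks(6)
    e <- fx - apply_transform(Tr, lm)
    expect_equal(fiducial_registration_error(Tr, fx, lm),
                 sqrt(mean(rowSums(e^2))))
    # FRE^2 = 2 J / n
    expect_equal(fiducial_registration_error(Tr, fx, lm)^2,
                 2 * registration_objective(Tr, fx, lm) / 6)

    targets <- random_points(10)
    expect_equal(target_registration_error(Tr, Tr, targets), 0)
    Tshift <- compose(rigid_transform(t = c(0, 0, 1)), Tr)
    expect_equal(target_registration_error(Tshift, Tr, targets), 1,
                 tolerance = 1e-12)
    # pure rotation about the centroid: mean deviation = mean 2 r_i sin(th/2)
    ctr <- colMeans(targets)
    th <- 25
    Trot <- rigid_transform(rotation_about_axis(c(0, 0, 1), th),
                            ctr - Rz(th) %*% ctr)
    radii <- sqrt(rowSums(sweep(targets, 2, ctr)[, 1:2, drop = FALSE]^2))
    expect_equal(target_registration_error(Trot, I, targets),
                 mean(2 * radii * sin(th / 2 * pi / 180)),
                 tolerance = 1e-9)
  })
})

test_that("TRE trends to zero as landmark noise shrinks", {
  mesh <- make_synthetic_tibia(n_axial = 16, n_theta = 16)
  lm <- extract_feature_points(mesh, 6, seed = 5)
  rownames(lm) <- paste0("L", 1:6)
  targets <- rbind(c(0, 0, 110), c(10, 0, 100))
  sigmas <- c(0, 0.5, 1, 2)
  mean_tre <- vapply(sigmas, function(s) {
    tres <- vapply(1:100, function(i) {
      Tt <- random_pose(i)
      noise <- withr::with_seed(i * 13 + round(s * 1000), {
        matrix(rnorm(18, sd = s), 6, 3)
      })
      fx <- apply_transform(Tt, lm) + noise
      est <- paired_point_register(fx, lm)$transform
      target_registration_error(est, Tt, targets)
    }, 1)
    mean(tres)
  }, 1)
  expect_equal(mean_tre[1], 0, tolerance = 1e-9)
  expect_true(all(diff(mean_tre) > 0))
})
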