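test_that("centroids of single-voxel and symmetric labels are exact", {
  arr <- array(0L, c(9, 9, 5))
  arr[3, 4, 2] <- 1L
  m <- label_mask(arr, spacing = c(1, 1, 3), origin = c(10, 0, 0))
  lm <- extract_centroids(m, "body")
  expect_equal(unlist(lm[1, c("x", "y", "z")], use.names = FALSE),
               c(10 + 2, 3, 3))
  # symmetric ellipsoid: centroid equals its centre within half a voxel
  cs <- tiny_phantom(seed = 3)
  lm2 <- extract_centroids(cs$mask, "body")
  err <- abs(as.matrix(lm2[, c("x", "y", "z")]) - cs$meta$body_centers)
  expect_true(all(sweep(err, 2, cs$mask$spacing / 2, `<=`)))
})

test_that("missing structures raise an error naming the vertebra", {
  arr <- array(0L, c(6, 6, 2))
  arr[2, 2, 1] <- 1L  # body of vertebra 1 only
  m <- label_mask(arr)
  expect_error(extract_centroids(m, c("body", "spinous_process")), "1")
})

test_that("fit_rigid is exact on noiseless correspondences", {
  set.seed(42)
  worst_rot <- 0; worst_tr <- 0; worst_rmse <- 0
  for (rep in 1:25) {
    mv <- random_landmarks(8)
    tf <- random_rotation(30)
    fx <- mv
    fx[, c("x", "y", "z")] <- transform_points(tf, lm_points_test(mv))
    fit <- fit_rigid(mv, fx)
    worst_rot <- max(worst_rot,
                     rotation_angle_test(t(fit$rotation) %*% tf$rotation))
    worst_tr <- max(worst_tr, max(abs(fit$translation - tf$translation)))
    worst_rmse <- max(worst_rmse, attr(fit, "rmse"))
  }
  expect_lt(worst_rot, 1e-6)
  expect_lt(worst_tr, 1e-6)
  expect_lt(worst_rmse, 1e-9)  # noiseless fit residual is at machine level
})

test_that("fit_rigid agrees with brute-force minimisation on a small case", {
  # independent oracle: grid search + refinement over rotations about z plus
  # translation, on a planar 3-point configuration rotated in-plane
  pts <- matrix(c(0, 0, 0, 10, 0, 0, 0, 6, 0), 3, 3, byrow = TRUE)
  ang <- 17 * pi / 180
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  fx <- t(Rz %*% t(pts)) + matrix(c(2, -1, 3), 3, 3, byrow = TRUE)
  obj <- function(a) {
    Ra <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    moved <- t(Ra %*% t(pts))
    tr <- colMeans(fx) - colMeans(moved)
    sum((sweep(moved, 2, -tr) - fx)^2)
  }
  grid <- seq(-pi, pi, length.out = 721)
  a_star <- grid[which.min(vapply(grid, obj, numeric(1)))]
  a_star <- stats::optimize(obj, a_star + c(-0.02, 0.02))$minimum
  mv <- landmark_set(1:3, rep("body", 3), pts)
  fxl <- landmark_set(1:3, rep("body", 3), fx)
  fit <- suppressWarnings(fit_rigid(mv, fxl))
  expect_equal(rotation_angle_test(fit$rotation), abs(a_star),
               tolerance = 1e-6)
  expect_lt(attr(fit, "rmse"), 1e-9)
})

test_that("collinear landmarks warn and resolve to the minimal rotation", {
  pts <- cbind(0, seq(0, 40, 10), 0)  # on the craniocaudal axis
  mv <- landmark_set(1:5, rep("body", 5), pts)
  tf <- rotation_about(10, "craniocaudal")  # rotation about that very axis
  fx <- mv
  fx[, c("x", "y", "z")] <- transform_points(tf, pts)
  expect_warning(fit <- fit_rigid(mv, fx), "collinear")
  # the rotation about the line is unconstrained -> minimal solution ~ 0 deg
  expect_lt(rotation_angle_test(fit$rotation) * 180 / pi, 1e-6)
})

test_that("fewer than three matched landmarks is an error", {
  a <- landmark_set(1:2, c("body", "body"), matrix(runif(6), 2, 3))
  b <- landmark_set(1:2, c("body", "body"), matrix(runif(6), 2, 3))
  expect_error(suppressWarnings(fit_rigid(a, b)), "insufficient")
})

test_that("fit_rigid composes consistently across frames", {
  set.seed(7)
  A <- random_landmarks(6)
  tf1 <- random_rotation(20); tf2 <- random_rotation(20)
  B <- A; B[, c("x", "y", "z")] <- transform_points(tf1, lm_points_test(A))
  C <- A; C[, c("x", "y", "z")] <- transform_points(
    compose_transforms(tf2, tf1), lm_points_test(A))
  f_ab <- fit_rigid(A, B); f_bc <- fit_rigid(B, C); f_ac <- fit_rigid(A, C)
  comp <- compose_transforms(f_bc, f_ab)
  expect_equal(comp$rotation, f_ac$rotation, tolerance = 1e-6)
  expect_equal(comp$translation, f_ac$translation, tolerance = 1e-6)
})

test_that("resample_onto honours interpolation contracts", {
  cs <- tiny_phantom(seed = 8)
  expect_error(resample_onto(cs$mask, rigid_transform(), grid_of(cs$mask),
                             "linear"), "nearest")
  same <- resample_onto(cs$ct, rigid_transform(), grid_of(cs$ct), "linear")
  expect_equal(same$data, cs$ct$data, tolerance = 1e-12)
  # rotation then inverse preserves the mask
  tf <- rotation_about(12, "craniocaudal", center = volume_center(cs$ct))
  fwd <- resample_onto(cs$mask, tf, grid_of(cs$mask))
  back <- resample_onto(fwd, invert_transform(tf), grid_of(cs$mask))
  expect_gte(dice(cs$mask, back)$per_volume, 0.95)
})

test_that("2-point registration beats 1-point under craniocaudal rotation", {
  cs <- tiny_phantom(seed = 21,
                     misalign = list(angle_deg = 10, axis = "craniocaudal",
                                     translation_mm = c(2, 1, 0)))
  dscs <- sapply(c(1, 2), function(pts) {
    st <- if (pts == 1) "body" else c("body", "spinous_process")
    fit <- suppressWarnings(fit_rigid(
      extract_centroids(phantom_segmenter(cs$ct), st),
      extract_centroids(cs$mask, st)))
    posterior_dsc(cs$mask, resample_onto(cs$ct_mask, fit, grid_of(cs$mask)))
  })
  expect_gt(dscs[2], dscs[1])
})

test_that("refinement with the oracle translator closes the loop", {
  cfg <- phantom_config(seed = 31,
                        misalignment = list(angle_deg = 5,
                                            axis = "craniocaudal",
                                            translation_mm = c(5, 0, 2)))
  cs <- generate_phantom(cfg)
  res <- suppressWarnings(refine_registration(
    cs$mr, cs$ct, phantom_oracle_translator(cfg), phantom_segmenter,
    rounds = 3, points = 2))
  resid <- compose_transforms(res$transform, cs$truth_transform)
  expect_lt(rotation_angle_test(resid$rotation) * 180 / pi, 1)
  expect_lt(sqrt(sum(resid$translation^2)), 1.5)
})

test_that("refinement stops early on an aligned pair and rounds=0 is initial", {
  cfg <- phantom_config(seed = 33)
  cs <- generate_phantom(cfg)
  tr <- phantom_oracle_translator(cfg)
  r0 <- suppressWarnings(refine_registration(cs$mr, cs$ct, tr,
                                             phantom_segmenter, rounds = 0))
  expect_equal(r0$rounds_run, 0)
  r1 <- suppressWarnings(refine_registration(cs$mr, cs$ct, tr,
                                             phantom_segmenter, rounds = 5))
  expect_lt(r1$rounds_run, 5)  # early stop below 0.5 mm displacement
  expect_lt(utils::tail(r1$displacements, 1), 0.5)
})

test_that("landmarks and transforms survive a JSON round trip", {
  lm <- random_landmarks(5, seed = 12)
  f <- tempfile(fileext = ".json")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f)
  expect_equal(lm_points_test(lm), lm_points_test(lm2), tolerance = 1e-12)
  tf <- random_rotation(15)
  f2 <- tempfile(fileext = ".json")
  write_transform(tf, f2)
  tf2 <- read_transform(f2)
  expect_equal(tf$rotation, tf2$rotation, tolerance = 1e-12)
  expect_equal(tf$translation, tf2$translation, tolerance = 1e-12)
})
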