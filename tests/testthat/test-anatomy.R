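test_that("sphere fit recovers exact sphere samples to numerical precision", {
  pts <- hbmforge:::fibonacci_sphere(30, c(1, 2, 3), 22)
  fit <- fit_sphere(pts)
  expect_equal(fit$centre, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(fit$radius, 22, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
})

test_that("noisy sphere fit matches an independent nonlinear refit", {
  skip_if_not_installed("minpack.lm")
  set.seed(42)
  pts <- hbmforge:::fibonacci_sphere(30, c(1, 2, 3), 22) +
    matrix(rnorm(90, sd = 0.1), 30, 3)
  fit <- fit_sphere(pts)
  # oracle: nonlinear least squares on radial residuals
  resid_fun <- function(p) {
    sqrt(rowSums((pts - matrix(p[1:3], 30, 3, byrow = TRUE))^2)) - p[4]
  }
  nls <- minpack.lm::nls.lm(par = c(0, 0, 0, 20), fn = resid_fun)
  expect_equal(fit$centre, nls$par[1:3], tolerance = 1e-2)
  expect_equal(fit$radius, nls$par[4], tolerance = 1e-2)
})

test_that("coplanar points are rejected by the sphere fit", {
  pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)
  expect_error(fit_sphere(pts), "degenerate|coplanar")
})

test_that("origin placement puts the H-point where the posture demands", {
  asm <- single_hex_assembly(unit_hex() * 100)
  hp <- c(12, -3, 40)
  seated <- set_model_origin(asm, "seated", hp)
  expect_equal(node_matrix(seated), node_matrix(asm) -
                 matrix(hp, 8, 3, byrow = TRUE), ignore_attr = TRUE)
  # standing: sole 800 mm below -> H-point ends at (0, 0, 800)
  standing <- set_model_origin(asm, "standing", hp, sole_z = hp[3] - 800)
  hp_new <- hp + c(-hp[1], -hp[2], -(hp[3] - 800))
  expect_equal(hp_new, c(0, 0, 800))
  # idempotence: re-running with the transformed H-point is the identity
  seated2 <- set_model_origin(seated, "seated", c(0, 0, 0))
  expect_equal(node_matrix(seated2), node_matrix(seated))
})

test_that("model rotation composes z then y and preserves distances", {
  asm <- single_hex_assembly()
  expect_equal(node_matrix(rigid_transform_model(asm, 0, 0)),
               node_matrix(asm))
  flipped <- rigid_transform_model(
    single_hex_assembly(matrix(c(1, 2, 0), 8, 3, byrow = TRUE)), 180, 0)
  expect_equal(node_matrix(flipped)[1, ], c(-1, -2, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
  # lateral thorax case (z 330) against an independent matrix composition
  set.seed(7)
  p <- matrix(rnorm(30, sd = 100), 10, 3)
  asm10 <- hbm_assembly(nodes = data.frame(id = 1:10, x = p[, 1],
                                           y = p[, 2], z = p[, 3]))
  got <- node_matrix(rigid_transform_model(asm10, 330, 23))
  a <- 330 * pi / 180; b <- 23 * pi / 180
  Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  expect_equal(got, p %*% t(Ry %*% Rz), tolerance = 1e-12,
               ignore_attr = TRUE)
  d0 <- dist(p); d1 <- dist(got)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})

test_that("volumetric bone scaling acts per axis about the anchor", {
  set.seed(3)
  p <- matrix(rnorm(60, sd = 30), 20, 3)
  expect_equal(scale_bone_volumetric(p, c(1, 1, 1)), p)
  ctr <- colMeans(p)
  s <- scale_bone_volumetric(p, 1.08)
  expect_equal(sqrt(rowSums((s - matrix(ctr, 20, 3, TRUE))^2)),
               1.08 * sqrt(rowSums((p - matrix(ctr, 20, 3, TRUE))^2)))
  # anisotropic: the bounding box scales per axis about the anchor
  s2 <- scale_bone_volumetric(p, c(1.08, 1.05, 1.08), anchor = c(0, 0, 0))
  expect_equal(apply(s2, 2, range),
               apply(p, 2, range) %*% diag(c(1.08, 1.05, 1.08)),
               ignore_attr = TRUE)
  expect_error(scale_bone_volumetric(p, c(1, -1, 1)), "positive")
})

test_that("stature ratio percent behaves as a scale rule", {
  r <- stature_ratio_scale(1750, 1620)
  expect_equal(r$percent, 100 * 1750 / 1620)
  expect_equal(r$percent_int, 108L)
  expect_equal(stature_ratio_scale(1620, 1620)$percent, 100)
  expect_equal(stature_ratio_scale(1458, 1620)$percent_int, 90L)
  # reciprocity: forward times backward percent is 100^2
  expect_equal(stature_ratio_scale(1750, 1620)$percent *
                 stature_ratio_scale(1620, 1750)$percent, 1e4,
               tolerance = 1e-9)
})

test_that("clavicle scaling reproduces the target joint distance", {
  expect_equal(clavicle_scale(140, 150), 150 / 140)
  expect_equal(clavicle_scale(150, 150), 1)
  sc_joint <- c(10, 5, 0)
  ac_joint <- c(150, 20, 30)
  fac <- clavicle_scale(sqrt(sum((ac_joint - sc_joint)^2)), 162)
  clav <- rbind(sc_joint, ac_joint, c(80, 10, 10))
  scaled <- scale_bone_volumetric(clav, fac, anchor = sc_joint)
  expect_equal(sqrt(sum((scaled[2, ] - scaled[1, ])^2)), 162,
               tolerance = 1e-9)
})

test_that("skeletal reorientation is rigid per group and errors on a missing transform", {
  set.seed(11)
  groups <- list(pelvis = matrix(rnorm(30, sd = 40), 10, 3),
                 ribcage = matrix(rnorm(24, sd = 60), 8, 3))
  ident <- list(pelvis = rigid_transform(), ribcage = rigid_transform())
  expect_equal(reorient_skeleton_vru(groups, ident), groups)
  hip <- c(0, 0, 0)
  tr <- list(pelvis = pelvis_rotation(42, hip),
             ribcage = random_rigid())
  out <- reorient_skeleton_vru(groups, tr)
  # distances to the hip centre are preserved by the pelvis rotation
  expect_equal(sqrt(rowSums(out$pelvis^2)),
               sqrt(rowSums(groups$pelvis^2)), tolerance = 1e-9)
  # rotation angle about y is the stated 42 degrees
  p <- c(100, 0, 0)
  q <- apply_transform(tr$pelvis, p)
  ang <- atan2(-q[3], q[1]) * 180 / pi
  expect_equal(abs(ang), 42, tolerance = 1e-9)
  # intra-group distances preserved under the common ribcage transform
  expect_equal(as.numeric(dist(out$ribcage)),
               as.numeric(dist(groups$ribcage)), tolerance = 1e-9)
  expect_error(reorient_skeleton_vru(groups, tr["pelvis"]),
               "no rigid transform.*ribcage")
})

test_that("rigid transform utilities preserve distances and compose", {
  set.seed(13)
  for (k in 1:5) {
    tr <- random_rigid()
    p <- matrix(rnorm(30, sd = 100), 10, 3)
    q <- apply_transform(tr, p)
    expect_equal(as.numeric(dist(q)), as.numeric(dist(p)),
                 tolerance = 1e-9)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  }
  t1 <- random_rigid(); t2 <- random_rigid()
  p <- rnorm(3)
  expect_equal(apply_transform(compose_transforms(t2, t1), p),
               apply_transform(t2, apply_transform(t1, p)))
})
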