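test_that("support-surface pre-morph blends the two bone transforms with partition-of-unity weights", {
  set.seed(30)
  sleeve <- matrix(rnorm(45, sd = 20), 15, 3) +
    matrix(c(0, 0, 50), 15, 3, byrow = TRUE)
  bones <- list(femur = matrix(rnorm(30, sd = 20), 10, 3) +
                  matrix(c(0, 0, 120), 10, 3, byrow = TRUE),
                tibia = matrix(rnorm(30, sd = 20), 10, 3) +
                  matrix(c(0, 0, -50), 10, 3, byrow = TRUE))
  surf <- list(list(name = "knee", points = sleeve,
                    bones = c("femur", "tibia"), region = "left_extremity"))

  ident <- list(femur = rigid_transform(), tibia = rigid_transform())
  out0 <- pre_morph_support_surfaces(surf, ident, bones)
  expect_equal(landmark_coords(out0$target), landmark_coords(out0$source))

  R90 <- rotation_about_point(c(0, 1, 0), 90, c(0, 0, 0))
  same <- list(femur = R90, tibia = R90)
  out1 <- pre_morph_support_surfaces(surf, same, bones)
  expect_equal(landmark_coords(out1$target), apply_transform(R90, sleeve),
               ignore_attr = TRUE)

  mixed <- list(femur = R90, tibia = rigid_transform())
  out2 <- pre_morph_support_surfaces(surf, mixed, bones)
  w <- out2$weights$knee
  expect_true(all(abs(rowSums(w) - 1) < 1e-12))
  p1 <- apply_transform(R90, sleeve)
  blended <- w[, 1] * p1 + w[, 2] * sleeve
  expect_equal(landmark_coords(out2$target), blended, ignore_attr = TRUE)
  # every blended point lies between the two rigid predictions
  lo <- pmin(p1, sleeve); hi <- pmax(p1, sleeve)
  tc <- landmark_coords(out2$target)
  expect_true(all(tc >= lo - 1e-9 & tc <= hi + 1e-9))

  expect_error(pre_morph_support_surfaces(
    list(list(name = "bad", points = sleeve, bones = "femur")),
    mixed, bones), "exactly two")
  expect_error(pre_morph_support_surfaces(
    list(list(name = "bad", points = sleeve,
              bones = c("femur", "patella"))), mixed, bones),
    "no transform.*patella")
})

test_that("identity morph leaves every node in place across all stages", {
  fx <- get_fixture()
  tg <- make_fixture_targets(fx, "scaled_male", scale = c(1, 1, 1))
  res <- morph_derivative(fx$assembly, tg$plan, tg$source, tg$target,
                          ridge = 0)
  expect_lt(max(abs(node_matrix(res$assembly) - node_matrix(fx$assembly))),
            1e-9)
})

test_that("a global affine target map is reproduced across sequential stages", {
  fx <- get_fixture()
  tg <- make_fixture_targets(fx, "scaled_male", scale = c(1.2, 1.2, 1.2))
  res <- morph_derivative(fx$assembly, tg$plan, tg$source, tg$target,
                          ridge = 0)
  expect_lt(max(abs(node_matrix(res$assembly) -
                      1.2 * node_matrix(fx$assembly))), 1e-6)
  # element tables and ids untouched
  expect_identical(res$assembly$solids, fx$assembly$solids)
  expect_identical(res$assembly$shells, fx$assembly$shells)
  expect_identical(res$assembly$nodes$id, fx$assembly$nodes$id)
})

test_that("stage locality: a stage's output is independent of stages that do not feed it", {
  # two well-separated blocks, each its own stage; with no exterior-node
  # coupling the result for block B must be bitwise the same whether A is
  # morphed before or after it
  cA <- unit_hex() * 100
  cB <- unit_hex() * 100 + matrix(c(1000, 0, 0), 8, 3, byrow = TRUE)
  asm <- hbm_assembly(
    nodes = data.frame(id = 1:16, x = c(cA[, 1], cB[, 1]),
                       y = c(cA[, 2], cB[, 2]), z = c(cA[, 3], cB[, 3])),
    solids = rbind(
      data.frame(id = 1L, part = 1L, n1 = 1L, n2 = 2L, n3 = 3L, n4 = 4L,
                 n5 = 5L, n6 = 6L, n7 = 7L, n8 = 8L),
      data.frame(id = 2L, part = 1L, n1 = 9L, n2 = 10L, n3 = 11L,
                 n4 = 12L, n5 = 13L, n6 = 14L, n7 = 15L, n8 = 16L)),
    parts = data.frame(id = 1L, name = "blocks", region = "torso",
                       material = "flesh", density = 1e-6))
  lab <- c(paste0("a", 1:8), paste0("b", 1:8))
  src <- landmark_set(lab, "torso", "skin", rbind(cA, cB))
  tgt <- landmark_set(lab, "torso", "skin",
                      rbind(cA + matrix(c(10, 0, 0), 8, 3, byrow = TRUE),
                            cB + matrix(c(0, 0, 20), 8, 3, byrow = TRUE)))
  stA <- morph_stage("A", 1:8, paste0("a", 1:8), use_saved = FALSE)
  stB <- morph_stage("B", 9:16, paste0("b", 1:8), use_saved = FALSE)
  r1 <- morph_derivative(asm, morph_plan(stA, stB), src, tgt, ridge = 0)
  r2 <- morph_derivative(asm, morph_plan(stB, stA), src, tgt, ridge = 0)
  expect_identical(node_matrix(r1$assembly)[9:16, ],
                   node_matrix(r2$assembly)[9:16, ])
  expect_identical(node_matrix(r1$assembly)[1:8, ],
                   node_matrix(r2$assembly)[1:8, ])
})

test_that("plan coverage violations are reported", {
  fx <- get_fixture()
  tg <- make_fixture_targets(fx, "scaled_male")
  s1 <- tg$plan$stages[[1]]; s2 <- tg$plan$stages[[2]]
  # a node in two stages
  bad2 <- morph_plan(s1, morph_stage("torso", c(s2$move_nodes,
                                                s1$move_nodes[1]),
                                     s2$landmark_labels))
  expect_error(morph_derivative(fx$assembly, bad2, tg$source, tg$target),
               "more than one stage")
  # a node in no stage
  bad0 <- morph_plan(s1, morph_stage("torso", s2$move_nodes[-1],
                                     s2$landmark_labels))
  expect_error(morph_derivative(fx$assembly, bad0, tg$source, tg$target),
               "no stage")
})

test_that("seated-to-standing morph preserves topology and reports quality", {
  fx <- get_fixture()
  tg <- make_fixture_targets(fx, "standing")
  res <- morph_derivative(fx$assembly, tg$plan, tg$source, tg$target)
  expect_identical(res$assembly$solids, fx$assembly$solids)
  expect_identical(res$assembly$shells, fx$assembly$shells)
  expect_identical(res$assembly$nodes$id, fx$assembly$nodes$id)
  expect_equal(nrow(res$nodes), nrow(fx$assembly$nodes))
  # thigh landmarks moved rigidly: distances to the hip centre preserved
  thigh_rows <- tg$source$region == "left_extremity" &
    tg$source$surface != "support" &
    landmark_coords(tg$source)[, 3] > -1e-6
  src_d <- sqrt(rowSums(sweep(landmark_coords(tg$source)[thigh_rows, ],
                              2, fx$hip_centres$L)^2))
  tgt_d <- sqrt(rowSums(sweep(landmark_coords(tg$target)[thigh_rows, ],
                              2, fx$hip_centres$L)^2))
  expect_equal(tgt_d, src_d, tolerance = 1e-9)
  rep <- morph_report(fx$assembly, res$assembly)
  expect_gt(rep$max_displacement, 100)
  expect_true(is.finite(rep$violations_derivative))
})

test_that("morph report violation counts match a brute-force recount and flag corrupted elements", {
  fx <- get_fixture()
  tg <- make_fixture_targets(fx, "standing")
  res <- morph_derivative(fx$assembly, tg$plan, tg$source, tg$target)
  rep <- morph_report(fx$assembly, res$assembly)
  # independent recount: loop over all elements with the metric functions
  der <- res$assembly
  xyz <- node_matrix(der)
  count <- 0L
  for (r in seq_len(nrow(der$solids))) {
    p <- xyz[match(unlist(der$solids[r, paste0("n", 1:8)]), der$nodes$id), ]
    if (scaled_jacobian(p, "hex8") < 0.3 ||
        aspect_ratio(p, "hex8") > 12) count <- count + 1L
  }
  for (r in seq_len(nrow(der$shells))) {
    p <- xyz[match(unlist(der$shells[r, paste0("n", 1:4)]), der$nodes$id), ]
    if (scaled_jacobian(p, "quad4") < 0.3 || aspect_ratio(p, "quad4") > 12 ||
        warpage(p) > 30) count <- count + 1L
  }
  expect_identical(rep$violations_derivative, count)
  # derivative equal to base: identical histograms, zero violation delta
  rep0 <- morph_report(fx$assembly, fx$assembly)
  expect_identical(rep0$violations_base, rep0$violations_derivative)
  expect_equal(rep0$base$histograms$jacobian$counts,
               rep0$derivative$histograms$jacobian$counts)
  expect_equal(rep0$max_displacement, 0)
  # hand-corrupt one element: it must top the worst list.  Pick a node
  # used by exactly one solid (a mesh corner) and collapse it onto a
  # neighbouring corner of that element, degenerating only that element.
  bad <- res$assembly
  usage <- table(unlist(bad$solids[paste0("n", 1:8)]))
  in_shell <- unique(unlist(bad$shells[paste0("n", 1:4)]))
  lone <- setdiff(as.integer(names(usage)[usage == 1]), in_shell)[1]
  erow <- which(apply(bad$solids[paste0("n", 1:8)], 1,
                      function(nn) lone %in% nn))[1]
  nn <- unlist(bad$solids[erow, paste0("n", 1:8)], use.names = FALSE)
  other <- nn[nn != lone][1]
  bad$nodes[match(lone, bad$nodes$id), c("x", "y", "z")] <-
    bad$nodes[match(other, bad$nodes$id), c("x", "y", "z")]
  repb <- morph_report(res$assembly, bad)
  expect_equal(repb$worst$jacobian$id[1], bad$solids$id[erow])
  expect_lte(repb$worst$jacobian$jacobian[1], 0)
})
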