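test_that("ideal elements score perfect metrics", {
  expect_equal(scaled_jacobian(unit_hex(), "hex8"), 1)
  expect_equal(aspect_ratio(unit_hex(), "hex8"), 1)
  sq <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), 4, 3, byrow = TRUE)
  expect_equal(scaled_jacobian(sq, "quad4"), 1)
  expect_equal(warpage(sq), 0)
})

test_that("sheared hex matches a finite-difference trilinear Jacobian oracle", {
  shear <- unit_hex()
  shear[5:8, 1] <- shear[5:8, 1] + 0.5
  got <- scaled_jacobian(shear, "hex8")
  # oracle: numerical Jacobian of the trilinear map at the 8 corners
  trilinear <- function(x, xi) {
    N <- c((1 - xi[1]) * (1 - xi[2]) * (1 - xi[3]),
           xi[1] * (1 - xi[2]) * (1 - xi[3]),
           xi[1] * xi[2] * (1 - xi[3]),
           (1 - xi[1]) * xi[2] * (1 - xi[3]),
           (1 - xi[1]) * (1 - xi[2]) * xi[3],
           xi[1] * (1 - xi[2]) * xi[3],
           xi[1] * xi[2] * xi[3],
           (1 - xi[1]) * xi[2] * xi[3])
    as.numeric(t(x) %*% N)
  }
  corner_xi <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                     c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  h <- 1e-6
  vals <- apply(corner_xi, 1, function(xi) {
    J <- vapply(1:3, function(k) {
      # one-sided difference into the element
      dir <- rep(0, 3); dir[k] <- if (xi[k] == 0) h else -h
      sgn <- if (xi[k] == 0) 1 else -1
      sgn * (trilinear(shear, xi + dir) - trilinear(shear, xi)) / h
    }, numeric(3))
    det(J) / prod(sqrt(colSums(J^2)))
  })
  expect_equal(got, min(vals), tolerance = 1e-5)
})

test_that("degenerate elements give non-positive Jacobian, never an exception", {
  degen <- unit_hex()
  degen[7, ] <- degen[8, ]          # coincident corners
  expect_lte(scaled_jacobian(degen, "hex8"), 0)
})

test_that("aspect ratio equals the brute-force edge extremes", {
  expect_equal(aspect_ratio(brick_hex(12, 1, 1), "hex8"), 12)
  set.seed(40)
  hx <- unit_hex() + matrix(rnorm(24, sd = 0.15), 8, 3)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(5, 6), c(6, 7),
                 c(7, 8), c(8, 5), c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  len <- apply(edges, 1, function(e) sqrt(sum((hx[e[1], ] - hx[e[2], ])^2)))
  expect_equal(aspect_ratio(hx, "hex8"), max(len) / min(len))
  sq0 <- matrix(c(0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 1, 0), 4, 3, byrow = TRUE)
  expect_equal(aspect_ratio(sq0, "quad4"), Inf)
})

test_that("warpage matches a direct normal-angle computation and is rigid-invariant", {
  q <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0.3), 4, 3, byrow = TRUE)
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  ang <- function(i, j, k, l) {
    n1 <- cross(q[j, ] - q[i, ], q[k, ] - q[i, ])
    n2 <- cross(q[k, ] - q[i, ], q[l, ] - q[i, ])
    acos(sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))) * 180 / pi
  }
  oracle <- max(ang(1, 2, 3, 4), ang(2, 3, 4, 1))
  expect_equal(warpage(q), oracle, tolerance = 1e-9)
  set.seed(41)
  tr <- random_rigid()
  expect_equal(warpage(apply_transform(tr, q)), warpage(q),
               tolerance = 1e-9)
})

test_that("all metrics are invariant under rigid motion and uniform scaling", {
  set.seed(42)
  for (k in 1:20) {
    hx <- unit_hex() + matrix(rnorm(24, sd = 0.2), 8, 3)
    tr <- random_rigid()
    s <- runif(1, 0.3, 4)
    hx2 <- apply_transform(tr, hx) * 1  # rigid
    hx3 <- hx * s                        # uniform scale
    expect_equal(scaled_jacobian(hx2, "hex8"), scaled_jacobian(hx, "hex8"),
                 tolerance = 1e-9)
    expect_equal(scaled_jacobian(hx3, "hex8"), scaled_jacobian(hx, "hex8"),
                 tolerance = 1e-9)
    expect_equal(aspect_ratio(hx2, "hex8"), aspect_ratio(hx, "hex8"),
                 tolerance = 1e-9)
    expect_equal(aspect_ratio(hx3, "hex8"), aspect_ratio(hx, "hex8"),
                 tolerance = 1e-9)
    q <- (unit_hex() + matrix(rnorm(24, sd = 0.2), 8, 3))[1:4, ]
    expect_equal(warpage(apply_transform(tr, q)), warpage(q),
                 tolerance = 1e-8)
    expect_equal(warpage(q * s), warpage(q), tolerance = 1e-9)
  }
})

test_that("threshold classification fails the constructed boundary cases", {
  # jacobian 0.29 vs 0.30: shear a unit cube so its corner jacobian hits
  # the requested value exactly: top face offset t gives J = 1/sqrt(1+t^2)
  mkshear <- function(J) {
    t <- sqrt(1 / J^2 - 1)
    hx <- unit_hex(); hx[5:8, 1] <- hx[5:8, 1] + t
    hx
  }
  expect_equal(scaled_jacobian(mkshear(0.29), "hex8"), 0.29,
               tolerance = 1e-12)
  nodes_for <- function(c8, extra_quad = NULL) {
    asm <- single_hex_assembly(c8)
    if (!is.null(extra_quad)) {
      asm$shells <- data.frame(id = 2L, part = 1L, n1 = 1L, n2 = 2L,
                               n3 = 3L, n4 = 4L, thickness = 1,
                               include = NA_character_)
      asm$nodes[1:4, c("x", "y", "z")] <- extra_quad
    }
    asm
  }
  rep1 <- classify_elements(nodes_for(mkshear(0.29)))
  expect_true(rep1$elements$fail_jacobian[1])
  rep2 <- classify_elements(nodes_for(mkshear(0.31)))
  expect_false(rep2$elements$fail[1])
  # aspect 11.9 passes, warp 31 degrees fails
  rep3 <- classify_elements(single_hex_assembly(brick_hex(11.9, 1, 1)))
  expect_false(rep3$elements$fail[1])
  rep4 <- classify_elements(single_hex_assembly(brick_hex(12.1, 1, 1)))
  expect_true(rep4$elements$fail_aspect[1])
  # a quad warped to a chosen angle: lift one corner
  lift_for_warp <- function(deg) {
    f <- function(h) {
      q <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, h), 4, 3,
                  byrow = TRUE)
      warpage(q) - deg
    }
    stats::uniroot(f, c(1e-4, 2))$root
  }
  h31 <- lift_for_warp(31)
  quad31 <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, h31), 4, 3,
                   byrow = TRUE)
  asm <- single_hex_assembly(unit_hex() + 10)
  asm$nodes <- rbind(asm$nodes,
                     data.frame(id = 9:12, x = quad31[, 1], y = quad31[, 2],
                                z = quad31[, 3], include = NA))
  asm$shells <- data.frame(id = 2L, part = 1L, n1 = 9L, n2 = 10L,
                           n3 = 11L, n4 = 12L, thickness = 1,
                           include = NA_character_)
  rep5 <- classify_elements(asm)
  shellrow <- rep5$elements$type == "shell"
  expect_equal(rep5$elements$warp[shellrow], 31, tolerance = 1e-6)
  expect_true(rep5$elements$fail_warp[shellrow])
  expect_true(2L %in% rep5$violations$warp)
})

test_that("violation sets equal an independent full rescan of the fixture", {
  fx <- get_fixture()
  rep <- classify_elements(fx$assembly)
  expect_equal(rep$n_failed, 0)
  expect_length(rep$violations$jacobian, 0)
  expect_equal(nrow(rep$elements),
               nrow(fx$assembly$solids) + nrow(fx$assembly$shells))
  # histogram mass beyond thresholds equals the violation counts
  expect_equal(sum(rep$elements$jacobian < 0.3),
               length(rep$violations$jacobian))
})

test_that("pentahedra are measured through their wedge corners and edges", {
  wedge <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                 c(0, 0, 1), c(1, 0, 1), c(0, 1, 1))
  expect_gt(scaled_jacobian(wedge, "penta6"), 0.5)
  expect_equal(aspect_ratio(wedge, "penta6"), sqrt(2))
  # collapsed-hex encoding is recognized by the classifier
  asm <- hbm_assembly(
    nodes = data.frame(id = 1:6, x = wedge[, 1], y = wedge[, 2],
                       z = wedge[, 3]),
    solids = data.frame(id = 1L, part = 1L, n1 = 1L, n2 = 2L, n3 = 3L,
                        n4 = 3L, n5 = 4L, n6 = 5L, n7 = 6L, n8 = 6L),
    parts = data.frame(id = 1L, name = "wedge", region = "torso",
                       material = "flesh", density = 1e-6))
  rep <- classify_elements(asm)
  expect_equal(rep$elements$kind, "penta6")
  expect_false(rep$elements$fail)
})
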