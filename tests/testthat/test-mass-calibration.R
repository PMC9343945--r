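test_that("hex volume by tetra decomposition is exact for parallelepipeds", {
  expect_equal(hex_volume(unit_hex()), 1)
  set.seed(50)
  for (k in 1:10) {
    A <- matrix(rnorm(9), 3, 3)
    if (abs(det(A)) < 0.1) next
    par <- unit_hex() %*% t(A)
    expect_equal(hex_volume(par), abs(det(A)), tolerance = 1e-9)
  }
})

test_that("region masses follow density and sum like a brute-force recount", {
  # single unit-cube hex at 1e-6 kg/mm^3 weighs 1e-6 kg
  asm <- single_hex_assembly(unit_hex(), density = 1e-6)
  m <- compute_region_masses(asm)
  expect_equal(m$total, 1e-6)
  expect_equal(m$regions$mass, 1e-6)

  fx <- get_fixture()
  m1 <- compute_region_masses(fx$assembly)
  # independent summation oracle: analytic box volumes (all fixture
  # elements are axis-aligned boxes) times part density
  xyz <- node_matrix(fx$assembly)
  total <- 0
  for (r in seq_len(nrow(fx$assembly$solids))) {
    p <- xyz[match(unlist(fx$assembly$solids[r, paste0("n", 1:8)]),
                   fx$assembly$nodes$id), ]
    vol <- prod(apply(p, 2, function(v) diff(range(v))))
    dens <- fx$assembly$parts$density[
      match(fx$assembly$solids$part[r], fx$assembly$parts$id)]
    total <- total + vol * dens
  }
  for (r in seq_len(nrow(fx$assembly$shells))) {
    p <- xyz[match(unlist(fx$assembly$shells[r, paste0("n", 1:4)]),
                   fx$assembly$nodes$id), ]
    side <- apply(p, 2, function(v) diff(range(v)))
    area <- prod(side[side > 0])
    dens <- fx$assembly$parts$density[
      match(fx$assembly$shells$part[r], fx$assembly$parts$id)]
    total <- total + area * fx$assembly$shells$thickness[r] * dens
  }
  expect_equal(m1$total, total, tolerance = 1e-12)
  # linearity: doubling all densities doubles all masses
  dd <- stats::setNames(fx$assembly$parts$density * 2,
                        fx$assembly$parts$id)
  m2 <- compute_region_masses(fx$assembly, densities = dd)
  expect_equal(m2$regions$mass, 2 * m1$regions$mass)
  # missing density errors naming the part
  asm_na <- fx$assembly
  asm_na$parts$density[1] <- NA
  expect_error(compute_region_masses(asm_na), "no density for part")
})

test_that("flesh-density solve hits arbitrary feasible region targets within 0.1%", {
  b <- mass_budget(region = c("head", "torso", "lower_extremities"),
                   target_kg = c(4.5, 30, 22),
                   non_flesh_kg = c(1.2, 8, 5),
                   flesh_volume_mm3 = c(3e6, 2.5e7, 1.4e7))
  sol <- solve_flesh_densities(b)
  expect_true(all(abs(sol$achieved$mass_kg - b$target_kg) /
                    b$target_kg < 1e-3))
  # direct arithmetic example
  b1 <- mass_budget("r", 12, 2, 1e7)
  expect_equal(solve_flesh_densities(b1)$solved$flesh_density, 1e-6)
  # a region given a relatively higher target solves to a strictly
  # higher flesh density than the others
  b2 <- mass_budget(c("lower_extremities", "rest"),
                    target_kg = c(25, 20),
                    non_flesh_kg = c(5, 5),
                    flesh_volume_mm3 = c(1e7, 1e7))
  s2 <- solve_flesh_densities(b2)
  expect_gt(s2$solved$flesh_density[1], s2$solved$flesh_density[2])
})

test_that("infeasible and degenerate budgets are rejected", {
  expect_error(solve_flesh_densities(mass_budget("r", 1, 2, 1e7)),
               "infeasible")
  expect_error(solve_flesh_densities(mass_budget("r", 5, 2, 0)),
               "zero flesh volume")
})

test_that("variant density parameters scale the solved densities", {
  b <- mass_budget("torso", 30, 8, 2.5e7)
  pars <- density_parameters(M_standing = 1.03)
  s <- solve_flesh_densities(b, pars, sex = "M", posture = "standing")
  expect_equal(s$densities$flesh_density,
               1.03 * s$solved$flesh_density)
  expect_error(density_parameters(F_seated = -1), "positive")
})

test_that("added mass follows the quadratic timestep scaling law", {
  # element with dt_crit exactly half the target: density x4, added 3x mass
  L <- 10
  asm <- single_hex_assembly(unit_hex() * L, density = 1e-6)
  mat <- data.frame(part = 1L, E = 1, nu = 0, rho = 1e-6)
  c0 <- sqrt(1 / 1e-6)           # wave speed, mm/ms
  dtc <- L / c0                  # characteristic length = V/A = L
  est <- estimate_added_mass(asm, mat, dt_target = 2 * dtc)
  m0 <- L^3 * 1e-6
  expect_equal(est$elements$dt_crit, dtc)
  expect_equal(est$total_added_kg, 3 * m0, tolerance = 1e-12)
  # dt_crit >= target: no mass added
  est0 <- estimate_added_mass(asm, mat, dt_target = dtc / 2)
  expect_equal(est0$total_added_kg, 0)
  expect_error(estimate_added_mass(asm, data.frame(part = 1L, E = -1,
                                                   nu = 0, rho = 1e-6),
                                   1e-4), "non-physical")
})

test_that("added mass concentrates in the thin stiff part and grows with the target timestep", {
  # a slender 'fibula-like' part next to a bulky flesh block
  thin <- unit_hex() %*% diag(c(0.5, 0.5, 40))
  bulk <- unit_hex() %*% diag(c(60, 60, 60)) +
    matrix(c(20, 0, 0), 8, 3, byrow = TRUE)
  nodes <- data.frame(id = 1:16,
                      x = c(thin[, 1], bulk[, 1]),
                      y = c(thin[, 2], bulk[, 2]),
                      z = c(thin[, 3], bulk[, 3]))
  solids <- rbind(
    data.frame(id = 1L, part = 1L, n1 = 1L, n2 = 2L, n3 = 3L, n4 = 4L,
               n5 = 5L, n6 = 6L, n7 = 7L, n8 = 8L),
    data.frame(id = 2L, part = 2L, n1 = 9L, n2 = 10L, n3 = 11L, n4 = 12L,
               n5 = 13L, n6 = 14L, n7 = 15L, n8 = 16L))
  asm <- hbm_assembly(nodes = nodes, solids = solids,
                      parts = data.frame(id = 1:2,
                                         name = c("fibula", "flesh"),
                                         region = c("leg", "leg"),
                                         material = c("bone", "flesh"),
                                         density = c(2e-6, 1e-6)))
  mat <- data.frame(part = 1:2, E = c(15, 0.001), nu = c(0.3, 0.45),
                    rho = c(2e-6, 1e-6))
  est <- estimate_added_mass(asm, mat, dt_target = 3e-4)
  fib <- est$parts$added_kg[est$parts$part == 1]
  other <- est$parts$added_kg[est$parts$part == 2]
  expect_gt(fib, 0)
  expect_equal(other, 0)
  # per-element closed-form oracle for the fibula element
  c_fib <- sqrt(15 * 0.7 / (1.3 * 0.4 * 2e-6))
  l_fib <- (0.5 * 0.5 * 40) / (0.5 * 40)   # volume / largest face area
  dtc <- l_fib / c_fib
  m_fib <- 0.5 * 0.5 * 40 * 2e-6
  expect_equal(fib, m_fib * ((3e-4 / dtc)^2 - 1), tolerance = 1e-9)
  # monotone non-decreasing in the target timestep
  est2 <- estimate_added_mass(asm, mat, dt_target = 6e-4)
  expect_gte(est2$total_added_kg, est$total_added_kg)
})

test_that("added-mass percentage bookkeeping rounds to two decimals", {
  expect_equal(added_mass_percent(0.12, 62), 0.19)
  expect_equal(added_mass_percent(1, 3), 33.33)
})
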