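test_that("uniform pressure patch test is exact", {
  m <- make_block(E = 100, nu = 0.3)
  m$constraints[m$nodes[, 3] == 0, 3] <- TRUE
  m$constraints[1, 1:2] <- TRUE
  m$constraints[2, 2] <- TRUE
  top <- which(m$nodes[, 3] == 1)
  f <- matrix(0, nrow(m$nodes), 3)
  f[top, 3] <- -0.5 / length(top)
  sol <- solve_static(m, load_case(forces = f))
  expect_equal(unname(sol$stress[1, "szz"]), -0.5, tolerance = 1e-8)
  expect_lt(max(abs(sol$stress[1, c(1, 2, 4, 5, 6)])), 1e-8)
  expect_lt(sol$residual, 1e-8)
})

test_that("uniform eigenstrain growth is stress-free and dilates exactly", {
  m <- pin_rigid_modes(make_block(nx = 2, ny = 2, nz = 2, E = 200, nu = 0.3))
  eig <- matrix(0, nrow(m$hexes), 6)
  eig[, 3] <- 0.01  # 1% vertical growth
  sol <- solve_static(m, load_case(eigenstrain = eig))
  expect_lt(max(abs(sol$stress)), 1e-8)
  top <- which(m$nodes[, 3] == 1)
  expect_equal(unname(sol$u[top, 3]), rep(0.01, length(top)),
               tolerance = 1e-8)
})

test_that("global equilibrium: reactions balance applied forces", {
  m <- make_block(nx = 2, ny = 2, nz = 4, lz = 4)
  m$constraints[m$nodes[, 3] == 0, ] <- TRUE
  set.seed(5)
  f <- matrix(0, nrow(m$nodes), 3)
  free_nodes <- which(m$nodes[, 3] > 0)
  f[free_nodes, ] <- stats::rnorm(3 * length(free_nodes), sd = 0.1)
  sol <- solve_static(m, load_case(forces = f))
  total <- colSums(sol$reactions) + colSums(f)
  expect_lt(max(abs(total)) / max(abs(f)), 1e-8)
})

test_that("cantilever tip deflection matches the beam closed form", {
  # 1 x 1 x 10 mm cantilever; 40 elements along the length keeps the
  # fully integrated trilinear hexes within the coarse-mesh tolerance
  m <- make_block(lz = 10, nz = 40, E = 1000, nu = 0)
  m$constraints[m$nodes[, 3] == 0, ] <- TRUE
  tip <- which(m$nodes[, 3] == 10)
  P <- 0.01
  f <- matrix(0, nrow(m$nodes), 3)
  f[tip, 1] <- P / length(tip)
  sol <- solve_static(m, load_case(forces = f))
  eb <- P * 10^3 / (3 * 1000 * (1 / 12))  # PL^3 / 3EI
  expect_equal(mean(sol$u[tip, 1]), eb, tolerance = 0.2)
})

test_that("singular systems and small-strain violations are caught", {
  m <- make_block()  # completely unconstrained
  f <- matrix(0, nrow(m$nodes), 3); f[1, 1] <- 1
  expect_error(solve_static(m, load_case(forces = f)), "singular|rigid")
  expect_error(load_case(eigenstrain = matrix(0.3, 1, 6)), "small-strain")
})

test_that("tension-only iteration keeps only stretched antagonist springs", {
  m <- make_block(E = 100)
  m$constraints[m$nodes[, 3] == 0, ] <- TRUE
  # two anchored antagonist springs attached to a top corner
  m$nodes <- rbind(m$nodes, c(3, 0, 1), c(-3, 0, 1))
  m$constraints <- rbind(m$constraints, matrix(TRUE, 2, 3))
  top <- which(m$nodes[, 1] == 1 & m$nodes[, 2] == 0 & m$nodes[, 3] == 1)[1]
  m$springs <- data.frame(node_a = c(top, top),
                          node_b = nrow(m$nodes) - c(1, 0),
                          stiffness = 10, tension_only = TRUE,
                          isotropic = FALSE, label = "ligament")
  f <- matrix(0, nrow(m$nodes), 3)
  f[top, 1] <- -0.5  # pull toward -x
  sol <- resolve_tension_only(m, load_case(forces = f))
  # moving toward -x stretches the spring anchored at +3 and slackens -3
  expect_true(sol$active[1])
  expect_false(sol$active[2])

  # all-slack configuration reduces to the pure hex solution
  f2 <- matrix(0, nrow(m$nodes), 3)
  f2[top, 3] <- -0.1
  sol2 <- resolve_tension_only(m, load_case(forces = f2))
  m_nospring <- m
  m_nospring$springs <- m$springs[0, ]
  sol_pure <- solve_static(m_nospring, load_case(forces = f2))
  if (!any(sol2$active)) {
    expect_equal(sol2$u, sol_pure$u, tolerance = 1e-10)
  }

  # converged active set is stable under re-solve
  sol3 <- resolve_tension_only(m, load_case(forces = f * 1.0001))
  expect_equal(sol3$active, sol$active)
})

test_that("two-pass gravity restores geometry and zero weight is inert", {
  tm <- assign_materials(small_template(), default_material_cards(11),
                         patient_profile(11, "F", 0, 37))
  gv0 <- apply_gravity_two_pass(tm, 0)
  expect_lt(max(abs(gv0$stress)), 1e-12)
  expect_lt(max(abs(gv0$unloaded_nodes - tm$nodes)), 1e-12)

  # bilateral springs (no tension-only) -> exact restoration
  tmb <- tm
  tmb$springs$tension_only <- FALSE
  gvb <- apply_gravity_two_pass(tmb, 37)
  expect_lt(gvb$rms_deviation, 1e-6)

  # with tension-only ligaments, the deviation stays small
  gv <- apply_gravity_two_pass(tm, 37)
  expect_lt(gv$rms_deviation, 0.5)
})

test_that("straight symmetric template loads left/right equally", {
  tm <- assign_materials(small_template(), default_material_cards(11),
                         patient_profile(11, "F", 0, 37))
  gv <- apply_gravity_two_pass(tm, 37)
  for (lvl in c("T4", "T8", "L2")) {
    qs <- spinegrowth:::ivd_quadrant_stress_raw(tm, gv$stress, lvl)
    expect_lt(abs(qs[["ant_left"]] - qs[["ant_right"]]), 1e-6)
    expect_lt(abs(qs[["post_left"]] - qs[["post_right"]]), 1e-6)
    # the column is in net compression under gravity
    expect_lt(mean(qs), 0)
  }
  expect_error(spinegrowth:::ivd_quadrant_stress_raw(tm, gv$stress, "L5"),
               "no IVD")
})

test_that("scoliotic model compresses the concave side more", {
  m <- small_patient_model()  # convex left
  gv <- apply_gravity_two_pass(m, 37)
  qs <- spinegrowth:::ivd_quadrant_stress_raw(m, gv$stress, "T8")
  # tension-positive: concave (right) more negative than convex (left)
  expect_lt(qs[["ant_right"]], qs[["ant_left"]])
  rep <- ivd_quadrant_stress(m, gv$stress, "T8", convex_side = "left")
  expect_gt(rep[["ant_concave"]], rep[["ant_convex"]])
  # compression-positive reporting flips the sign
  expect_equal(unname(rep[["ant_convex"]]), -unname(qs[["ant_left"]]))
})
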