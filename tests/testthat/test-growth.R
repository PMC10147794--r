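test_that("beta schedule decays linearly in the Risser sign to zero", {
  expect_equal(beta_from_risser(0), 0.4)
  expect_equal(beta_from_risser(2), 0.24)
  expect_equal(beta_from_risser(5), 0)
  rs <- seq(0, 5, by = 0.5)
  bs <- beta_from_risser(rs)
  expect_true(all(diff(bs) <= 0))
  expect_true(all(bs >= 0))
  expect_error(beta_from_risser(6), "\\[0, 5\\]")
})

test_that("the growth law evaluates and floors correctly", {
  expect_equal(modulated_growth(1.0, 0.4, -0.5, 0), 0.8)
  expect_equal(modulated_growth(2.5, 0.4, 0.7, 0.7), 2.5)   # sigma == sigma_m
  expect_equal(modulated_growth(2.5, 0, -3, 0), 2.5)        # maturity limit
  expect_equal(modulated_growth(1.0, 0.4, -10, 0), 0)       # floored, no resorption
})

test_that("coefficient allocation covers 17 x 13 x 3 = 663 entries", {
  prof <- patient_profile(11, "F", 0, 37)
  co <- allocate_coefficients(baseline_growth_table(prof), prof)
  expect_equal(nrow(co), 663)
  expect_true(all(is.finite(co$alpha)))
  expect_equal(nrow(unique(co[c("level", "region", "direction")])), 663)

  zero <- baseline_growth_table(prof)
  zero$rate <- 0
  expect_true(all(allocate_coefficients(zero, prof)$alpha == 0))

  # missing table entry is reported
  short <- baseline_growth_table(prof)[-1, ]
  expect_error(allocate_coefficients(short, prof), "missing")

  # maturity scales the baseline: Risser 5 grows nothing
  mature <- baseline_growth_table(patient_profile(16, "F", 5, 55))
  expect_true(all(mature$rate == 0))
})

test_that("quadrant modulation touches only vertical body-quadrant entries", {
  prof <- patient_profile(11, "F", 0, 37)
  co <- allocate_coefficients(baseline_growth_table(prof), prof)
  sym <- stats::setNames(rep(list(c(ant_left = -0.2, ant_right = -0.2,
                                    post_left = -0.2, post_right = -0.2)),
                             16), spine_levels()[1:16])
  expect_equal(modulate_quadrants(co, sym, beta = 0.4)$alpha, co$alpha)

  asym <- stats::setNames(rep(list(c(ant_left = -0.1, ant_right = -0.5,
                                     post_left = -0.1, post_right = -0.5)),
                              16), spine_levels()[1:16])
  mod <- modulate_quadrants(co, asym, beta = 0.4)
  # concave (right, more compression) grows slower than convex (left)
  for (lvl in c("T8", "L2")) {
    aL <- mod$alpha[mod$level == lvl & mod$region == "body_ant_left" &
                      mod$direction == "vertical"]
    aR <- mod$alpha[mod$level == lvl & mod$region == "body_ant_right" &
                      mod$direction == "vertical"]
    expect_lt(aR, aL)
  }
  # everything else untouched
  untouched <- !(mod$region %in% body_quadrants() & mod$direction == "vertical")
  expect_equal(mod$alpha[untouched], co$alpha[untouched])
  # beta = 0 (Risser 5) leaves all coefficients unchanged
  expect_equal(modulate_quadrants(co, asym, beta = 0)$alpha, co$alpha)
  expect_error(modulate_quadrants(co, sym[1:3], 0.4), "missing quadrant")
})

test_that("dt = 0 is the identity and symmetric growth stays straight", {
  tm <- assign_materials(small_template(), default_material_cards(11),
                         patient_profile(11, "F", 0, 37))
  prof <- patient_profile(11, "F", 0, 37)
  step0 <- advance_interval(tm, prof, dt = 0)
  expect_identical(step0$model, tm)

  step <- advance_interval(tm, prof, dt = 1)
  # height grows, curvature does not
  h0 <- max(tm$nodes[, 3]) - min(tm$nodes[, 3])
  h1 <- max(step$model$nodes[, 3]) - min(step$model$nodes[, 3])
  expect_gt(h1, h0)
  ci <- measure_indices(mesh_landmarks(step$model))
  expect_lt(ci$thoracic_cobb, 0.5)
})

test_that("simulation is deterministic and emits per-timepoint outputs", {
  pat <- default_patient()
  prof <- patient_profile(11, "F", 0, 37, cas = 46.3, calb = 13.7,
                          timepoints = c(0, 0.5, 1))
  tr1 <- simulate_growth(pat$landmarks, prof, refinement = c(2, 2, 2))
  tr2 <- simulate_growth(pat$landmarks, prof, refinement = c(2, 2, 2))
  expect_identical(tr1$indices, tr2$indices)
  expect_identical(tr1$quadrant_stress, tr2$quadrant_stress)
  expect_equal(nrow(tr1$indices), 3)
  expect_equal(nrow(tr1$quadrant_stress), 12)  # 3 timepoints x 4 quadrants
  expect_true(all(c("thoracic_cobb", "wedge_apex") %in% names(tr1$indices)))

  d <- withr::local_tempdir()
  write_trajectory(tr1, d)
  expect_true(file.exists(file.path(d, "indices.csv")))
  expect_true(file.exists(file.path(d, "quadrant_stress.csv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  got <- utils::read.csv(file.path(d, "indices.csv"))
  expect_equal(got$thoracic_cobb, tr1$indices$thoracic_cobb, tolerance = 1e-9)
})
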