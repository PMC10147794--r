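test_that("default template has the expected structure", {
  tm <- small_template()
  expect_equal(sum(tapply(tm$elem$structure == "vertebra",
                          tm$elem$level, any)), 17)
  expect_equal(length(unique(tm$elem$level[tm$elem$structure == "ivd"])), 16)
  # every body hex carries one of the 4 quadrant labels
  body <- tm$elem[tm$elem$structure == "vertebra", ]
  expect_true(all(body$region %in% body_quadrants()))
  # 17 levels x 4 quadrants = 68 stress-modulatable regions present
  expect_equal(nrow(unique(body[c("level", "region")])), 68)
  # node indices in range
  expect_true(all(tm$hexes >= 1 & tm$hexes <= nrow(tm$nodes)))
})

test_that("IVD-endplate interfaces share nodes (tied contact)", {
  tm <- small_template()
  for (lvl in c("T1", "T8", "L4")) {
    i <- match(lvl, spine_levels())
    lower <- spine_levels()[i + 1]
    ivd <- which(tm$elem$structure == "ivd" & tm$elem$level == lvl)
    ivd_nodes <- unique(as.vector(tm$hexes[ivd, ]))
    expect_true(all(tm$inf_face[[lvl]] %in% ivd_nodes))
    expect_true(all(tm$sup_face[[lower]] %in% ivd_nodes))
    expect_setequal(ivd_nodes, c(tm$inf_face[[lvl]], tm$sup_face[[lower]]))
  }
})

test_that("straight template measures zero curvature and passes quality", {
  tm <- small_template()
  ci <- measure_indices(mesh_landmarks(tm))
  expect_lt(ci$thoracic_cobb, 1e-6)
  expect_lt(ci$kyphosis, 1e-6)
  expect_lt(max(abs(ci$wedging)), 1e-6)
  rep <- mesh_quality(tm)
  ck <- check_quality(rep)
  expect_true(ck$overall)
  expect_true(all(rep$jacobian > 0))
})

test_that("dimension-table validation names the offending level", {
  dims <- default_dimension_table()
  expect_error(build_template(dims[-3, ]), "T3")
  dims2 <- default_dimension_table()
  dims2$height[5] <- -1
  expect_error(build_template(dims2), "positive")
  expect_error(build_template(refinement = c(3, 4, 2)), "even")
})

test_that("mesh quality metrics match closed forms", {
  cube <- make_block()
  q <- mesh_quality(cube)
  expect_equal(q$jacobian, 1, tolerance = 1e-12)
  expect_equal(q$aspect, 1, tolerance = 1e-12)
  expect_equal(q$skewness, 0, tolerance = 1e-9)
  expect_equal(q$warpage, 0, tolerance = 1e-9)
  expect_equal(q$quad_min, 90, tolerance = 1e-9)
  expect_equal(q$quad_max, 90, tolerance = 1e-9)

  tall <- make_block(lz = 2)
  expect_equal(mesh_quality(tall)$aspect, 2, tolerance = 1e-12)

  # 60/120 parallelogram prism: quad angles 60/120, scaled Jacobian sin60.
  # make_block nodes are in structured-grid order (x fastest), not VTK
  # corner order, so the parallelogram rows follow the grid layout.
  sheared <- make_block()
  sheared$nodes <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0), c(1.5, sqrt(3) / 2, 0),
    c(0, 0, 1), c(1, 0, 1), c(0.5, sqrt(3) / 2, 1), c(1.5, sqrt(3) / 2, 1))
  qs <- mesh_quality(sheared)
  expect_equal(qs$quad_min, 60, tolerance = 1e-9)
  expect_equal(qs$quad_max, 120, tolerance = 1e-9)
  expect_equal(qs$jacobian, sin(pi / 3), tolerance = 1e-9)

  # inverted element is reported and keeps a negative Jacobian
  inv <- make_block()
  inv$nodes[c(5, 6, 7, 8), 3] <- -1
  expect_warning(qi <- mesh_quality(inv), "inverted")
  expect_lt(qi$jacobian, 0)
})

test_that("check_quality counts failing fractions", {
  rep <- mesh_quality(make_block())
  rep100 <- rep[rep(1, 100), ]
  rep100$aspect[1] <- 10
  ck <- check_quality(rep100)
  expect_equal(unname(ck$fractions["aspect"]), 0.99)
  expect_true(ck$overall)
  expect_false(check_quality(rep100, floor = 1)$overall)
})

test_that("shipped dimension-table CSV matches the built-in defaults", {
  path <- system.file("extdata", "default_dimensions.csv",
                      package = "spinegrowth")
  dims <- utils::read.csv(path, colClasses = c(level = "character"))
  expect_equal(dims, default_dimension_table(), tolerance = 1e-9)
  expect_s3_class(build_template(dims, refinement = c(2, 2, 2)), "hex_mesh")
})
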