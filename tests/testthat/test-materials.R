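test_that("SFR reproduces the clinical flexibility values", {
  # five (CAS, CALB) pairs spanning Risser 0-4, printed to 2 decimals
  cas <- c(46.3, 50.1, 52.9, 50.8, 52.9)
  calb <- c(13.7, 18.5, 23.2, 26.2, 36.8)
  expect_equal(round(compute_sfr(cas, calb), 2),
               c(0.70, 0.63, 0.56, 0.48, 0.30))
  expect_equal(compute_sfr(40, 40), 0)
  expect_error(compute_sfr(0, 10), "positive")
  expect_warning(compute_sfr(40, 50), "outside")
  expect_equal(suppressWarnings(compute_sfr(40, 50, clamp = TRUE)), 0)
})

test_that("age scaling multiplies the adult value", {
  expect_equal(scale_by_age(material_card("vertebra", 350,
                                          age_scale_factor = 0.95)), 332.5)
  expect_equal(scale_by_age(material_card("ribs", 2100,
                                          age_scale_factor = 0.95)), 1995.0)
  expect_equal(scale_by_age(material_card("ivd", 20,
                                          age_scale_factor = 0.95)), 19.0)
  expect_equal(round(scale_by_age(material_card("costal_cartilage", 10.4,
                                                age_scale_factor = 0.95)), 1),
               9.9)
  expect_equal(scale_by_age(material_card("x", 123, age_scale_factor = 1)), 123)
  expect_error(material_card("x", -1), "positive")
  expect_error(material_card("x", 1, age_scale_factor = 1.5), "0, 1.2")
})

test_that("IVD flexibility scaling follows E(1 - C*SFR) and is monotone", {
  expect_equal(scale_ivd_modulus(19.0, 0.56, 0.3), 19.0 * (1 - 0.3 * 0.56))
  expect_equal(scale_ivd_modulus(19.0, 0, 0.3), 19.0)
  expect_equal(scale_ivd_modulus(19.0, 0.56, 0), 19.0)
  sfrs <- seq(0, 1, by = 0.1)
  vals <- vapply(sfrs, function(s) scale_ivd_modulus(20, s, 0.3), 0)
  expect_true(all(diff(vals) < 0))
  expect_error(scale_ivd_modulus(20, 1, 1), "nonphysical")
})

test_that("assign_materials wires cards into elements and springs", {
  tm <- small_template()
  prof <- patient_profile(16, "M", 2, 60.7, cas = 52.9, calb = 23.2)
  cards <- default_material_cards(16)
  m <- assign_materials(tm, cards, prof)
  vert_E <- unique(m$elem$E[m$elem$structure == "vertebra"])
  ivd_E <- unique(m$elem$E[m$elem$structure == "ivd"])
  expect_length(vert_E, 1)
  expect_equal(vert_E, 350 * default_age_scale(16, "bone"))
  # IVD: age scaling then flexibility scaling
  expect_equal(ivd_E,
               scale_ivd_modulus(20 * default_age_scale(16, "bone"),
                                 prof$sfr, 0.3))
  expect_lt(ivd_E, 20 * default_age_scale(16, "bone"))
  # sfr = 0 leaves the IVD at the age-scaled baseline
  rigid <- patient_profile(16, "M", 2, 60.7, cas = 50, calb = 50)
  m0 <- assign_materials(tm, cards, rigid)
  expect_equal(unique(m0$elem$E[m0$elem$structure == "ivd"]),
               20 * default_age_scale(16, "bone"))
  # SFR isolation: vertebral E identical, IVD E differs
  expect_equal(m0$elem$E[m0$elem$structure == "vertebra"],
               m$elem$E[m$elem$structure == "vertebra"])
  # springs scaled from their base stiffness; idempotent on re-assignment
  lig <- m$springs$label == "ligament"
  expect_equal(m$springs$stiffness[lig],
               m$springs$stiffness0[lig] * default_age_scale(16, "ligament"))
  m2 <- assign_materials(m, cards, prof)
  expect_equal(m2$springs$stiffness, m$springs$stiffness)

  # unmatched structure label errors
  expect_error(assign_materials(tm, cards["ivd"], prof), "material card")
})

test_that("patient profile validates maturity and timepoints", {
  expect_error(patient_profile(11, "F", risser = 6), "\\[0, 5\\]")
  expect_error(patient_profile(11, "F", timepoints = c(0, 0.5, 0.5)),
               "strictly increasing")
  expect_error(patient_profile(11, "F", risser = c(2, 1),
                               timepoints = c(0, 1)), "non-decreasing")
  p <- patient_profile(11, "F", risser = c(0, 2), timepoints = c(0, 2))
  expect_equal(spinegrowth:::risser_at(p, 1), 1)
  expect_equal(spinegrowth:::risser_at(p, 5), 2)  # held beyond documentation
})
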