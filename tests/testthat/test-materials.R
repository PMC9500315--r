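# Density-modulus law and material assignment.

test_that("as-used power law reproduces the tabulated trabecular moduli", {
  tab <- default_region_bmd()
  expected <- c(403.10, 182.75, 589.43, 99.08, 1027.46, 346.62, 914.93,
                636.33, 694.04, 201.13, 527.53, 155.34, 275.07, 30.08,
                352.26, 197.16)
  got <- round(bmd_to_modulus(tab$bmd_mg_cc, density_modulus_law("as_used")), 2)
  expect_equal(got, expected, tolerance = 0.01 / min(expected))
  # spot values
  law <- density_modulus_law("as_used")
  expect_equal(round(bmd_to_modulus(200.4, law), 2), 403.10)
  expect_equal(round(bmd_to_modulus(55.1, law), 2), 30.08)
  expect_equal(round(bmd_to_modulus(319.2, law), 2), 1027.46)
})

test_that("zero density maps to the 0.001 MPa sentinel in both modes", {
  expect_equal(bmd_to_modulus(0, density_modulus_law("as_used")), 0.001)
  expect_equal(bmd_to_modulus(0, density_modulus_law("as_printed")), 0.001)
  expect_error(bmd_to_modulus(-1), class = "cervifem_domain_error")
})

test_that("as-printed piecewise branches evaluate as printed", {
  law <- density_modulus_law("as_printed")
  # branch 1 (below 0.27 g/cc): 2.2 power with the 33900 prefactor
  expect_equal(bmd_to_modulus(55.1, law), 33900 * 0.0551^2.2, tolerance = 1e-12)
  # branch 2 (linear in g/cc)
  expect_equal(bmd_to_modulus(400, law), 5407 * 0.4 + 469, tolerance = 1e-12)
  # branch 3 coincides with the as-used law above 0.60 g/cc
  expect_equal(bmd_to_modulus(700, law),
               bmd_to_modulus(700, density_modulus_law("as_used")),
               tolerance = 1e-12)
})

test_that("both law modes are monotone non-decreasing on random pairs", {
  set.seed(42)
  for (mode in c("as_used", "as_printed")) {
    law <- density_modulus_law(mode)
    b <- sort(runif(200, 0, 900))
    E <- bmd_to_modulus(b, law)
    expect_true(all(diff(E) >= -1e-9), info = mode)
    expect_true(all(E > 0))
  }
})

test_that("modes agree (0.5%) only on the 2.01-power branch", {
  used <- density_modulus_law("as_used")
  printed <- density_modulus_law("as_printed")
  hi <- c(650, 700, 800)
  expect_equal(bmd_to_modulus(hi, printed), bmd_to_modulus(hi, used),
               tolerance = 0.005)
  lo <- c(55.1, 135.2, 200.4, 400)
  rel <- abs(bmd_to_modulus(lo, printed) / bmd_to_modulus(lo, used) - 1)
  expect_true(all(rel > 0.005))
})

test_that("material cards validate their ranges", {
  expect_error(material_card("x", -1, 0.3), class = "cervifem_domain_error")
  expect_error(material_card("x", 100, 0.5), class = "cervifem_domain_error")
  cards <- default_material_cards()
  expect_equal(cards$youngs_modulus[cards$name == "PEEK"], 4000)
  expect_equal(cards$poisson_ratio[cards$name == "PEEK"], 0.35)
  expect_equal(cards$youngs_modulus[cards$name == "NP"], 1.0)
  expect_equal(cards$poisson_ratio[cards$name == "NP"], 0.49)
})

test_that("assign_materials fills every element and errors on gaps", {
  model <- get_coarse_model()
  expect_error(assign_materials(model, bmd = data.frame()),
               class = "cervifem_assembly_error")
  bad <- default_region_bmd()
  bad <- bad[bad$region != "C4_central_body", ]
  expect_error(assign_materials(model, bad), class = "cervifem_assembly_error",
               regexp = "C4_central_body")
  model <- assign_materials(model)
  expect_false(anyNA(model$E))
  expect_false(anyNA(model$nu))
  # C4 central set carries the mapped modulus
  ids <- model$mesh$elsets[["C4_central_body"]]
  expect_equal(unique(model$E[ids]), 10200 * 0.3192^2.01)
  # PEEK spacers and titanium instruments
  expect_equal(unique(model$E[model$mesh$elsets[["spacer_C2C3"]]]), 4000)
  expect_equal(unique(model$E[model$mesh$elsets[["plate"]]]), 110000)
  # ligament trusses keep their constants
  expect_equal(unique(model$E[model$mesh$elsets[["lig_PLL"]]]), 70)
  expect_equal(unique(model$area[model$mesh$elsets[["lig_ALL"]]]), 38)
})
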