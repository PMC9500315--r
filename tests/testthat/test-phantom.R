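# Synthetic phantom generation: vertebrae, discs, ligaments, instruments,
# assembly contracts.

test_that("cortical wedge layer has the level-appropriate thickness", {
  spec <- coarse_spec()
  v <- generate_vertebra(spec, "C3")
  th <- cortical_thickness_measured(v, n = 100)
  expect_true(all(abs(th - 0.28) <= 0.01 * 0.28))
  vt <- generate_vertebra(spec, "T1")
  tht <- cortical_thickness_measured(vt, n = 100)
  expect_true(all(abs(tht - 0.24) <= 0.01 * 0.24))
})

test_that("degenerate or unresolvable vertebra specs are rejected", {
  expect_error(phantom_spec(body_height = 0), class = "cervifem_spec_error")
  expect_error(phantom_spec(mesh_size = -1), class = "cervifem_spec_error")
  spec <- phantom_spec(mesh_size = 9) # coarser than the smallest half-axis
  expect_error(generate_vertebra(spec, "C3"),
               class = "cervifem_resolution_error", regexp = "mesh_size")
})

test_that("trabecular volume converges to the analytic elliptic cylinder", {
  spec <- phantom_spec(body_width = 16, body_depth = 12, body_height = 10,
                       mesh_size = 0.8)
  v <- generate_vertebra(spec, "C4")
  vol <- element_volumes(v)
  trab <- sum(vol[c(v$elsets$central_body, v$elsets$exterior_body)])
  expect_lt(abs(trab / (pi * 8 * 6 * 10) - 1), 0.02)
})

test_that("disc NP shares stay inside the anatomical bands", {
  spec <- phantom_spec()
  d <- generate_disc(spec, "C5-C6")
  sh <- disc_np_shares(d)
  expect_gte(sh$volume_share, 0.40)
  expect_lte(sh$volume_share, 0.50)
  expect_gte(sh$area_share, 0.25)
  expect_lte(sh$area_share, 0.50)
  # requested area fraction is recovered on a coarse mesh
  s2 <- phantom_spec(np_area_fraction = 0.25, np_volume_fraction = 0.40,
                     mesh_size = 2.5)
  sh2 <- disc_np_shares(generate_disc(s2, "C5-C6"))
  expect_lt(abs(sh2$area_share - 0.25), 0.03)
  # out-of-band requests are specification errors
  expect_error(phantom_spec(np_volume_fraction = 0.60),
               class = "cervifem_spec_error")
  expect_error(phantom_spec(np_area_fraction = 0.20),
               class = "cervifem_spec_error")
})

test_that("ligament census matches resection: 6 groups at C5-C6, 5 at C3-C4", {
  model <- get_coarse_model()
  expect_setequal(ligament_groups_at(model, "C5-C6"),
                  c("ALL", "PLL", "ISL", "SSL", "ITL", "LF"))
  expect_setequal(ligament_groups_at(model, "C3-C4"),
                  c("PLL", "ISL", "SSL", "ITL", "LF"))
  # ALL trusses carry the tabulated cross-section
  expect_equal(unique(model$area[model$mesh$elsets$lig_ALL]), 38)
  # paired groups have two units per junction
  expect_length(model$mesh$elsets[["lig_ITL_C5-C6"]], 2L)
  expect_length(model$mesh$elsets[["lig_LF_C6-C7"]], 2L)
  expect_length(model$mesh$elsets[["lig_PLL_C5-C6"]], 1L)
})

test_that("instrument construct: 8 screws, 3 spacers, 1 plate, trajectories", {
  model <- get_coarse_model()
  es <- names(model$mesh$elsets)
  expect_length(grep("^screw_C[0-9]_(left|right)$", es), 8L)
  expect_length(grep("^screw_core_", es), 8L) # carved drill holes
  expect_length(grep("^spacer_C[0-9]", es), 3L)
  expect_true("plate" %in% es)
  expect_length(grep("^trajectory_", es), 8L)
  expect_true(all(vapply(grep("^trajectory_", es, value = TRUE),
                         function(s) length(model$mesh$elsets[[s]]) > 0,
                         logical(1))))
  # spacer at C4-C5 fills a 7 mm space (height echo)
  sp <- model$mesh$elsets[["spacer_C4C5"]]
  nodes <- cervifem:::elset_nodes(model$mesh, sp)
  expect_equal(diff(range(model$mesh$nodes[nodes, 3])), 7, tolerance = 1e-9)
  # screws exceeding the body depth are a geometry error
  expect_error(assemble_spine(coarse_spec(),
                              instrument_spec(screw_length = 30)),
               class = "cervifem_geometry_error")
})

test_that("plate standoff is echoed by the measured plate-to-cortex gap", {
  spec <- coarse_spec()
  m <- assemble_spine(spec, instrument_spec(plate_standoff = 1.0),
                      order = "linear")
  g <- plate_gap(m, "C3")
  expect_equal(g, 1.0, tolerance = 0.25) # up to surface discretization
})

test_that("assembly defines contacts, base and coupling deterministically", {
  model <- get_coarse_model()
  expect_setequal(names(model$contacts), c("C5-C6", "C6-C7", "C7-T1", "T1-T2"))
  expect_true(all(vapply(model$contacts, function(cp) cp$mu == 0.07,
                         logical(1))))
  expect_true(length(model$mesh$nsets$base) > 0)
  expect_true("head" %in% names(model$couplings))
  # every set the downstream modules need exists
  need <- c(paste0(c("C2", "C5", "T2"), "_central_body"),
            paste0(c("C2", "C5", "T2"), "_exterior_body"),
            "trajectory_C2_left", "trajectory_C5_right",
            "spacer_endplate_C2C3_upper")
  expect_true(all(need %in% names(model$mesh$elsets)))
  expect_true(all(c("C2_odontoid_facet_left", "C2_odontoid_facet_right",
                    "C2_spinous_process") %in% names(model$mesh$nsets)))
  # determinism: same spec twice gives bit-identical nodes and sets
  m2 <- assemble_spine(coarse_spec(), order = "linear")
  expect_identical(m2$mesh$nodes, model$mesh$nodes)
  expect_identical(m2$mesh$elsets, model$mesh$elsets)
  f1 <- tempfile(fileext = ".vtu"); f2 <- tempfile(fileext = ".vtu")
  write_model(model$mesh, f1); write_model(m2$mesh, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("mesh quality inspection reports per-block gate percentages", {
  spec <- coarse_spec()
  v <- generate_vertebra(spec, "C5")
  q <- mesh_quality(v)
  expect_true(all(c("pct_jacobian_fail", "pct_skew_fail",
                    "pct_collapse_fail") %in% names(q)))
  expect_true(all(q$pct_collapse_fail >= 0 & q$pct_collapse_fail <= 100))
})
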