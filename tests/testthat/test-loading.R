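# Head-weight and isometric-strength load construction.

test_that("head weight force reproduces the reference 30.7 N and scales linearly", {
  expect_equal(head_weight_force(body_params()), 30.7, tolerance = 1e-3)
  b2 <- body_params(body_mass = 2 * 39.97)
  expect_equal(head_weight_force(b2), 2 * head_weight_force(body_params()))
  expect_error(body_params(body_mass = 0), class = "cervifem_domain_error")
  expect_error(body_params(head_mass_fraction = 0),
               class = "cervifem_domain_error")
})

test_that("motion torques reproduce the printed table within 1 N*mm", {
  tq <- motion_torque_table()
  expect_equal(unname(tq["flexion"]), 1308, tolerance = 1 / 1308)
  expect_equal(unname(tq["extension"]), 2138, tolerance = 1 / 2138)
  expect_equal(unname(tq["lateral_flexion"]), 1696, tolerance = 1 / 1696)
  expect_equal(unname(tq["rotation"]), 651, tolerance = 1 / 651)
  hm <- 30.7 / 9.81
  expect_equal(motion_torque(542, hm), 1696)
  expect_equal(motion_torque(208, hm), 651)
  expect_equal(motion_torque(0, hm), 0)
})

test_that("load cases split gravity, share it across motions, and sign the axis", {
  model <- get_coarse_model()
  cases <- lapply(c("flexion", "extension", "lateral_flexion", "rotation"),
                  function(m) build_load_case(model, m))
  names(cases) <- c("flexion", "extension", "lateral_flexion", "rotation")
  for (lc in cases) {
    # total applied nodal force is (0, 0, -HW)
    expect_equal(sum(lc$forces$value[lc$forces$dof == 3]), -30.7,
                 tolerance = 1e-3)
    expect_true(all(lc$forces$dof == 3))
    expect_equal(lc$gravity_force, cases$flexion$gravity_force)
  }
  # equal split between left and right facet patches
  left <- model$mesh$nsets[["C2_odontoid_facet_left"]]
  fl <- cases$flexion$forces
  expect_equal(sum(fl$value[fl$node %in% left]), -30.7 / 2, tolerance = 1e-3)
  # flexion and extension share the axis with opposite signs
  expect_equal(cases$flexion$torque, -cases$extension$torque *
                 (1308 / 2138), tolerance = 1e-9)
  expect_equal(which(cases$lateral_flexion$torque != 0), 2L)
  expect_equal(which(cases$rotation$torque != 0), 3L)
  expect_equal(cases$extension$torque_magnitude, 2138, tolerance = 1e-9)
})

test_that("coupling reduction transmits the prescribed moment", {
  # the reduced load vector puts the torque on the reference rotation DOFs,
  # so the net moment about the reference point equals the prescription
  model <- get_coarse_model()
  lc <- build_load_case(model, "rotation")
  red <- cervifem:::build_reduction(model)
  f <- cervifem:::load_vector(model, red, lc)
  ci <- match("head", names(model$couplings))
  rot_dofs <- red$coup_start[ci] + 4:6
  expect_equal(f[rot_dofs], lc$torque)
})
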