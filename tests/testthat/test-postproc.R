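# Principal strains, damage index, ROM extraction, trajectory summaries and
# the safety verdict.

test_that("principal strains: closed-form cases and rotation invariance", {
  # isotropic tensor
  iso <- principal_strains(matrix(c(0.01, 0.01, 0.01, 0, 0, 0), 1))
  expect_equal(as.vector(iso), rep(0.01, 3))
  # pure shear, engineering gamma: principals (+g/2, 0, -g/2)
  g <- 0.004
  sh <- principal_strains(matrix(c(0, 0, 0, g, 0, 0), 1))
  expect_equal(as.vector(sh), c(g / 2, 0, -g / 2), tolerance = 1e-14)
  # extreme C2 extension strains: principals recover the diagonal
  tens <- principal_strains(diag(c(0.0147, 0, -0.0167)))
  expect_equal(unname(tens[1, "e1"]), 0.0147)
  expect_equal(unname(tens[1, "e3"]), -0.0167)
  # invariance under random rotations; trace preserved
  set.seed(11)
  for (k in 1:20) {
    S <- matrix(rnorm(9, sd = 0.01), 3); S <- (S + t(S)) / 2
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    S6 <- function(M) matrix(c(M[1, 1], M[2, 2], M[3, 3], 2 * M[1, 2],
                               2 * M[2, 3], 2 * M[1, 3]), 1)
    p1 <- principal_strains(S6(S))
    p2 <- principal_strains(S6(q %*% S %*% t(q)))
    expect_equal(p1, p2, tolerance = 1e-10)
    expect_equal(sum(p1), sum(diag(S)), tolerance = 1e-12)
    expect_true(all(diff(as.vector(p1)) <= 1e-14))
  }
  expect_error(principal_strains(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)),
               class = "cervifem_domain_error")
})

test_that("damage index reproduces the worked extension example and bounds", {
  th <- damage_thresholds()
  expect_equal(th$tension_limit, 0.015)
  expect_equal(th$compression_limit, -0.020)
  di <- damage_index(c(0.0147, -0.0167), th)
  expect_equal(di, 0.98, tolerance = 1e-12)
  expect_lt(di, 1) # below the safety threshold: not broken
  # threshold boundary cases are exactly 1
  expect_equal(damage_index(c(0.015, 0), th), 1.0)
  expect_equal(damage_index(c(0, -0.020), th), 1.0)
  # sign handling: strains of the wrong sign contribute nothing
  expect_equal(damage_index(c(-0.01, 0.005), th), 0)
  expect_error(damage_thresholds(tension_limit = -1),
               class = "cervifem_domain_error")
})

test_that("damage index is non-negative, zero only at zero, monotone", {
  th <- damage_thresholds()
  set.seed(5)
  e1 <- sort(runif(50, 0, 0.03)); e3 <- sort(runif(50, -0.04, 0))
  di <- damage_index(cbind(e1, 0, rev(e3)), th)
  expect_true(all(di >= 0))
  expect_equal(damage_index(c(0, 0), th), 0)
  # weakly increasing in |e1| with e3 fixed
  di1 <- damage_index(cbind(e1, 0, -0.001), th)
  expect_true(all(diff(di1) >= 0))
  di3 <- damage_index(cbind(0.001, 0, e3), th)
  expect_true(all(diff(di3) <= 0)) # e3 rising toward 0 lowers the ratio
  # tightening thresholds can only raise Di (verdict monotonicity)
  tight <- damage_thresholds(0.005, -0.005)
  expect_true(all(damage_index(cbind(e1, 0, e3), tight) >=
                    damage_index(cbind(e1, 0, e3), th)))
})

test_that("segment ROM recovers an imposed rigid rotation and is antisymmetric", {
  model <- mini_segment_model()
  # impose a rigid 5-degree rotation about x on the upper vertebra
  th5 <- 5 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th5), -sin(th5)), c(0, sin(th5), cos(th5)))
  upper_nodes <- sort(unique(unlist(model$mesh$nsets[
    paste0("U_", c("endplate_sup", "endplate_inf", "spinous_process"))])))
  disp <- matrix(0, nrow(model$mesh$nodes), 3)
  ctr <- colMeans(model$mesh$nodes[upper_nodes, ])
  disp[upper_nodes, ] <- sweep(model$mesh$nodes[upper_nodes, ], 2, ctr) %*%
    t(R) - sweep(model$mesh$nodes[upper_nodes, ], 2, ctr)
  fake <- list(displacements = disp)
  expect_equal(segment_rom(fake, model, "U-L", "extension"), 5,
               tolerance = 1e-6)
  # zero displacement gives zero ROM
  expect_equal(segment_rom(list(displacements = disp * 0), model, "U-L",
                           "extension"), 0)
  # linearity/antisymmetry on the solved contact-free fixture; torques are
  # kept small so the finite-rotation extraction stays in its linear range
  r1 <- solve_mini_segment(model, 0.02)
  r2 <- solve_mini_segment(model, 0.04)
  rn <- solve_mini_segment(model, -0.02)
  a1 <- segment_rom(r1, model, "U-L", "extension")
  expect_gt(abs(a1), 1e-4)
  expect_equal(segment_rom(r2, model, "U-L", "extension"), 2 * a1,
               tolerance = 1e-6)
  expect_equal(segment_rom(rn, model, "U-L", "extension"), -a1,
               tolerance = 1e-6)
})

test_that("trajectory report localizes the seeded extreme element", {
  model <- mini_segment_model()
  ne <- mesh_nelem(model$mesh)
  model$mesh$elsets[["trajectory_U_left"]] <- 1:8
  model$mesh$elsets[["trajectory_U_right"]] <- 9:16
  strain <- matrix(0, ne, 6)
  strain[5, ] <- c(0.02, 0, 0, 0, 0, 0)   # seeded tension extreme
  strain[12, ] <- c(0, 0, -0.03, 0, 0, 0) # seeded compression extreme
  rep <- trajectory_report(list(strain = strain), model)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$elem_at_max[rep$trajectory == "U_left"], 5L)
  expect_equal(rep$elem_at_max[rep$trajectory == "U_right"], 12L)
  expect_equal(rep$max_e1[rep$trajectory == "U_left"], 0.02)
  expect_equal(rep$min_e3[rep$trajectory == "U_right"], -0.03)
  # all-zero strain gives zero extremes
  rep0 <- trajectory_report(list(strain = matrix(0, ne, 6)), model)
  expect_true(all(rep0$max_di == 0))
})

test_that("safety verdict passes below one, fails above, and is threshold-monotone", {
  model <- mini_segment_model()
  model$mesh$elsets[["U_central_body"]] <- 1:10
  model$mesh$elsets[["trajectory_U_left"]] <- 11:16
  ne <- mesh_nelem(model$mesh)
  strain <- matrix(0, ne, 6)
  strain[3, 1] <- 0.0147 # Di = 0.98 under default thresholds
  mk_reports <- function(th) {
    sets <- c("U_central_body", "trajectory_U_left")
    rs <- lapply(cervifem:::MOTIONS, function(m)
      damage_report(list(strain = strain, load_case = list(motion = m)),
                    model, th, sets = sets))
    names(rs) <- cervifem:::MOTIONS
    rs
  }
  v <- safety_verdict(mk_reports(damage_thresholds()))
  expect_true(v$pass)
  expect_equal(v$max_di, 0.98, tolerance = 1e-12)
  # tightened thresholds flip the verdict on the same strains
  v2 <- safety_verdict(mk_reports(damage_thresholds(0.005, -0.005)))
  expect_false(v2$pass)
  expect_true("U_central_body" %in% v2$offenders$set)
  # missing motions are an error
  expect_error(safety_verdict(mk_reports(damage_thresholds())[1:3]),
               class = "cervifem_spec_error")
})
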