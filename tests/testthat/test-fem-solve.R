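# Solver-level behaviour: constraint reduction, oracles, tension-only
# trusses, penalty contact, energy consistency.

test_that("solver matches the dense brute-force oracle on a small tet4 mesh", {
  mesh <- bar_mesh(L = 4, W = 1, H = 1, nx = 4, ny = 1, nz = 1) # 60 DOFs
  model <- bar_model(mesh, E = 800, nu = 0.3)
  left <- which(mesh$nodes[, 1] == 0)
  right <- which(mesh$nodes[, 1] == 4)
  model <- fix_nodes(model, left)
  lc <- custom_case(data.frame(node = right, dof = 3L,
                               value = -2 / length(right)))
  res <- solve_static(model, lc)
  fixed_dofs <- as.vector(t(outer(3 * (left - 1), 1:3, "+")))
  u_oracle <- oracle_dense_solve(mesh$nodes, mesh$blocks[[1]]$conn,
                                 E = 800, nu = 0.3, fixed_dofs,
                                 data.frame(dof = 3 * (right - 1) + 3,
                                            value = -2 / length(right)))
  expect_lt(max(abs(res$u - u_oracle)) / max(abs(u_oracle)), 1e-8)
  # fixed DOFs stay at zero; energy balance holds
  expect_equal(max(abs(res$u[fixed_dofs])), 0)
  expect_lt(res$energy$rel_gap, 1e-6)
})

test_that("patch test through the solve path is exact", {
  mesh <- bar_mesh(L = 2, W = 2, H = 2, nx = 2, ny = 2, nz = 2,
                   kind = "tet10")
  model <- bar_model(mesh, E = 900, nu = 0.25)
  X <- mesh$nodes
  A <- matrix(c(1e-3, 4e-4, -2e-4,
                2e-4, -8e-4, 5e-4,
                -3e-4, 1e-4, 6e-4), 3, byrow = TRUE)
  U <- X %*% t(A)
  on_face <- X[, 1] %in% c(0, 2) | X[, 2] %in% c(0, 2) | X[, 3] %in% c(0, 2)
  bnd <- which(on_face)
  model$fixed <- data.frame(node = rep(bnd, each = 3),
                            dof = rep(1:3, length(bnd)),
                            value = as.vector(t(U[bnd, ])))
  res <- solve_static(model, custom_case())
  S <- (A + t(A)) / 2
  expected <- c(S[1, 1], S[2, 2], S[3, 3], 2 * S[1, 2], 2 * S[2, 3],
                2 * S[1, 3])
  err <- sweep(res$strain, 2, expected)
  expect_lt(max(abs(err)), 1e-10)
  # interior displacement reproduces the linear field
  expect_equal(res$displacements, U, tolerance = 1e-10)
})

test_that("cantilever tip deflection is within 8% of beam theory", {
  # 1 x 1 x 10 mm block, E = 1000, nu = 0: F L^3 / (3 E I), I = 1/12
  mesh <- bar_mesh(L = 10, W = 1, H = 1, nx = 10, ny = 2, nz = 2,
                   kind = "tet10")
  model <- bar_model(mesh, E = 1000, nu = 0.0)
  left <- which(mesh$nodes[, 1] == 0)
  right <- which(mesh$nodes[, 1] == 10)
  model <- fix_nodes(model, left)
  Ftot <- -0.5
  lc <- custom_case(data.frame(node = right, dof = 3L,
                               value = Ftot / length(right)))
  res <- solve_static(model, lc)
  tip <- mean(res$displacements[right, 3])
  ref <- Ftot * 10^3 / (3 * 1000 * (1 / 12))
  expect_lt(abs(tip / ref - 1), 0.08)
})

test_that("mesh refinement reduces the beam-fixture error monotonically", {
  deflect <- function(nx) {
    mesh <- bar_mesh(L = 10, W = 1, H = 1, nx = nx, ny = 1, nz = 1,
                     kind = "tet10")
    model <- bar_model(mesh, E = 1000, nu = 0.0)
    left <- which(mesh$nodes[, 1] == 0)
    right <- which(mesh$nodes[, 1] == 10)
    model <- fix_nodes(model, left)
    res <- solve_static(model, custom_case(
      data.frame(node = right, dof = 3L, value = -0.5 / length(right))))
    mean(res$displacements[right, 3])
  }
  ref <- deflect(20)
  errs <- abs(vapply(c(2, 4, 8), deflect, numeric(1)) - ref)
  expect_true(all(diff(errs) < 0))
})

test_that("tied coincident nodes move together; single truss obeys FL/EA", {
  # two collinear bars with duplicated interface nodes, tied
  m1 <- bar_mesh(L = 2, nx = 2, ny = 1, nz = 1)
  m2 <- bar_mesh(L = 2, nx = 2, ny = 1, nz = 1)
  m2$nodes[, 1] <- m2$nodes[, 1] + 2
  n1 <- nrow(m1$nodes)
  nodes <- rbind(m1$nodes, m2$nodes)
  blocks <- list(m1$blocks[[1]],
                 list(kind = "tet4", conn = m2$blocks[[1]]$conn + n1))
  mesh <- fe_mesh(nodes, blocks)
  iface1 <- which(nodes[, 1] == 2 & seq_len(nrow(nodes)) <= n1)
  iface2 <- which(nodes[, 1] == 2 & seq_len(nrow(nodes)) > n1)
  nn <- cervifem:::nearest_node(nodes[iface1, , drop = FALSE],
                                nodes[iface2, , drop = FALSE])
  model <- bar_model(mesh, E = 500, nu = 0.2)
  model$ties <- cbind(iface2, iface1[nn$index])
  left <- which(nodes[, 1] == 0)
  right <- which(nodes[, 1] == 4)
  model <- fix_nodes(model, left)
  res <- solve_static(model, custom_case(
    data.frame(node = right, dof = 1L, value = 1 / length(right))))
  expect_equal(res$displacements[iface1, ], res$displacements[iface2, ],
               tolerance = 1e-12)

  # single truss: tip displacement F L / (E A)
  tn <- rbind(c(0, 0, 0), c(0, 0, 12))
  tmesh <- fe_mesh(tn, list(list(kind = "truss2",
                                 conn = matrix(1:2, 1))))
  tmodel <- spine_model(tmesh)
  tmodel$E <- 20; tmodel$nu <- 0.3; tmodel$area <- 38
  tmodel <- fix_nodes(tmodel, 1L)
  tmodel <- fix_nodes(tmodel, 2L, dofs = 1:2) # keep the axial DOF only
  res <- solve_static(tmodel, custom_case(
    data.frame(node = 2L, dof = 3L, value = 5)))
  expect_equal(res$displacements[2, 3], 5 * 12 / (20 * 38), tolerance = 1e-12)
  expect_equal(res$truss$strain, 5 / (20 * 38), tolerance = 1e-12)
})

test_that("compressed tension-only members carry zero force", {
  # A and B anchor an apex C; a vertical hanger D-C keeps C stable when the
  # oblique members go slack under a downward load
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0), c(1, 3, 0))
  conn <- rbind(c(1L, 3L), c(2L, 3L), c(4L, 3L))
  mesh <- fe_mesh(nodes, list(list(kind = "truss2", conn = conn)))
  model <- spine_model(mesh)
  model$E <- rep(50, 3); model$nu <- rep(0.3, 3); model$area <- rep(10, 3)
  model$tension_only <- rep(TRUE, 3)
  model <- fix_nodes(model, c(1L, 2L, 4L))
  model <- fix_nodes(model, 3L, dofs = c(1L, 3L))
  res <- solve_static(model, custom_case(
    data.frame(node = 3L, dof = 2L, value = -1)))
  expect_false(res$truss$active[1])
  expect_false(res$truss$active[2])
  expect_equal(res$truss$force[1:2], c(0, 0))
  expect_gte(res$truss$force[3], 1) # the hanger carries the load in tension
  # loading upward re-engages the oblique members
  res2 <- solve_static(model, custom_case(
    data.frame(node = 3L, dof = 2L, value = 1)))
  expect_true(all(res2$truss$force >= -1e-9))
})

test_that("zero load gives zero displacement and strain", {
  mesh <- bar_mesh(L = 3, nx = 3)
  model <- bar_model(mesh)
  model <- fix_nodes(model, which(mesh$nodes[, 1] == 0))
  res <- solve_static(model, custom_case())
  expect_equal(max(abs(res$u)), 0)
  expect_equal(max(abs(res$strain), na.rm = TRUE), 0)
})

test_that("kinematic coupling drives its node set rigidly", {
  mesh <- bar_mesh(L = 6, W = 2, H = 2, nx = 6, ny = 2, nz = 2)
  model <- bar_model(mesh, E = 200, nu = 0.3)
  left <- which(mesh$nodes[, 1] == 0)
  right <- which(mesh$nodes[, 1] == 6)
  model <- fix_nodes(model, left)
  ref <- colMeans(mesh$nodes[right, , drop = FALSE])
  model$couplings[["tip"]] <- list(ref = ref, nodes = right)
  lc <- structure(list(motion = "custom",
                       forces = data.frame(node = integer(0), dof = integer(0),
                                           value = numeric(0)),
                       coupling = "tip", torque = c(0, 0, 40),
                       fixed_nset = NULL), class = "load_case")
  res <- solve_static(model, lc)
  # coupled nodes satisfy u = u_ref + theta x r exactly
  nref <- 3 * nrow(mesh$nodes)
  uref <- res$u[nref + 1:3]; th <- res$u[nref + 4:6]
  for (n in right) {
    r <- mesh$nodes[n, ] - ref
    expect_equal(res$displacements[n, ],
                 uref + c(th[2] * r[3] - th[3] * r[2],
                          th[3] * r[1] - th[1] * r[3],
                          th[1] * r[2] - th[2] * r[1]),
                 tolerance = 1e-12)
  }
  expect_gt(th[3], 0) # positive twist under positive moment
})

test_that("penalty contact transmits load without penetration and can slip", {
  # lower block fixed at its base; upper block hovers 0.05 mm above and is
  # stabilized by very soft hanger trusses so the contact state is free to
  # switch
  lower <- bar_mesh(L = 2, W = 2, H = 1, nx = 2, ny = 2, nz = 1)
  upper <- bar_mesh(L = 2, W = 2, H = 1, nx = 2, ny = 2, nz = 1)
  upper$nodes[, 3] <- upper$nodes[, 3] + 1.05
  n1 <- nrow(lower$nodes)
  nodes <- rbind(lower$nodes, upper$nodes)
  anchor <- nrow(nodes) + 1L
  nodes <- rbind(nodes, c(1, 1, 5))
  up_top <- n1 + which(upper$nodes[, 3] == max(upper$nodes[, 3]))
  truss_conn <- cbind(rep(anchor, length(up_top)), up_top)
  blocks <- list(lower$blocks[[1]],
                 list(kind = "tet4", conn = upper$blocks[[1]]$conn + n1),
                 list(kind = "truss2", conn = truss_conn))
  lowf <- cervifem:::boundary_faces_tet(lower$blocks[[1]]$conn)
  ztop <- abs(nodes[lowf$n1, 3] - 1) < 1e-9 & abs(nodes[lowf$n2, 3] - 1) < 1e-9 &
    abs(nodes[lowf$n3, 3] - 1) < 1e-9
  nelem_low <- nrow(lower$blocks[[1]]$conn)
  mesh <- fe_mesh(nodes, blocks,
                  nsets = list(slave = n1 + which(upper$nodes[, 3] == 1.05)),
                  surfaces = list(master = data.frame(
                    elem = lowf$elem[ztop], face = lowf$face[ztop])))
  model <- spine_model(mesh)
  ne <- mesh_nelem(mesh)
  ntr <- nrow(truss_conn)
  model$E <- c(rep(500, ne - ntr), rep(1e-4, ntr))
  model$nu <- rep(0.3, ne)
  model$area <- c(rep(NA, ne - ntr), rep(1, ntr))
  model$contacts[["pad"]] <- list(name = "pad", master_surface = "master",
                                  slave_nset = "slave", mu = 0.07)
  model <- fix_nodes(model, which(nodes[, 3] == 0))
  model <- fix_nodes(model, anchor)
  press <- data.frame(node = up_top, dof = 3L, value = -2 / length(up_top))
  res <- solve_static(model, custom_case(press))
  expect_true(any(res$contact$active))
  # no penetration beyond tolerance, total normal force carries the load
  expect_lt(max(-res$contact$gap), 1e-3)
  expect_equal(sum(res$contact$normal_force), 2, tolerance = 0.05)
  # a small tangential load stays in the micro-slip regime: part of the
  # pad sticks and slips remain tiny
  shear <- rbind(press, data.frame(node = up_top, dof = 1L,
                                   value = 0.05 / length(up_top)))
  res2 <- solve_static(model, custom_case(shear))
  expect_true(any(res2$contact$active))
  expect_true(any(res2$contact$active & !res2$contact$slipping))
  expect_lt(max(res2$contact$slip), 0.01)
  # a tangential load above mu N makes nodes slip
  shear2 <- rbind(press, data.frame(node = up_top, dof = 1L,
                                    value = 0.5 / length(up_top)))
  res3 <- solve_static(model, custom_case(shear2))
  expect_true(any(res3$contact$slipping))
  expect_gt(max(res3$contact$slip), max(res2$contact$slip))
})
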