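# Element-level stiffness and strain kernels.

test_that("tet4 stiffness matches the hand-assembled B-matrix oracle", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  K <- element_stiffness_solid(coords, E = 1, nu = 0, kind = "tet4")
  K_oracle <- oracle_tet4_stiffness(coords, E = 1, nu = 0)
  expect_equal(K, K_oracle, tolerance = 1e-12)
  # a skewed tet with realistic constants
  set.seed(7)
  c2 <- coords + matrix(runif(12, -0.2, 0.2), 4)
  expect_equal(element_stiffness_solid(c2, 1200, 0.3, "tet4"),
               oracle_tet4_stiffness(c2, 1200, 0.3), tolerance = 1e-10)
})

test_that("solid stiffness has the rigid-body null space and symmetry", {
  kinds <- list(
    tet4 = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    tet10 = single_tet10(),
    wedge6 = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)))
  w6 <- kinds$wedge6
  kinds$wedge15 <- rbind(w6,
                         (w6[1, ] + w6[2, ]) / 2, (w6[2, ] + w6[3, ]) / 2,
                         (w6[3, ] + w6[1, ]) / 2, (w6[4, ] + w6[5, ]) / 2,
                         (w6[5, ] + w6[6, ]) / 2, (w6[6, ] + w6[4, ]) / 2,
                         (w6[1, ] + w6[4, ]) / 2, (w6[2, ] + w6[5, ]) / 2,
                         (w6[3, ] + w6[6, ]) / 2)
  for (kind in names(kinds)) {
    X <- kinds[[kind]]
    K <- element_stiffness_solid(X, 1000, 0.3, kind)
    expect_lt(max(abs(K - t(K))), 1e-9 * max(abs(K)))
    # translations and small rotations produce no force
    for (d in 1:3) {
      tr <- rep(diag(3)[d, ], nrow(X))
      expect_lt(max(abs(K %*% tr)), 1e-9 * max(abs(K)))
    }
    rot <- as.vector(t(cbind(-X[, 2], X[, 1], 0)))
    expect_lt(max(abs(K %*% rot)), 1e-9 * max(abs(K)))
    # exactly six zero-energy modes (no hourglassing)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L, info = kind)
  }
})

test_that("tet10 single-element patch: linear field gives exact constant strain", {
  X <- single_tet10()
  A <- matrix(c(2e-3, 1e-3, -4e-4,
                5e-4, -2e-3, 1e-3,
                -1e-3, 3e-4, 1.5e-3), 3, byrow = TRUE)
  u <- X %*% t(A)
  mesh <- fe_mesh(X, list(list(kind = "tet10",
                               conn = matrix(1:10, 1))))
  model <- bar_model(mesh, E = 500, nu = 0.25)
  res <- list(u = as.vector(t(u)))
  eps <- compute_element_strain(res, model)
  S <- (A + t(A)) / 2
  expected <- c(S[1, 1], S[2, 2], S[3, 3], 2 * S[1, 2], 2 * S[2, 3],
                2 * S[1, 3])
  expect_equal(as.vector(eps[1, ]), expected, tolerance = 1e-12)
})

test_that("truss stiffness is EA/L along the axis and frame-objective", {
  # tabulated ligament constants as closed-form checks
  coords <- rbind(c(0, 0, 0), c(10, 0, 0))
  K <- element_stiffness_truss(coords, E = 20, A = 38)
  expect_equal(K[1, 1], 20 * 38 / 10) # 76 N/mm axial
  coords2 <- rbind(c(0, 0, 0), c(20, 0, 0))
  expect_equal(element_stiffness_truss(coords2, 70, 20)[1, 1], 70) # PLL
  # rotating the element rotates K by the same rotation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Kr <- element_stiffness_truss(coords %*% t(R), 20, 38)
  B <- kronecker(diag(2), R)
  expect_equal(Kr, B %*% K %*% t(B), tolerance = 1e-12)
  expect_error(element_stiffness_truss(rbind(c(1, 1, 1), c(1, 1, 1)), 1, 1),
               class = "cervifem_geometry_error")
})

test_that("strain recovery: rigid rotation gives O(theta^2) strain, bar stretch delta/L", {
  mesh <- bar_mesh(L = 4, nx = 4, kind = "tet10")
  model <- bar_model(mesh)
  th <- 1e-4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  u <- mesh$nodes %*% t(R) - mesh$nodes
  eps <- compute_element_strain(list(u = as.vector(t(u))), model)
  expect_lt(max(abs(eps)), 10 * th^2)
  # uniform stretch
  ux <- 0.01 * mesh$nodes[, 1] / 4 # delta = 0.01 over L = 4
  u0 <- cbind(ux, 0, 0)
  eps <- compute_element_strain(list(u = as.vector(t(u0))), model)
  expect_equal(unname(eps[, 1]), rep(0.01 / 4, nrow(eps)), tolerance = 1e-12)
})

test_that("degenerate elements are rejected with a quality error", {
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0))
  expect_error(element_stiffness_solid(flat, 1, 0.3, "tet4"),
               class = "cervifem_geometry_error")
})
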