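# Test fixtures and independent oracles, built in code at test time.

# independent tet4 stiffness in plain R: linear shape functions from the
# inversion of the [1 x y z] matrix, explicit B-matrix product
oracle_tet4_stiffness <- function(coords, E, nu) {
  A <- cbind(1, coords)
  V6 <- det(A)
  C <- solve(A) # rows: coefficients of 1, x, y, z per shape function (cols)
  grads <- t(C[2:4, ]) # dN_i/dx, /dy, /dz
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    dx <- grads[i, 1]; dy <- grads[i, 2]; dz <- grads[i, 3]
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dx
    B[2, c0 + 2] <- dy
    B[3, c0 + 3] <- dz
    B[4, c0 + 1] <- dy; B[4, c0 + 2] <- dx
    B[5, c0 + 2] <- dz; B[5, c0 + 3] <- dy
    B[6, c0 + 1] <- dz; B[6, c0 + 3] <- dx
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  t(B) %*% D %*% B * abs(V6) / 6
}

# dense brute-force solve: assemble tet4 elements with the oracle stiffness,
# eliminate fixed DOFs explicitly, invert directly
oracle_dense_solve <- function(nodes, conn, E, nu, fixed_dofs, forces) {
  n <- 3 * nrow(nodes)
  K <- matrix(0, n, n)
  for (e in seq_len(nrow(conn))) {
    idx <- as.vector(t(outer(3 * (conn[e, ] - 1), 1:3, "+")))
    K[idx, idx] <- K[idx, idx] +
      oracle_tet4_stiffness(nodes[conn[e, ], ], E, nu)
  }
  f <- numeric(n)
  f[forces$dof] <- forces$value
  free <- setdiff(seq_len(n), fixed_dofs)
  u <- numeric(n)
  u[free] <- solve(K[free, free], f[free])
  u
}

# small structured bar: tet4 blocks spanning [0,L] x [0,W] x [0,H]
bar_mesh <- function(L = 10, W = 1, H = 1, nx = 10, ny = 1, nz = 1,
                     kind = "tet4") {
  g <- cervifem:::grid_hex(seq(0, L, length.out = nx + 1),
                           seq(0, W, length.out = ny + 1),
                           seq(0, H, length.out = nz + 1))
  conn <- cervifem:::orient_tets(g$nodes, cervifem:::hex_to_tet(g$hex))
  m <- fe_mesh(g$nodes, list(list(kind = "tet4", conn = conn)))
  if (kind == "tet10") m <- cervifem:::quadratize_mesh(m)
  m
}

# wrap a mesh into a minimal solvable model with uniform material
bar_model <- function(mesh, E = 1000, nu = 0.0) {
  model <- spine_model(mesh)
  ne <- mesh_nelem(mesh)
  model$E <- rep(E, ne)
  model$nu <- rep(nu, ne)
  model
}

# custom load case for fixtures: nodal forces only, fixation via model$fixed
custom_case <- function(forces = NULL) {
  structure(list(motion = "custom",
                 forces = if (is.null(forces))
                   data.frame(node = integer(0), dof = integer(0),
                              value = numeric(0)) else forces,
                 coupling = NULL, torque = NULL, fixed_nset = NULL),
            class = "load_case")
}

fix_nodes <- function(model, nodes, dofs = 1:3, values = 0) {
  model$fixed <- rbind(model$fixed,
                       data.frame(node = rep(nodes, each = length(dofs)),
                                  dof = rep(dofs, length(nodes)),
                                  value = values))
  model
}

# one regular tet10 (corner tet + edge midpoints) for single-element tests
single_tet10 <- function() {
  c4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mid <- rbind((c4[1, ] + c4[2, ]) / 2, (c4[2, ] + c4[3, ]) / 2,
               (c4[1, ] + c4[3, ]) / 2, (c4[1, ] + c4[4, ]) / 2,
               (c4[2, ] + c4[4, ]) / 2, (c4[3, ] + c4[4, ]) / 2)
  rbind(c4, mid)
}

# coarse phantom spec used across phantom/pipeline tests (small but valid)
coarse_spec <- function(...) {
  phantom_spec(mesh_size = 3.5, ...)
}

# two stacked blocks joined by a soft interlayer: a miniature motion
# segment with the node sets segment_rom() expects
mini_segment_model <- function() {
  lower <- bar_mesh(L = 4, W = 4, H = 2, nx = 2, ny = 2, nz = 1)
  disc <- bar_mesh(L = 4, W = 4, H = 1, nx = 2, ny = 2, nz = 1)
  disc$nodes[, 3] <- disc$nodes[, 3] + 2
  upper <- bar_mesh(L = 4, W = 4, H = 2, nx = 2, ny = 2, nz = 1)
  upper$nodes[, 3] <- upper$nodes[, 3] + 3
  mesh <- cervifem:::mesh_join(list(lower, disc, upper), tol = 1e-9)
  z <- mesh$nodes[, 3]
  ids <- seq_len(nrow(mesh$nodes))
  mesh$nsets <- list(
    L_endplate_inf = ids[z == 0], L_endplate_sup = ids[z == 2],
    L_spinous_process = ids[z == 1 & mesh$nodes[, 2] == 0],
    U_endplate_inf = ids[z == 3], U_endplate_sup = ids[z == 5],
    U_spinous_process = ids[z == 4 & mesh$nodes[, 2] == 0],
    base = ids[z == 0], top = ids[z == 5])
  model <- spine_model(mesh, info = list(levels = c("U", "L"),
                                         junctions = "U-L"))
  cent <- element_centroids(mesh)
  soft <- cent[, 3] > 2 & cent[, 3] < 3
  model$E <- ifelse(soft, 5, 2000)
  model$nu <- rep(0.3, length(model$E))
  model$couplings[["drive"]] <- list(
    ref = colMeans(mesh$nodes[mesh$nsets$top, , drop = FALSE]),
    nodes = mesh$nsets$top)
  model$fixed <- data.frame(node = rep(mesh$nsets$base, each = 3),
                            dof = rep(1:3, length(mesh$nsets$base)),
                            value = 0)
  model
}

solve_mini_segment <- function(model, mx) {
  lc <- structure(list(motion = "extension",
                       forces = data.frame(node = integer(0),
                                           dof = integer(0),
                                           value = numeric(0)),
                       coupling = "drive", torque = c(mx, 0, 0),
                       fixed_nset = NULL), class = "load_case")
  solve_static(model, lc)
}

# shared assembled models, cached across test files
get_coarse_model <- function(order = "linear") {
  key <- paste0("cervifem.test.model.", order)
  m <- getOption(key)
  if (is.null(m)) {
    m <- assemble_spine(coarse_spec(), order = order)
    opts <- list(m)
    names(opts) <- key
    options(opts)
  }
  m
}
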