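# Global system assembly: element stiffness, constraint reduction (ties as
# DOF merging, kinematic couplings, fixed DOFs) and sparse matrices.

#' Element stiffness of a solid element
#'
#' Standard isoparametric small-strain stiffness; tet4 uses 1-point, tet10
#' 4-point, wedge6 3x2-point and wedge15 3x3-point quadrature.
#'
#' @param coords node coordinates (k x 3, VTK ordering).
#' @param E Young's modulus in MPa.
#' @param nu Poisson's ratio.
#' @param kind one of `"tet4"`, `"tet10"`, `"wedge6"`, `"wedge15"`.
#' @return dense symmetric stiffness matrix (3k x 3k), N/mm.
#' @export
element_stiffness_solid <- function(coords, E, nu, kind = "tet4") {
  if (!kind %in% names(KIND_ID)) cf_spec_error("unsupported solid kind '%s'", kind)
  coords <- as.matrix(coords)
  k <- KIND_NNODE[[kind]]
  if (nrow(coords) != k) cf_spec_error("coords must be %d x 3 for %s", k, kind)
  conn <- matrix(seq_len(k), 1)
  res <- .elem_stiffness_batch(coords, conn, KIND_ID[[kind]], E, nu)
  if (res$detj_min[1] <= 0)
    cf_geometry_error("element has non-positive Jacobian (quality failure)")
  K <- matrix(0, 3 * k, 3 * k)
  K[cbind(res$i, res$j)] <- res$x
  K
}

#' Element stiffness of a 2-node truss
#'
#' Axial stiffness EA/L along the element axis; no rotational DOFs and no
#' bending (ligament trusses additionally carry load only in tension, which
#' is enforced at solve time).
#'
#' @param coords node coordinates (2 x 3).
#' @param E Young's modulus in MPa.
#' @param A cross-section area in mm^2.
#' @return dense 6 x 6 stiffness matrix, N/mm.
#' @export
element_stiffness_truss <- function(coords, E, A) {
  d <- coords[2, ] - coords[1, ]
  L <- sqrt(sum(d^2))
  if (L <= 0) cf_geometry_error("zero-length truss element")
  n <- d / L
  k <- E * A / L
  nn <- k * outer(n, n)
  rbind(cbind(nn, -nn), cbind(-nn, nn))
}

# stiffness triplets of all solid blocks (cached once per model)
solid_triplets <- function(model) {
  mesh <- model$mesh
  off <- block_offsets(mesh)
  ii <- list(); jj <- list(); xx <- list()
  for (bi in seq_along(mesh$blocks)) {
    b <- mesh$blocks[[bi]]
    if (!b$kind %in% names(KIND_ID) || nrow(b$conn) == 0) next
    ids <- off[bi] + seq_len(nrow(b$conn))
    E <- model$E[ids]; nu <- model$nu[ids]
    if (anyNA(E) || anyNA(nu))
      cf_assembly_error("materials not assigned for block %d (%s)", bi, b$kind)
    res <- .elem_stiffness_batch(mesh$nodes, b$conn, KIND_ID[[b$kind]], E, nu)
    bad <- which(res$detj_min <= 0)
    if (length(bad))
      cf_geometry_error("non-positive Jacobian in %s elements (first: %d)",
                        b$kind, ids[bad[1]])
    ii[[length(ii) + 1L]] <- res$i
    jj[[length(jj) + 1L]] <- res$j
    xx[[length(xx) + 1L]] <- res$x
  }
  list(i = as.integer(unlist(ii)), j = as.integer(unlist(jj)),
       x = as.numeric(unlist(xx)))
}

# truss data (geometry, stiffness scalars) cached per model
truss_table <- function(model) {
  mesh <- model$mesh
  off <- block_offsets(mesh)
  out <- NULL
  for (bi in seq_along(mesh$blocks)) {
    b <- mesh$blocks[[bi]]
    if (b$kind != "truss2" || nrow(b$conn) == 0) next
    ids <- off[bi] + seq_len(nrow(b$conn))
    d <- mesh$nodes[b$conn[, 2], , drop = FALSE] -
      mesh$nodes[b$conn[, 1], , drop = FALSE]
    L <- sqrt(rowSums(d^2))
    if (any(L <= 0)) cf_geometry_error("zero-length truss element")
    out <- rbind(out, data.frame(
      elem = ids, n1 = b$conn[, 1], n2 = b$conn[, 2],
      nx = d[, 1] / L, ny = d[, 2] / L, nz = d[, 3] / L, L = L,
      E = model$E[ids], A = model$area[ids],
      tension_only = model$tension_only[ids]))
  }
  out
}

# triplets for a subset of trusses
truss_triplets <- function(tt, active, n_full) {
  tt <- tt[active, , drop = FALSE]
  if (nrow(tt) == 0) return(list(i = integer(0), j = integer(0), x = numeric(0)))
  ii <- jj <- list(); xx <- list()
  k <- tt$E * tt$A / tt$L
  nhat <- cbind(tt$nx, tt$ny, tt$nz)
  d1 <- 3 * (tt$n1 - 1L); d2 <- 3 * (tt$n2 - 1L)
  I <- J <- X <- NULL
  for (a in 1:3) for (b in 1:3) {
    kab <- k * nhat[, a] * nhat[, b]
    I <- c(I, d1 + a, d1 + a, d2 + a, d2 + a)
    J <- c(J, d1 + b, d2 + b, d1 + b, d2 + b)
    X <- c(X, kab, -kab, -kab, kab)
  }
  list(i = I, j = J, x = X)
}

# constraint reduction ------------------------------------------------------

# union-find representative vector for the tie pairs
tie_representatives <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Build the full-to-reduced transformation for a model:
#  - tied node classes share translational DOFs,
#  - coupled nodes follow their reference point rigidly
#    (u = u_ref + theta x (X - X_ref)),
#  - fixed DOFs become prescribed reduced DOFs.
build_reduction <- function(model) {
  N <- nrow(model$mesh$nodes)
  ncoup <- length(model$couplings)
  n_full <- 3L * N + 6L * ncoup
  rep_of <- tie_representatives(N, model$ties)

  coup_of_class <- integer(N) # 0 = none, else coupling index (by class rep)
  for (ci in seq_along(model$couplings)) {
    cls <- unique(rep_of[model$couplings[[ci]]$nodes])
    clash <- cls[coup_of_class[cls] != 0 & coup_of_class[cls] != ci]
    if (length(clash))
      cf_assembly_error("node class %d belongs to two couplings", clash[1])
    coup_of_class[cls] <- ci
  }
  node_coupling <- coup_of_class[rep_of]

  is_mpc_slave <- logical(N)
  for (mp in model$mpcs) is_mpc_slave[mp$slave] <- TRUE
  if (any(is_mpc_slave & node_coupling != 0L))
    cf_assembly_error("an embedded node participates in a kinematic coupling")
  for (mp in model$mpcs) {
    if (any(is_mpc_slave[mp$masters]))
      cf_assembly_error("an embedded node hosts another embedded node")
    if (any(rep_of[mp$slave] != mp$slave))
      cf_assembly_error("an embedded node is also tie-merged")
  }

  reps <- sort(unique(rep_of))
  free_reps <- reps[coup_of_class[reps] == 0L & !is_mpc_slave[reps]]
  red_start <- integer(N)
  red_start[free_reps] <- 3L * (seq_along(free_reps) - 1L)
  n_red_nodes <- 3L * length(free_reps)
  coup_start <- n_red_nodes + 6L * (seq_len(max(ncoup, 1L)) - 1L)
  n_red <- n_red_nodes + 6L * ncoup

  # transformation triplets
  est <- 3L * N + 6L * ncoup
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  plain <- which(node_coupling == 0L & !is_mpc_slave)
  if (length(plain)) {
    rows <- rep(3L * (plain - 1L), each = 3L) + rep(1:3, length(plain))
    cols <- rep(red_start[rep_of[plain]], each = 3L) + rep(1:3, length(plain))
    ti <- c(ti, rows); tj <- c(tj, cols); tx <- c(tx, rep(1, length(rows)))
  }
  for (ci in seq_along(model$couplings)) {
    cp <- model$couplings[[ci]]
    nodes <- which(node_coupling == ci)
    r0 <- coup_start[ci]
    X <- model$mesh$nodes[nodes, , drop = FALSE]
    rx <- X[, 1] - cp$ref[1]; ry <- X[, 2] - cp$ref[2]; rz <- X[, 3] - cp$ref[3]
    nn <- length(nodes)
    base <- 3L * (nodes - 1L)
    # u_x = uref_x + th_y * rz - th_z * ry
    ti <- c(ti, base + 1L, base + 1L, base + 1L,
            base + 2L, base + 2L, base + 2L,
            base + 3L, base + 3L, base + 3L)
    tj <- c(tj, rep(r0 + 1L, nn), rep(r0 + 5L, nn), rep(r0 + 6L, nn),
            rep(r0 + 2L, nn), rep(r0 + 6L, nn), rep(r0 + 4L, nn),
            rep(r0 + 3L, nn), rep(r0 + 4L, nn), rep(r0 + 5L, nn))
    tx <- c(tx, rep(1, nn), rz, -ry,
            rep(1, nn), rx, -rz,
            rep(1, nn), ry, -rx)
    # reference virtual node maps to itself
    full0 <- 3L * N + 6L * (ci - 1L)
    ti <- c(ti, full0 + 1:6)
    tj <- c(tj, r0 + 1:6)
    tx <- c(tx, rep(1, 6))
  }
  # embedded nodes: u_slave = sum_i w_i u_master_i (masters are plain or
  # tie-merged nodes; their reduced DOFs are the class representatives')
  for (mp in model$mpcs) {
    mreps <- rep_of[mp$masters]
    if (any(coup_of_class[mreps] != 0L))
      cf_assembly_error("an embedded node hosts onto a coupled node")
    for (d in 1:3) {
      ti <- c(ti, rep(3L * (mp$slave - 1L) + d, 4L))
      tj <- c(tj, red_start[mreps] + d)
      tx <- c(tx, mp$w)
    }
  }
  Tmat <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                               dims = c(n_full, n_red))

  fixed_red <- integer(0); fixed_val <- numeric(0)
  if (nrow(model$fixed)) {
    r <- rep_of[model$fixed$node]
    if (any(coup_of_class[r] != 0L))
      cf_assembly_error("a fixed node participates in a kinematic coupling")
    if (any(is_mpc_slave[model$fixed$node]))
      cf_assembly_error("a fixed node is an embedded (MPC slave) node")
    fr <- red_start[r] + model$fixed$dof
    keep <- !duplicated(fr)
    fixed_red <- fr[keep]; fixed_val <- model$fixed$value[keep]
  }
  list(T = Tmat, n_full = n_full, n_red = n_red, rep_of = rep_of,
       node_coupling = node_coupling, red_start = red_start,
       coup_start = coup_start, fixed_red = fixed_red, fixed_val = fixed_val,
       N = N)
}

#' Assemble the reduced linear system of a model
#'
#' Applies tie DOF merging and coupling reduction to the solid-element
#' stiffness and returns the reduced sparse symmetric matrix together with
#' the reduction operator. The matrix is positive semi-definite before
#' boundary conditions (rigid-body modes remain) and positive definite on
#' the free DOFs after fixation of a well-connected model.
#'
#' @param model a `spine_model` with materials assigned.
#' @param load_case optional [build_load_case()] result used to build the
#'   reduced load vector.
#' @return list with the reduction (`red`), solids-only reduced stiffness
#'   `K_solid`, cached truss table, and reduced load vector `f`.
#' @export
assemble_system <- function(model, load_case = NULL) {
  red <- build_reduction(model)
  tr <- solid_triplets(model)
  K_full <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                 dims = c(red$n_full, red$n_full))
  K_solid <- Matrix::t(red$T) %*% K_full %*% red$T
  f <- load_vector(model, red, load_case)
  list(red = red, K_solid = K_solid, tt = truss_table(model), f = f)
}

# reduced load vector from nodal forces + coupling torque + fixed values
load_vector <- function(model, red, load_case) {
  f_full <- numeric(red$n_full)
  if (!is.null(load_case)) {
    if (nrow(load_case$forces)) {
      idx <- 3L * (load_case$forces$node - 1L) + load_case$forces$dof
      f_full[idx] <- f_full[idx] + load_case$forces$value
    }
    if (!is.null(load_case$coupling)) {
      ci <- match(load_case$coupling, names(model$couplings))
      if (is.na(ci)) cf_assembly_error("unknown coupling '%s'", load_case$coupling)
      rot <- 3L * red$N + 6L * (ci - 1L) + 4:6
      f_full[rot] <- f_full[rot] + load_case$torque
    }
  }
  as.numeric(Matrix::t(red$T) %*% f_full)
}

# fixed-DOF rows of a model from a load case's base set (translations)
apply_base_fixation <- function(model, load_case) {
  if (is.null(load_case$fixed_nset)) return(model)
  base <- model$mesh$nsets[[load_case$fixed_nset]]
  model$fixed <- rbind(model$fixed,
                       data.frame(node = rep(base, each = 3L),
                                  dof = rep(1:3, length(base)),
                                  value = 0))
  model
}
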