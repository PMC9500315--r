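# Static solve with tension-only truss active sets and small-sliding
# penalty contact with Coulomb friction.

# point-to-triangle closest point; returns list(point, w = barycentric)
closest_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(list(point = a, w = c(1, 0, 0)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(list(point = b, w = c(0, 1, 0)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(list(point = a + v * ab, w = c(1 - v, v, 0)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(list(point = c, w = c(0, 0, 1)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(list(point = a + w * ac, w = c(1 - w, 0, w)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(list(point = b + w * (c - b), w = c(0, 1 - w, w)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  list(point = a + ab * v + ac * w, w = c(1 - v - w, v, w))
}

# small-sliding pairing: project every slave node once onto the nearest
# master corner triangle; pairing, normal and reference gap are then fixed
contact_init <- function(model, penalty_factor = 50) {
  mesh <- model$mesh
  pairs <- list()
  for (cp in model$contacts) {
    surf <- mesh$surfaces[[cp$master_surface]]
    slaves <- mesh$nsets[[cp$slave_nset]]
    if (is.null(surf) || is.null(slaves) || !nrow(surf) || !length(slaves))
      cf_assembly_error("contact pair %s references missing sets", cp$name)
    loc <- elem_locate(mesh, surf$elem)
    tris <- matrix(0L, nrow(surf), 3L)
    Etri <- numeric(nrow(surf))
    ecent <- matrix(0, nrow(surf), 3L)
    for (r in seq_len(nrow(surf))) {
      b <- mesh$blocks[[loc$block[r]]]
      corners <- FACE_CORNERS[[b$kind]][[surf$face[r]]]
      tris[r, ] <- b$conn[loc$local[r], corners]
      Etri[r] <- model$E[surf$elem[r]]
      ecent[r, ] <- colMeans(mesh$nodes[b$conn[loc$local[r], 1:4], , drop = FALSE])
    }
    rows <- lapply(slaves, function(s) {
      p <- mesh$nodes[s, ]
      best <- NULL; bd <- Inf; bi <- NA
      for (r in seq_len(nrow(tris))) {
        cpnt <- closest_point_triangle(p, mesh$nodes[tris[r, 1], ],
                                       mesh$nodes[tris[r, 2], ],
                                       mesh$nodes[tris[r, 3], ])
        d <- sqrt(sum((p - cpnt$point)^2))
        if (d < bd) { bd <- d; best <- cpnt; bi <- r }
      }
      a <- mesh$nodes[tris[bi, 1], ]; b2 <- mesh$nodes[tris[bi, 2], ]
      c2 <- mesh$nodes[tris[bi, 3], ]
      nrm <- c((b2[2] - a[2]) * (c2[3] - a[3]) - (b2[3] - a[3]) * (c2[2] - a[2]),
               (b2[3] - a[3]) * (c2[1] - a[1]) - (b2[1] - a[1]) * (c2[3] - a[3]),
               (b2[1] - a[1]) * (c2[2] - a[2]) - (b2[2] - a[2]) * (c2[1] - a[1]))
      area <- 0.5 * sqrt(sum(nrm^2))
      nrm <- nrm / (2 * area)
      # orient outward from the master element
      if (sum(nrm * (colMeans(rbind(a, b2, c2)) - ecent[bi, ])) < 0) nrm <- -nrm
      g0 <- sum(nrm * (p - best$point))
      k <- penalty_factor * Etri[bi] * sqrt(2 * area)
      list(slave = s, tri = tris[bi, ], w = best$w, n = nrm, g0 = g0,
           k = k, mu = cp$mu, pair = cp$name)
    })
    pairs <- c(pairs, rows)
  }
  pairs
}

# per-slave 12x12 penalty block: a = (1, -w1, -w2, -w3) outer with
# M = k n n^T plus a tangential spring -- full stick penalty k while
# sticking, secant Coulomb stiffness mu N / |u_t| while slipping (so the
# tangential force magnitude equals mu N at the current slip)
contact_triplets <- function(pairs, state, n_full) {
  I <- J <- NULL; X <- NULL
  fI <- NULL; fX <- NULL
  for (idx in seq_along(pairs)) {
    pc <- pairs[[idx]]
    st <- state[[idx]]
    if (!st$active) next
    a <- c(1, -pc$w)
    nodes <- c(pc$slave, pc$tri)
    n <- pc$n
    P <- diag(3) - outer(n, n)
    kt <- if (st$slip) st$k_sec else pc$k
    M <- pc$k * outer(n, n) + kt * P
    dof <- as.vector(t(outer(3L * (nodes - 1L), 1:3, "+")))
    block <- kronecker(outer(a, a), M)
    I <- c(I, rep(dof, each = 12L))
    J <- c(J, rep(dof, times = 12L))
    X <- c(X, as.vector(t(block)))
    # reference-gap force (normal penalty measures g0 + n.rel)
    cvec <- as.vector(t(outer(a, n))) # length 12, node-major dof order
    fI <- c(fI, dof); fX <- c(fX, -pc$k * pc$g0 * cvec)
  }
  list(i = I, j = J, x = X, fi = fI, fx = fX)
}

# evaluate contact kinematics at a displacement vector
contact_eval <- function(pairs, u_full) {
  lapply(pairs, function(pc) {
    us <- u_full[3L * (pc$slave - 1L) + 1:3]
    um <- pc$w[1] * u_full[3L * (pc$tri[1] - 1L) + 1:3] +
      pc$w[2] * u_full[3L * (pc$tri[2] - 1L) + 1:3] +
      pc$w[3] * u_full[3L * (pc$tri[3] - 1L) + 1:3]
    rel <- us - um
    g <- pc$g0 + sum(pc$n * rel)
    tvec <- rel - sum(pc$n * rel) * pc$n
    tmag <- sqrt(sum(tvec^2))
    list(g = g, N = max(0, -pc$k * g), slip_vec = tvec, slip = tmag,
         that = if (tmag > 0) tvec / tmag else c(0, 0, 0))
  })
}

#' Solve the static problem for one load case
#'
#' Outer fixed-point loop: (i) solve the reduced linear system by sparse
#' Cholesky, (ii) deactivate trusses in compression and reactivate those
#' returning to tension, (iii) update the penalty contact active set and the
#' Coulomb stick/slip state on the fixed small-sliding pairing; iterate
#' until the active sets are unchanged and the displacement increment is
#' below `rtol`.
#'
#' @param model a `spine_model` with materials assigned.
#' @param load_case a [build_load_case()] result (or `NULL` for a model with
#'   its own `fixed` table and nodal loads already set).
#' @param rtol relative displacement-increment tolerance.
#' @param max_outer maximum outer iterations.
#' @param penalty_factor contact penalty scale (times master-element
#'   stiffness E*sqrt(face area)).
#' @param penetration_tol admissible residual penetration in mm.
#' @param friction_rtol relative displacement-increment tolerance for the
#'   secant Coulomb fixed point while nodes slip (the regularized friction
#'   force converges linearly, so it gets its own, looser gate than
#'   `rtol`; nodes with vanishing normal force make the force-cap error
#'   itself ill-scaled).
#' @param system optional pre-assembled system from [assemble_system()]
#'   (reused across motions).
#' @return an object of class `solve_result` with nodal displacements,
#'   per-element volume-averaged strain tensors, truss status/forces,
#'   contact gap/slip tables and energy diagnostics.
#' @export
solve_static <- function(model, load_case = NULL, rtol = 1e-8,
                         max_outer = 50, penalty_factor = 50,
                         penetration_tol = 1e-3, friction_rtol = 1e-5,
                         system = NULL) {
  if (!is.null(load_case)) model <- apply_base_fixation(model, load_case)
  if (is.null(system)) {
    sys <- assemble_system(model, load_case)
  } else {
    sys <- system
    sys$red <- build_reduction(model) # fixed DOFs may differ per case
    sys$f <- load_vector(model, sys$red, load_case)
  }
  red <- sys$red
  K_solid <- sys$K_solid
  tt <- sys$tt
  n_red <- red$n_red

  free <- setdiff(seq_len(n_red), red$fixed_red)
  u_red <- numeric(n_red)
  u_red[red$fixed_red] <- red$fixed_val

  pairs <- contact_init(model, penalty_factor)
  state <- lapply(pairs, function(p)
    list(active = p$g0 < 0, slip = FALSE, N = 0, k_sec = p$k))
  truss_active <- if (!is.null(tt)) rep(TRUE, nrow(tt)) else logical(0)

  u_prev <- NULL
  converged <- FALSE
  cap_err <- 0
  iter <- 0L
  Tt <- Matrix::t(red$T)
  repeat {
    iter <- iter + 1L
    K <- K_solid
    if (!is.null(tt) && any(truss_active)) {
      trip <- truss_triplets(tt, truss_active, red$n_full)
      dK <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                                 dims = c(red$n_full, red$n_full))
      K <- K + Tt %*% dK %*% red$T
    }
    f <- sys$f
    if (length(pairs)) {
      ct <- contact_triplets(pairs, state, red$n_full)
      if (length(ct$i)) {
        dK <- Matrix::sparseMatrix(i = ct$i, j = ct$j, x = ct$x,
                                   dims = c(red$n_full, red$n_full))
        K <- K + Tt %*% dK %*% red$T
        df <- numeric(red$n_full)
        idx <- ct$fi
        for (q in seq_along(idx)) df[idx[q]] <- df[idx[q]] + ct$fx[q]
        f <- f + as.numeric(Tt %*% df)
      }
    }
    Kff <- K[free, free, drop = FALSE]
    rhs <- f[free]
    if (length(red$fixed_red))
      rhs <- rhs - as.numeric(K[free, red$fixed_red, drop = FALSE] %*%
                                red$fixed_val)
    uf <- tryCatch({
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                             perm = TRUE)
      as.numeric(Matrix::solve(ch, rhs))
    }, error = function(e) {
      tryCatch(as.numeric(Matrix::solve(Kff, rhs)),
               error = function(e2)
                 cf_assembly_error(paste0(
                   "singular system after boundary conditions (free-floating ",
                   "part?): %s"), conditionMessage(e2)))
    })
    u_red[free] <- uf
    u_full <- as.numeric(red$T %*% u_red)

    # truss active set update
    changed <- FALSE
    if (!is.null(tt) && nrow(tt)) {
      du <- cbind(u_full[3 * (tt$n2 - 1) + 1] - u_full[3 * (tt$n1 - 1) + 1],
                  u_full[3 * (tt$n2 - 1) + 2] - u_full[3 * (tt$n1 - 1) + 2],
                  u_full[3 * (tt$n2 - 1) + 3] - u_full[3 * (tt$n1 - 1) + 3])
      ax <- du[, 1] * tt$nx + du[, 2] * tt$ny + du[, 3] * tt$nz
      want <- ifelse(tt$tension_only, ax > 0 | abs(ax) < 1e-14, TRUE)
      if (any(want != truss_active)) { truss_active <- want; changed <- TRUE }
      truss_strain <- ax / tt$L
    } else truss_strain <- numeric(0)

    # contact status update: settle the active set first (stick only),
    # then allow stick/slip transitions -- friction decisions taken while
    # the active set is still moving would use meaningless normal forces
    if (length(pairs)) {
      ev <- contact_eval(pairs, u_full)
      active_new <- vapply(ev, function(e) e$g < 0, logical(1))
      active_old <- vapply(state, `[[`, logical(1), "active")
      activation_moved <- any(active_new != active_old)
      cap_err <- 0
      for (idx in seq_along(pairs)) {
        pc <- pairs[[idx]]; e <- ev[[idx]]
        slip_new <- FALSE
        k_old <- state[[idx]]$k_sec
        k_sec <- k_old
        if (!activation_moved && active_new[idx]) {
          # full-stick spring force vs the Coulomb cap decides the state;
          # slipping nodes carry the secant stiffness mu N / |u_t|; a 5%
          # hysteresis band keeps marginal nodes from chattering
          cap <- pc$mu * e$N
          gate <- if (state[[idx]]$slip) 0.95 * cap else 1.05 * cap
          if (pc$k * e$slip > gate + 1e-12) {
            slip_new <- TRUE
            k_sec <- cap / max(e$slip, 1e-12)
            if (state[[idx]]$slip) # how far the force sits from the cap
              cap_err <- max(cap_err, abs(k_old * e$slip - cap) /
                               max(cap, 1e-12))
          }
        }
        if (active_new[idx] != state[[idx]]$active ||
            slip_new != state[[idx]]$slip)
          changed <- TRUE
        state[[idx]] <- list(active = active_new[idx], slip = slip_new,
                             N = e$N, k_sec = k_sec)
      }
    }

    dmax <- if (is.null(u_prev)) Inf else {
      sc <- max(abs(u_red), 1e-300)
      max(abs(u_red - u_prev)) / sc
    }
    u_prev <- u_red
    # each inner solve is exact for its active sets, so unchanged sets mean
    # convergence -- except while nodes slip, where the secant Coulomb
    # stiffness keeps evolving until the displacement increment settles
    any_slip <- length(pairs) && any(vapply(state, `[[`, logical(1), "slip"))
    slip_settled <- !any_slip || dmax < max(rtol, friction_rtol) ||
      cap_err < 1e-3
    if (!changed && slip_settled) { converged <- TRUE; break }
    if (iter >= max_outer) break
  }
  if (!converged)
    cf_convergence_error(paste0(
      "no convergence within %d outer iterations (last increment %.2e; ",
      "truss/contact sets still changing)"), max_outer, dmax)

  # final diagnostics
  energy_lhs <- as.numeric(u_red %*% (K %*% u_red))
  energy_rhs <- sum(f * u_red)
  contact_df <- NULL
  if (length(pairs)) {
    ev <- contact_eval(pairs, u_full)
    contact_df <- data.frame(
      pair = vapply(pairs, function(p) p$pair, character(1)),
      node = vapply(pairs, function(p) p$slave, numeric(1)),
      gap = vapply(ev, function(e) e$g, numeric(1)),
      normal_force = vapply(ev, function(e) e$N, numeric(1)),
      slip = vapply(ev, function(e) e$slip, numeric(1)),
      active = vapply(state, function(s) s$active, logical(1)),
      slipping = vapply(state, function(s) s$slip, logical(1)))
    pen <- -contact_df$gap[contact_df$active]
    if (length(pen) && max(pen) > penetration_tol)
      cf_convergence_error("residual penetration %.2e mm exceeds tolerance %.1e",
                           max(pen), penetration_tol)
  }

  res <- structure(list(
    u = u_full, u_red = u_red,
    displacements = matrix(u_full[seq_len(3 * red$N)], ncol = 3, byrow = TRUE),
    red = red,
    load_case = load_case,
    iterations = iter, converged = converged,
    energy = list(strain_energy2 = energy_lhs, external_work = energy_rhs,
                  rel_gap = abs(energy_lhs - energy_rhs) /
                    max(abs(energy_lhs), 1e-300)),
    truss = if (!is.null(tt)) data.frame(
      elem = tt$elem, strain = truss_strain,
      force = ifelse(truss_active, tt$E * tt$A * truss_strain, 0),
      active = truss_active) else NULL,
    contact = contact_df), class = "solve_result")
  res$strain <- compute_element_strain(res, model)
  res
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("<solve_result> %s: %d iterations, |u|max = %.4g mm\n",
              if (is.null(x$load_case)) "custom" else x$load_case$motion,
              x$iterations, max(abs(x$displacements))))
  cat(sprintf("  energy balance: uKu = %.6g, fu = %.6g (rel gap %.1e)\n",
              x$energy$strain_energy2, x$energy$external_work,
              x$energy$rel_gap))
  if (!is.null(x$contact) && nrow(x$contact))
    cat(sprintf("  contact: %d/%d active, max slip %.4g mm\n",
                sum(x$contact$active), nrow(x$contact), max(x$contact$slip)))
  invisible(x)
}

#' Volume-averaged small-strain tensors per element
#'
#' epsilon = (grad u + grad u^T) / 2 evaluated at the quadrature points and
#' volume-averaged per element. Rows are (xx, yy, zz, xy, yz, xz) with
#' engineering shear; truss elements report the axial strain in column 1
#' with the remaining components `NA`.
#'
#' @param result a `solve_result`.
#' @param model the model that produced it.
#' @return numeric matrix (n_elem x 6).
#' @export
compute_element_strain <- function(result, model) {
  mesh <- model$mesh
  u <- result$u[seq_len(3 * nrow(mesh$nodes))]
  out <- matrix(NA_real_, mesh_nelem(mesh), 6)
  off <- block_offsets(mesh)
  for (bi in seq_along(mesh$blocks)) {
    b <- mesh$blocks[[bi]]
    if (nrow(b$conn) == 0) next
    ids <- off[bi] + seq_len(nrow(b$conn))
    if (b$kind %in% names(KIND_ID)) {
      sv <- .elem_strain_batch(mesh$nodes, b$conn, KIND_ID[[b$kind]], u)
      out[ids, ] <- sv[, 1:6, drop = FALSE]
    } else if (b$kind == "truss2") {
      d <- mesh$nodes[b$conn[, 2], , drop = FALSE] -
        mesh$nodes[b$conn[, 1], , drop = FALSE]
      L <- sqrt(rowSums(d^2))
      nh <- d / L
      du <- cbind(u[3 * (b$conn[, 2] - 1) + 1] - u[3 * (b$conn[, 1] - 1) + 1],
                  u[3 * (b$conn[, 2] - 1) + 2] - u[3 * (b$conn[, 1] - 1) + 2],
                  u[3 * (b$conn[, 2] - 1) + 3] - u[3 * (b$conn[, 1] - 1) + 3])
      out[ids, 1] <- rowSums(du * nh) / L
    }
  }
  out
}
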