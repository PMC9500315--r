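# Assembled model container: mesh + material fields + constraints.

#' Construct a spine model
#'
#' Wraps an assembled mesh with per-element material fields and the
#' constraint sets consumed by the solver: tie pairs (DOF equivalence via
#' node merging), kinematic couplings (a 6-DOF reference point rigidly
#' driving a node set), fixed DOFs, and small-sliding contact pairs.
#'
#' @param mesh an `fe_mesh`.
#' @param info free-form metadata list (levels, junction geometry, specs).
#' @return an object of class `spine_model`.
#' @export
spine_model <- function(mesh, info = list()) {
  n <- mesh_nelem(mesh)
  structure(list(
    mesh = mesh,
    E = rep(NA_real_, n),
    nu = rep(NA_real_, n),
    area = rep(NA_real_, n),          # truss cross-sections, mm^2
    mat_name = rep(NA_character_, n),
    tension_only = rep(FALSE, n),
    ties = matrix(integer(0), 0, 2),
    mpcs = list(),                    # embedded-node constraints
    couplings = list(),
    fixed = data.frame(node = integer(0), dof = integer(0),
                       value = numeric(0)),
    contacts = list(),
    info = info), class = "spine_model")
}

#' @export
print.spine_model <- function(x, ...) {
  cat("<spine_model>\n")
  print(x$mesh)
  cat(sprintf("  ties: %d pairs, couplings: %d, contacts: %d, fixed dofs: %d\n",
              nrow(x$ties), length(x$couplings), length(x$contacts),
              nrow(x$fixed)))
  cat(sprintf("  materials assigned: %d / %d elements\n",
              sum(!is.na(x$E)), length(x$E)))
  invisible(x)
}

# append a mesh (already in global coordinates) to a model, stitching
# coincident nodes; returns the updated model plus id offsets
model_append_mesh <- function(model, mesh, prefix = "", tol = 1e-9) {
  old_n_elem <- mesh_nelem(model$mesh)
  joined <- mesh_join(list(model$mesh, mesh), prefixes = c("", prefix),
                      tol = tol)
  add <- mesh_nelem(mesh)
  model$mesh <- joined
  model$E <- c(model$E, rep(NA_real_, add))
  model$nu <- c(model$nu, rep(NA_real_, add))
  model$area <- c(model$area, rep(NA_real_, add))
  model$mat_name <- c(model$mat_name, rep(NA_character_, add))
  model$tension_only <- c(model$tension_only, rep(FALSE, add))
  # ties/couplings/fixed/contact reference node ids: mesh_join only merges
  # duplicate coordinates, and the *first* occurrence keeps its id, so ids of
  # the pre-existing mesh are stable.
  model
}

# node ids referenced by a set of global element ids
elset_nodes <- function(mesh, elems) {
  loc <- elem_locate(mesh, elems)
  ids <- integer(0)
  for (bi in unique(loc$block)) {
    conn <- mesh$blocks[[bi]]$conn[loc$local[loc$block == bi], , drop = FALSE]
    ids <- c(ids, as.vector(conn))
  }
  sort(unique(ids))
}

# nodes of the bone (trabecular + cortical) of one level
level_bone_nodes <- function(model, level) {
  sets <- paste0(level, "_", c("central_body", "exterior_body", "cortical"))
  elems <- unlist(model$mesh$elsets[sets], use.names = FALSE)
  if (!length(elems)) cf_assembly_error("no bone element sets for level %s", level)
  elset_nodes(model$mesh, elems)
}

add_ties <- function(model, pairs) {
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  model$ties <- rbind(model$ties, pairs)
  model
}

# Embed nodes into host solid elements: each slave node's displacement is
# interpolated (linear barycentric) from the corner nodes of the tet that
# contains it, so embedded parts transmit load consistently distributed
# over the host mesh (no point-tie concentrations).
embed_nodes <- function(model, slave_ids, host_elems, what = "embedding",
                        bary_tol = 0.25) {
  mesh <- model$mesh
  loc <- elem_locate(mesh, host_elems)
  m <- length(host_elems)
  corners <- matrix(0L, m, 4L)
  for (r in seq_len(m)) {
    b <- mesh$blocks[[loc$block[r]]]
    if (!b$kind %in% c("tet4", "tet10"))
      cf_assembly_error("%s: host elements must be tets", what)
    corners[r, ] <- b$conn[loc$local[r], 1:4]
  }
  cent <- (mesh$nodes[corners[, 1], , drop = FALSE] +
             mesh$nodes[corners[, 2], , drop = FALSE] +
             mesh$nodes[corners[, 3], , drop = FALSE] +
             mesh$nodes[corners[, 4], , drop = FALSE]) / 4
  n_embedded <- 0L
  for (s in slave_ids) {
    p <- mesh$nodes[s, ]
    d2 <- (cent[, 1] - p[1])^2 + (cent[, 2] - p[2])^2 + (cent[, 3] - p[3])^2
    # test the nearest candidates until one contains the point
    ord <- order(d2)[seq_len(min(12L, m))]
    best_w <- NULL; best_min <- -Inf; best_r <- NA
    for (r in ord) {
      X <- mesh$nodes[corners[r, ], , drop = FALSE]
      A <- rbind(t(X), rep(1, 4))
      w <- tryCatch(solve(A, c(p, 1)), error = function(e) NULL)
      if (is.null(w)) next
      mn <- min(w)
      if (mn > best_min) { best_min <- mn; best_w <- w; best_r <- r }
      if (mn >= -1e-9) break
    }
    if (is.null(best_w) || best_min < -bary_tol) next # outside the hosts
    w <- pmax(best_w, 0); w <- w / sum(w)
    model$mpcs[[length(model$mpcs) + 1L]] <-
      list(slave = s, masters = corners[best_r, ], w = w)
    n_embedded <- n_embedded + 1L
  }
  attr(model, "last_embed_count") <- n_embedded
  model
}

# tie every node of `slave_ids` to its nearest node among `master_ids`
tie_nearest <- function(model, slave_ids, master_ids, capture,
                        what = "interface", partial = FALSE) {
  nn <- nearest_node(model$mesh$nodes[master_ids, , drop = FALSE],
                     model$mesh$nodes[slave_ids, , drop = FALSE])
  ok <- nn$dist <= capture
  if (!partial && !all(ok))
    cf_assembly_error("%s tie: %d nodes beyond capture radius %.2f mm",
                      what, sum(!ok), capture)
  pairs <- cbind(slave_ids[ok], master_ids[nn$index[ok]])
  add_ties(model, pairs)
}
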