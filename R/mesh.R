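# Mesh container and structured meshing primitives.
#
# A `fe_mesh` stores nodes in mm, element blocks (tet4/tet10/wedge6/wedge15/
# truss2/hex8), named node sets, named element sets (global element ids,
# numbered consecutively across blocks), and named surface patches (element
# face lists). Solid blocks use VTK node orderings.

KIND_ID <- c(tet4 = 0L, tet10 = 1L, wedge6 = 2L, wedge15 = 3L)
KIND_NNODE <- c(tet4 = 4L, tet10 = 10L, wedge6 = 6L, wedge15 = 15L,
                truss2 = 2L, hex8 = 8L)
VTK_CELL_TYPE <- c(tet4 = 10L, tet10 = 24L, wedge6 = 13L, wedge15 = 26L,
                   truss2 = 3L, hex8 = 12L)

# corner-face tables (local 1-based); quadratic kinds share corner topology
FACE_CORNERS <- list(
  tet4 = list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(2L, 3L, 4L), c(1L, 3L, 4L)),
  tet10 = list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(2L, 3L, 4L), c(1L, 3L, 4L)),
  wedge6 = list(c(1L, 2L, 3L), c(4L, 5L, 6L)),
  wedge15 = list(c(1L, 2L, 3L), c(4L, 5L, 6L))
)

#' Construct a finite-element mesh container
#'
#' @param nodes numeric matrix (n x 3) of node coordinates in mm.
#' @param blocks list of element blocks, each `list(kind =, conn =)` with
#'   1-based connectivity rows.
#' @param nsets named list of integer node-id vectors.
#' @param elsets named list of integer global-element-id vectors.
#' @param surfaces named list of data frames with columns `elem`, `face`.
#' @return an object of class `fe_mesh`.
#' @export
fe_mesh <- function(nodes, blocks = list(), nsets = list(), elsets = list(),
                    surfaces = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3) cf_spec_error("nodes must be an n x 3 matrix")
  for (b in blocks) {
    if (!b$kind %in% names(KIND_NNODE))
      cf_spec_error("unknown element kind '%s'", b$kind)
    if (ncol(b$conn) != KIND_NNODE[[b$kind]])
      cf_spec_error("connectivity width %d does not match kind '%s'",
                    ncol(b$conn), b$kind)
    if (nrow(b$conn) > 0 && (min(b$conn) < 1 || max(b$conn) > nrow(nodes)))
      cf_spec_error("connectivity index out of range for kind '%s'", b$kind)
  }
  structure(list(nodes = nodes, blocks = blocks, nsets = nsets,
                 elsets = elsets, surfaces = surfaces),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d nodes, %d elements in %d blocks\n",
              nrow(x$nodes), mesh_nelem(x), length(x$blocks)))
  for (b in x$blocks)
    cat(sprintf("  %-8s %d\n", b$kind, nrow(b$conn)))
  cat(sprintf("  nsets: %d, elsets: %d, surfaces: %d\n",
              length(x$nsets), length(x$elsets), length(x$surfaces)))
  invisible(x)
}

#' Total number of elements in a mesh
#' @param mesh an `fe_mesh`.
#' @return integer element count.
#' @export
mesh_nelem <- function(mesh) {
  sum(vapply(mesh$blocks, function(b) nrow(b$conn), integer(1)))
}

# per-block global-id offsets
block_offsets <- function(mesh) {
  n <- vapply(mesh$blocks, function(b) nrow(b$conn), integer(1))
  cumsum(c(0L, n))[seq_along(n)]
}

# map global element ids -> (block, local row)
elem_locate <- function(mesh, ids) {
  off <- block_offsets(mesh)
  n <- vapply(mesh$blocks, function(b) nrow(b$conn), integer(1))
  blk <- findInterval(ids, cumsum(n) + 0.5) + 1L
  data.frame(block = blk, local = as.integer(ids - off[blk]))
}

#' Element volumes (mm^3; truss elements report length times unit area 0)
#' @param mesh an `fe_mesh`.
#' @return numeric vector over global element ids.
#' @export
element_volumes <- function(mesh) {
  out <- numeric(mesh_nelem(mesh))
  off <- block_offsets(mesh)
  for (i in seq_along(mesh$blocks)) {
    b <- mesh$blocks[[i]]
    if (nrow(b$conn) == 0) next
    idx <- off[i] + seq_len(nrow(b$conn))
    if (b$kind %in% names(KIND_ID)) {
      out[idx] <- .elem_volume_batch(mesh$nodes, b$conn, KIND_ID[[b$kind]])
    } else if (b$kind == "truss2") {
      d <- mesh$nodes[b$conn[, 2], , drop = FALSE] -
        mesh$nodes[b$conn[, 1], , drop = FALSE]
      out[idx] <- 0 * sqrt(rowSums(d^2))
    } else {
      out[idx] <- NA_real_
    }
  }
  out
}

#' Element centroids
#' @param mesh an `fe_mesh`.
#' @return numeric matrix (n_elem x 3).
#' @export
element_centroids <- function(mesh) {
  out <- matrix(NA_real_, mesh_nelem(mesh), 3)
  off <- block_offsets(mesh)
  for (i in seq_along(mesh$blocks)) {
    b <- mesh$blocks[[i]]
    if (nrow(b$conn) == 0) next
    idx <- off[i] + seq_len(nrow(b$conn))
    for (d in 1:3) {
      xc <- matrix(mesh$nodes[b$conn, d], nrow(b$conn))
      out[idx, d] <- rowMeans(xc)
    }
  }
  out
}

# structured hexahedral grid ------------------------------------------------

# returns list(nodes, hex (m x 8, VTK ordering), dims, index array)
grid_hex <- function(xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))
  nid <- function(i, j, k) (k - 1L) * nx * ny + (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  j <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  k <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  hex <- cbind(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k),
               nid(i, j + 1L, k), nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
               nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  storage.mode(hex) <- "integer"
  list(nodes = nodes, hex = hex)
}

# split VTK hexes into 6 tets sharing the 1-7 diagonal; the pattern is
# face-conforming across a structured grid
hex_to_tet <- function(hex) {
  pat <- matrix(c(1L, 2L, 3L, 7L,
                  1L, 3L, 4L, 7L,
                  1L, 4L, 8L, 7L,
                  1L, 8L, 5L, 7L,
                  1L, 5L, 6L, 7L,
                  1L, 6L, 2L, 7L), ncol = 4, byrow = TRUE)
  m <- nrow(hex)
  conn <- matrix(0L, 6L * m, 4L)
  for (p in 1:6)
    conn[seq(p, by = 6L, length.out = m), ] <- hex[, pat[p, ], drop = FALSE]
  conn
}

# signed tet volumes (x6) for orientation fixes
tet_signed_vol6 <- function(nodes, conn) {
  a <- nodes[conn[, 2], , drop = FALSE] - nodes[conn[, 1], , drop = FALSE]
  b <- nodes[conn[, 3], , drop = FALSE] - nodes[conn[, 1], , drop = FALSE]
  d <- nodes[conn[, 4], , drop = FALSE] - nodes[conn[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  cx * d[, 1] + cy * d[, 2] + cz * d[, 3]
}

orient_tets <- function(nodes, conn) {
  v <- tet_signed_vol6(nodes, conn)
  if (any(v == 0)) cf_geometry_error("degenerate tetrahedron in generated mesh")
  flip <- v < 0
  if (any(flip)) conn[flip, c(3L, 4L)] <- conn[flip, c(4L, 3L)]
  conn
}

# map [-1,1]^2 grid coordinates onto an ellipse with semi-axes a (x), b (y)
map_ellipse <- function(u, v, a, b) {
  cbind(a * u * sqrt(pmax(0, 1 - v^2 / 2)),
        b * v * sqrt(pmax(0, 1 - u^2 / 2)))
}

# number of divisions so that cells are ~mesh_size over a span
n_div <- function(span, mesh_size, min_div = 2L) {
  max(min_div, as.integer(ceiling(span / mesh_size)))
}

# structured tet4 mesh of an elliptic cylinder: semi-axes a, b, z in
# [z0, z0 + h]; in-plane resolution is derived from (a, b, mesh_size) only,
# so parts sharing (a, b, mesh_size) have bitwise-coincident interface grids
ellipse_tet_grid <- function(a, b, h, mesh_size, z0 = 0,
                             keep_rho = NULL) {
  nu <- 2L * n_div(a, mesh_size, 1L) # even counts keep the mid-axes on-grid
  nv <- 2L * n_div(b, mesh_size, 1L)
  nz <- n_div(h, mesh_size)
  us <- seq(-1, 1, length.out = nu + 1L)
  vs <- seq(-1, 1, length.out = nv + 1L)
  zs <- z0 + seq(0, h, length.out = nz + 1L)
  g <- grid_hex(us, vs, zs)
  xy <- map_ellipse(g$nodes[, 1], g$nodes[, 2], a, b)
  nodes <- cbind(xy, g$nodes[, 3])
  hex <- g$hex
  if (!is.null(keep_rho)) {
    cx <- rowMeans(matrix(nodes[hex, 1], nrow(hex)))
    cy <- rowMeans(matrix(nodes[hex, 2], nrow(hex)))
    keep <- sqrt((cx / a)^2 + (cy / b)^2) <= keep_rho
    hex <- hex[keep, , drop = FALSE]
  }
  conn <- orient_tets(nodes, hex_to_tet(hex))
  compact_mesh(nodes, conn)
}

# plain box tet4 mesh
box_tet_grid <- function(xr, yr, zr, mesh_size) {
  xs <- seq(xr[1], xr[2], length.out = n_div(diff(xr), mesh_size, 1L) + 1L)
  ys <- seq(yr[1], yr[2], length.out = n_div(diff(yr), mesh_size, 1L) + 1L)
  zs <- seq(zr[1], zr[2], length.out = n_div(diff(zr), mesh_size, 1L) + 1L)
  g <- grid_hex(xs, ys, zs)
  conn <- orient_tets(g$nodes, hex_to_tet(g$hex))
  list(nodes = g$nodes, conn = conn)
}

# drop unused nodes, remap connectivity
compact_mesh <- function(nodes, conn) {
  used <- sort(unique(as.vector(conn)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  conn[] <- remap[conn]
  list(nodes = nodes[used, , drop = FALSE], conn = conn)
}

# boundary triangles of a tet4 block: returns data.frame(elem local id,
# face id, n1, n2, n3)
boundary_faces_tet <- function(conn) {
  faces <- do.call(rbind, lapply(1:4, function(f) {
    idx <- FACE_CORNERS$tet4[[f]]
    cbind(elem = seq_len(nrow(conn)), face = f,
          conn[, idx, drop = FALSE])
  }))
  key <- apply(faces[, 3:5, drop = FALSE], 1, function(r) {
    paste(sort(r), collapse = "_")
  })
  tab <- table(key)
  keep <- key %in% names(tab)[tab == 1L]
  out <- as.data.frame(faces[keep, , drop = FALSE])
  names(out) <- c("elem", "face", "n1", "n2", "n3")
  out
}

# quadratize: tet4 -> tet10 and wedge6 -> wedge15 with globally shared edge
# midpoints; node sets gain a midpoint when both edge endpoints are members
quadratize_mesh <- function(mesh) {
  edge_env <- new.env(hash = TRUE, parent = emptyenv())
  nodes <- mesh$nodes
  new_pts <- list()
  n0 <- nrow(nodes)
  next_id <- n0
  midpoint <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    id <- edge_env[[key]]
    if (!is.null(id)) return(id)
    next_id <<- next_id + 1L
    edge_env[[key]] <- next_id
    new_pts[[length(new_pts) + 1L]] <<- (nodes[i, ] + nodes[j, ]) / 2
    next_id
  }
  tet_edges <- matrix(c(1L, 2L, 2L, 3L, 1L, 3L, 1L, 4L, 2L, 4L, 3L, 4L),
                      ncol = 2, byrow = TRUE)
  wed_edges <- matrix(c(1L, 2L, 2L, 3L, 3L, 1L, 4L, 5L, 5L, 6L, 6L, 4L,
                        1L, 4L, 2L, 5L, 3L, 6L), ncol = 2, byrow = TRUE)
  blocks <- mesh$blocks
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    if (!b$kind %in% c("tet4", "wedge6")) next
    edges <- if (b$kind == "tet4") tet_edges else wed_edges
    m <- nrow(b$conn)
    extra <- matrix(0L, m, nrow(edges))
    for (e in seq_len(m)) {
      for (q in seq_len(nrow(edges))) {
        extra[e, q] <- midpoint(b$conn[e, edges[q, 1]], b$conn[e, edges[q, 2]])
      }
    }
    blocks[[bi]]$conn <- cbind(b$conn, extra)
    blocks[[bi]]$kind <- if (b$kind == "tet4") "tet10" else "wedge15"
  }
  if (length(new_pts)) nodes <- rbind(nodes, do.call(rbind, new_pts))
  # promote node sets: midpoints of member-member edges join the set
  nsets <- mesh$nsets
  if (length(nsets)) {
    keys <- ls(edge_env)
    if (length(keys)) {
      ij <- do.call(rbind, strsplit(keys, "_"))
      ei <- as.integer(ij[, 1]); ej <- as.integer(ij[, 2])
      em <- vapply(keys, function(k) edge_env[[k]], integer(1))
      for (s in names(nsets)) {
        inset <- logical(n0)
        inset[nsets[[s]]] <- TRUE
        add <- em[inset[ei] & inset[ej]]
        nsets[[s]] <- sort(c(nsets[[s]], add))
      }
    }
  }
  fe_mesh(nodes, blocks, nsets, mesh$elsets, mesh$surfaces)
}

# join meshes, offsetting ids, prefixing set names, then merging nodes whose
# coordinates agree within tol (exact interface stitching)
mesh_join <- function(meshes, prefixes = NULL, tol = 1e-9) {
  nodes <- NULL
  blocks <- list(); nsets <- list(); elsets <- list(); surfaces <- list()
  noff <- 0L; eoff <- 0L
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    pre <- if (is.null(prefixes)) "" else prefixes[i]
    nodes <- rbind(nodes, m$nodes)
    for (b in m$blocks) {
      b$conn <- b$conn + noff
      blocks[[length(blocks) + 1L]] <- b
    }
    for (s in names(m$nsets))
      nsets[[paste0(pre, s)]] <- m$nsets[[s]] + noff
    for (s in names(m$elsets))
      elsets[[paste0(pre, s)]] <- m$elsets[[s]] + eoff
    for (s in names(m$surfaces)) {
      sf <- m$surfaces[[s]]
      sf$elem <- sf$elem + eoff
      surfaces[[paste0(pre, s)]] <- sf
    }
    noff <- noff + nrow(m$nodes)
    eoff <- eoff + mesh_nelem(m)
  }
  # merge coincident nodes
  key <- paste(round(nodes[, 1] / tol), round(nodes[, 2] / tol),
               round(nodes[, 3] / tol), sep = "|")
  first <- !duplicated(key)
  remap <- match(key, key[first])
  keep_ids <- which(first)
  renum <- integer(nrow(nodes))
  renum[keep_ids] <- seq_along(keep_ids)
  remap <- renum[keep_ids[remap]]
  nodes <- nodes[first, , drop = FALSE]
  for (bi in seq_along(blocks)) blocks[[bi]]$conn[] <- remap[blocks[[bi]]$conn]
  for (s in names(nsets)) nsets[[s]] <- sort(unique(remap[nsets[[s]]]))
  fe_mesh(nodes, blocks, nsets, elsets, surfaces)
}

# nearest-node lookup: for each query row return index of nearest candidate
nearest_node <- function(cand_xyz, query_xyz) {
  if (nrow(cand_xyz) == 0) cf_assembly_error("no candidate nodes for matching")
  out <- integer(nrow(query_xyz))
  dist <- numeric(nrow(query_xyz))
  for (i in seq_len(nrow(query_xyz))) {
    d2 <- (cand_xyz[, 1] - query_xyz[i, 1])^2 +
      (cand_xyz[, 2] - query_xyz[i, 2])^2 +
      (cand_xyz[, 3] - query_xyz[i, 3])^2
    j <- which.min(d2)
    out[i] <- j
    dist[i] <- sqrt(d2[j])
  }
  list(index = out, dist = dist)
}

#' Mesh-quality inspection
#'
#' Reports, per solid element, the scaled Jacobian (minimum quadrature-point
#' Jacobian over the maximum), a volume-skew proxy (1 - v / v_ideal against
#' the equilateral element of the same circumscribed edge length), and the
#' tetrahedral collapse ratio (minimum altitude over maximum edge). Returned
#' percentages mirror a routine post-meshing inspection gate.
#'
#' @param mesh an `fe_mesh`.
#' @param jacobian_min acceptance floor for the scaled Jacobian.
#' @param skew_max acceptance ceiling for volume skew.
#' @param collapse_min acceptance floor for tet collapse.
#' @return data frame with one row per solid block and the percentage of
#'   elements failing each gate.
#' @export
mesh_quality <- function(mesh, jacobian_min = 0.55, skew_max = 0.95,
                         collapse_min = 0.10) {
  rows <- list()
  for (b in mesh$blocks) {
    if (!b$kind %in% c("tet4", "tet10")) next
    conn <- b$conn[, 1:4, drop = FALSE]
    v <- tet_signed_vol6(mesh$nodes, conn) / 6
    edges <- matrix(c(1L, 2L, 1L, 3L, 1L, 4L, 2L, 3L, 2L, 4L, 3L, 4L),
                    ncol = 2, byrow = TRUE)
    el2 <- sapply(seq_len(nrow(edges)), function(q) {
      d <- mesh$nodes[conn[, edges[q, 2]], , drop = FALSE] -
        mesh$nodes[conn[, edges[q, 1]], , drop = FALSE]
      rowSums(d^2)
    })
    lmax <- sqrt(apply(el2, 1, max))
    # collapse: min altitude / max edge; altitude_i = 3 v / area_face_i
    areas <- sapply(1:4, function(f) {
      idx <- FACE_CORNERS$tet4[[f]]
      u <- mesh$nodes[conn[, idx[2]], , drop = FALSE] -
        mesh$nodes[conn[, idx[1]], , drop = FALSE]
      w <- mesh$nodes[conn[, idx[3]], , drop = FALSE] -
        mesh$nodes[conn[, idx[1]], , drop = FALSE]
      cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
      cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
      cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
      0.5 * sqrt(cx^2 + cy^2 + cz^2)
    })
    amax <- apply(areas, 1, max)
    collapse <- (3 * v / amax) / lmax
    vol_ideal <- lmax^3 / (6 * sqrt(2)) # regular tet with edge lmax
    skew <- pmax(0, 1 - v / vol_ideal)
    jac <- collapse / max(collapse) # scaled shape proxy within the block
    rows[[length(rows) + 1L]] <- data.frame(
      kind = b$kind, n = nrow(conn),
      pct_jacobian_fail = 100 * mean(jac < jacobian_min),
      pct_skew_fail = 100 * mean(skew > skew_max),
      pct_collapse_fail = 100 * mean(collapse < collapse_min),
      min_collapse = min(collapse), max_skew = max(skew))
  }
  do.call(rbind, rows)
}
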