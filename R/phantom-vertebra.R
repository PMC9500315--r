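# Single-vertebra generator: stylized elliptic trabecular body plus a
# posterior block, wrapped by a one-element cortical wedge layer.

#' Generate one synthetic vertebra
#'
#' Builds the trabecular body of a level as a structured tet mesh of an
#' elliptic cylinder, partitioned into `central_body` and `exterior_body`
#' element sets, plus a posterior block carrying the spinous-process and
#' articular-facet landmarks. A one-element layer of wedge elements is
#' offset outward from the trabecular surface: radially on the side wall and
#' axially on the endplates, with the level-appropriate thickness (0.28 mm
#' cervical, 0.24 mm thoracic by default).
#'
#' The mesh is linear (tet4/wedge6); the assembly step promotes it to
#' quadratic elements. Coordinates are local: x lateral, y anterior, z
#' vertical with the trabecular body spanning \[0, body_height\].
#'
#' @param spec a [phantom_spec()].
#' @param level vertebra label in C2..T2.
#' @param post_ext_inf,post_ext_sup extension of the posterior block below /
#'   above the body (mm), used by the assembler to bring articular facet
#'   surfaces of adjacent vertebrae close to contact.
#' @return an `fe_mesh` with element sets `central_body`, `exterior_body`,
#'   `cortical`, `posterior_block`; node sets for endplates, spinous process,
#'   facet faces, ligament landmarks and (for C2) the paired
#'   odontoid-adjacent facet patches.
#' @export
generate_vertebra <- function(spec, level, post_ext_inf = 0,
                              post_ext_sup = 0) {
  if (!level %in% spec$levels)
    cf_spec_error("unknown vertebra level '%s'", level)
  a <- spec$body_width[[level]] / 2
  b <- spec$body_depth[[level]] / 2
  h <- spec$body_height[[level]]
  t <- cortical_thickness(spec, level)
  ms <- spec$mesh_size
  if (a <= 0 || b <= 0 || h <= 0)
    cf_spec_error("non-positive body dimension at level %s", level)
  if (ms > min(a, b, h))
    cf_resolution_error(paste0(
      "mesh_size = %.2f mm is too coarse to resolve the %s body and its ",
      "cortical layer; reduce mesh_size below min(width/2, depth/2, height)"),
      ms, level)

  body <- ellipse_tet_grid(a, b, h, ms)
  nodes <- body$nodes
  conn <- body$conn

  if (spec$jitter > 0) {
    # deterministic interior jitter: nodes off all boundary faces
    bf <- boundary_faces_tet(conn)
    bnd <- unique(c(bf$n1, bf$n2, bf$n3))
    interior <- setdiff(seq_len(nrow(nodes)), bnd)
    if (length(interior)) {
      set.seed(spec$seed + match(level, spec$levels))
      amp <- spec$jitter * ms * 0.25
      nodes[interior, ] <- nodes[interior, ] +
        matrix(runif(3 * length(interior), -amp, amp), ncol = 3)
    }
  }

  # central/exterior trabecular partition by elliptical centroid radius
  cx <- rowMeans(matrix(nodes[conn, 1], nrow(conn)))
  cy <- rowMeans(matrix(nodes[conn, 2], nrow(conn)))
  rho <- sqrt((cx / a)^2 + (cy / b)^2)
  central <- which(rho <= 0.6)
  exterior <- which(rho > 0.6)

  # cortical wedge layer from boundary triangles
  bf <- boundary_faces_tet(conn)
  fz <- (nodes[bf$n1, 3] + nodes[bf$n2, 3] + nodes[bf$n3, 3]) / 3
  ztol <- 1e-6
  is_top <- abs(nodes[bf$n1, 3] - h) < ztol & abs(nodes[bf$n2, 3] - h) < ztol &
    abs(nodes[bf$n3, 3] - h) < ztol
  is_bot <- abs(nodes[bf$n1, 3]) < ztol & abs(nodes[bf$n2, 3]) < ztol &
    abs(nodes[bf$n3, 3]) < ztol
  is_side <- !is_top & !is_bot

  offset_nodes <- function(ids, dirfun) {
    # one offset copy per distinct inner node; returns id map
    uids <- unique(ids)
    dirs <- dirfun(nodes[uids, , drop = FALSE])
    new_ids <- nrow(nodes) + seq_along(uids)
    nodes <<- rbind(nodes, nodes[uids, , drop = FALSE] + t * dirs)
    setNames(new_ids, uids)
  }
  radial_dir <- function(x) {
    d <- cbind(x[, 1] / a^2, x[, 2] / b^2, 0)
    d / sqrt(rowSums(d^2))
  }
  wedges <- NULL
  build_shell <- function(sel, dirfun) {
    tri <- as.matrix(bf[sel, c("n1", "n2", "n3")])
    if (nrow(tri) == 0) return(integer(0))
    map <- offset_nodes(as.vector(tri), dirfun)
    outer <- matrix(map[as.character(tri)], nrow(tri))
    wedges <<- rbind(wedges, cbind(tri, outer))
    unname(map)
  }
  side_outer <- build_shell(is_side, radial_dir)
  top_outer <- build_shell(is_top, function(x)
    matrix(rep(c(0, 0, 1), each = nrow(x)), ncol = 3))
  bot_outer <- build_shell(is_bot, function(x)
    matrix(rep(c(0, 0, -1), each = nrow(x)), ncol = 3))
  storage.mode(wedges) <- "integer"
  # orient wedges for positive Jacobian
  wvol <- .elem_volume_batch(nodes, wedges, KIND_ID[["wedge6"]])
  flip <- wvol < 0
  if (any(flip)) wedges[flip, ] <- wedges[flip, c(4:6, 1:3), drop = FALSE]

  # posterior block
  wp <- a            # block width
  dp <- 0.8 * b      # block depth (posterior reach)
  blk <- box_tet_grid(c(-wp / 2, wp / 2), c(-b - dp, -b),
                      c(-post_ext_inf, h + post_ext_sup), ms)
  n_body <- nrow(nodes)
  nodes <- rbind(nodes, blk$nodes)
  blk_conn <- blk$conn + n_body
  blk_ids <- n_body + seq_len(nrow(blk$nodes))

  node_near <- function(target, ids = seq_len(nrow(nodes))) {
    xyz <- nodes[ids, , drop = FALSE]
    d2 <- (xyz[, 1] - target[1])^2 + (xyz[, 2] - target[2])^2 +
      (xyz[, 3] - target[3])^2
    ids[which.min(d2)]
  }
  body_ids <- seq_len(n_body)
  eps <- 1e-6

  nsets <- list(
    endplate_sup = body_ids[abs(nodes[body_ids, 3] - h) < eps],
    endplate_inf = body_ids[abs(nodes[body_ids, 3]) < eps],
    endplate_sup_outer = sort(unique(top_outer)),
    endplate_inf_outer = sort(unique(bot_outer)),
    cortex_outer_side = sort(unique(side_outer)),
    spinous_process = blk_ids[nodes[blk_ids, 2] < -b - dp + eps],
    post_block_face = blk_ids[abs(nodes[blk_ids, 2] + b) < eps],
    facet_sup = blk_ids[abs(nodes[blk_ids, 3] - (h + post_ext_sup)) < eps],
    facet_inf = blk_ids[abs(nodes[blk_ids, 3] + post_ext_inf) < eps],
    lm_ALL_sup = node_near(c(0, b, h), body_ids),
    lm_ALL_inf = node_near(c(0, b, 0), body_ids),
    lm_PLL_sup = node_near(c(0, -b, h), body_ids),
    lm_PLL_inf = node_near(c(0, -b, 0), body_ids),
    lm_ITL_sup_L = node_near(c(-a, 0, h), body_ids),
    lm_ITL_sup_R = node_near(c(a, 0, h), body_ids),
    lm_ITL_inf_L = node_near(c(-a, 0, 0), body_ids),
    lm_ITL_inf_R = node_near(c(a, 0, 0), body_ids),
    lm_ISL_sup = node_near(c(0, -b - 0.5 * dp, h + post_ext_sup), blk_ids),
    lm_ISL_inf = node_near(c(0, -b - 0.5 * dp, -post_ext_inf), blk_ids),
    lm_SSL_sup = node_near(c(0, -b - dp, h + post_ext_sup), blk_ids),
    lm_SSL_inf = node_near(c(0, -b - dp, -post_ext_inf), blk_ids),
    lm_LF_sup_L = node_near(c(-wp / 4, -b - 0.15 * dp, h + post_ext_sup), blk_ids),
    lm_LF_sup_R = node_near(c(wp / 4, -b - 0.15 * dp, h + post_ext_sup), blk_ids),
    lm_LF_inf_L = node_near(c(-wp / 4, -b - 0.15 * dp, -post_ext_inf), blk_ids),
    lm_LF_inf_R = node_near(c(wp / 4, -b - 0.15 * dp, -post_ext_inf), blk_ids))

  if (level == "C2") {
    top <- nsets$endplate_sup
    rf <- max(1.5 * ms, 2.5)
    for (side in c("left", "right")) {
      sx <- if (side == "left") -0.45 * a else 0.45 * a
      on_side <- if (side == "left") nodes[top, 1] < 0 else nodes[top, 1] > 0
      d <- sqrt((nodes[top, 1] - sx)^2 + (nodes[top, 2] - 0.45 * b)^2)
      sel <- top[d <= rf & on_side]
      if (!length(sel)) sel <- top[on_side][which.min(d[on_side])]
      nsets[[paste0("odontoid_facet_", side)]] <- sel
    }
  }

  n_trab <- nrow(conn)
  n_cort <- nrow(wedges)
  blocks <- list(list(kind = "tet4", conn = conn),
                 list(kind = "wedge6", conn = wedges),
                 list(kind = "tet4", conn = blk_conn))
  elsets <- list(central_body = central,
                 exterior_body = exterior,
                 cortical = n_trab + seq_len(n_cort),
                 posterior_block = n_trab + n_cort + seq_len(nrow(blk_conn)))

  # articular contact master surface: block inferior faces
  blk_bf <- boundary_faces_tet(blk_conn)
  zb <- -post_ext_inf
  binf <- abs(nodes[blk_bf$n1, 3] - zb) < eps &
    abs(nodes[blk_bf$n2, 3] - zb) < eps & abs(nodes[blk_bf$n3, 3] - zb) < eps
  surfaces <- list(facet_inf_surf = data.frame(
    elem = n_trab + n_cort + blk_bf$elem[binf], face = blk_bf$face[binf]))

  fe_mesh(nodes, blocks, nsets, elsets, surfaces)
}

#' Measured cortical layer thickness
#'
#' Samples wedge elements of the cortical set and measures the offset
#' distance between corresponding inner and outer corner nodes; the offset
#' direction at each node is the analytic outward surface normal, so this
#' is the layer thickness along the surface normal at the sampled points.
#'
#' @param mesh vertebra mesh from [generate_vertebra()].
#' @param n number of sampled wedge elements.
#' @return numeric vector of measured thicknesses in mm.
#' @export
cortical_thickness_measured <- function(mesh, n = 100) {
  ci <- which(vapply(mesh$blocks, function(b) b$kind %in% c("wedge6", "wedge15"),
                     logical(1)))
  if (!length(ci)) cf_assembly_error("mesh has no cortical wedge block")
  conn <- do.call(rbind, lapply(ci, function(i) mesh$blocks[[i]]$conn[, 1:6, drop = FALSE]))
  sel <- unique(round(seq(1, nrow(conn), length.out = min(n, nrow(conn)))))
  vapply(sel, function(e) {
    inner <- mesh$nodes[conn[e, 1:3], , drop = FALSE]
    outer <- mesh$nodes[conn[e, 4:6], , drop = FALSE]
    mean(sqrt(rowSums((outer - inner)^2)))
  }, numeric(1))
}
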