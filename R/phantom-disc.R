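# Intervertebral disc generator: concentric nucleus pulposus (NP) core and
# anulus fibrosus (AF) ring filling the inter-endplate gap.

# barrel-shape factor so that the NP keeps the requested endplate area share
# while bulging to the requested volume share:
#   np boundary semi-axes = sqrt(f_area) * s(z) * (a, b),
#   s(z) = 1 + beta * sin(pi z / h),  mean(s^2) = f_vol / f_area
np_bulge_beta <- function(f_area, f_vol) {
  # mean over z of s^2 = 1 + beta * 4/pi + beta^2 / 2
  ratio <- f_vol / f_area
  disc <- (4 / pi)^2 + 2 * (ratio - 1)
  (-4 / pi + sqrt(disc))
}

#' Generate a synthetic intervertebral disc
#'
#' Fills the inter-endplate gap of a junction with a structured elliptic
#' cylinder partitioned into an inner nucleus pulposus core and an outer
#' anulus fibrosus ring. The NP boundary bulges at mid-height so that the
#' endplate area share equals `np_area_fraction` while the volume share
#' equals `np_volume_fraction`. The superior and inferior disc surfaces are
#' exposed as node sets `disc_sup` / `disc_inf` for tying to the adjacent
#' endplates.
#'
#' @param spec a [phantom_spec()].
#' @param junction junction label, e.g. `"C5-C6"`.
#' @param z0 inferior disc surface height (mm) in assembly coordinates.
#' @return an `fe_mesh` with element sets `NP` and `AF`.
#' @export
generate_disc <- function(spec, junction, z0 = 0) {
  if (!junction %in% spec$junctions)
    cf_spec_error("unknown junction '%s'", junction)
  validate_phantom_spec(spec)
  lev <- strsplit(junction, "-")[[1]]
  a <- min(spec$body_width[lev]) / 2
  b <- min(spec$body_depth[lev]) / 2
  h <- spec$disc_height[[junction]]
  if (h <= 0) cf_spec_error("disc_height must be positive at %s", junction)
  fa <- spec$np_area_fraction
  fv <- spec$np_volume_fraction
  beta <- np_bulge_beta(fa, fv)

  g <- ellipse_tet_grid(a, b, h, spec$mesh_size, z0 = z0)
  nodes <- g$nodes
  conn <- g$conn
  cx <- rowMeans(matrix(nodes[conn, 1], nrow(conn)))
  cy <- rowMeans(matrix(nodes[conn, 2], nrow(conn)))
  cz <- rowMeans(matrix(nodes[conn, 3], nrow(conn))) - z0
  s <- 1 + beta * sin(pi * cz / h)
  r_np <- sqrt(fa) * s
  rho <- sqrt((cx / a)^2 + (cy / b)^2)
  np <- which(rho <= r_np)
  af <- which(rho > r_np)
  eps <- 1e-6
  ids <- seq_len(nrow(nodes))
  m <- fe_mesh(nodes, list(list(kind = "tet4", conn = conn)),
               nsets = list(disc_sup = ids[abs(nodes[, 3] - (z0 + h)) < eps],
                            disc_inf = ids[abs(nodes[, 3] - z0) < eps]),
               elsets = list(NP = np, AF = af))
  attr(m, "np_geom") <- list(a = a, b = b, f_area = fa, f_vol = fv,
                             beta = beta)
  m
}

#' Measured NP area and volume shares of a disc mesh
#'
#' @param disc disc mesh from [generate_disc()].
#' @return list with `area_share` (NP share of the inferior endplate area)
#'   and `volume_share` (NP share of the disc volume).
#' @export
disc_np_shares <- function(disc) {
  vol <- element_volumes(disc)
  v_np <- sum(vol[disc$elsets$NP])
  v_all <- sum(vol)
  # endplate area share from the bottom element layer footprint
  zmin <- min(disc$nodes[, 3])
  cent <- element_centroids(disc)
  conn <- disc$blocks[[1]]$conn[, 1:4, drop = FALSE]
  touches <- matrix(abs(disc$nodes[conn, 3] - zmin) < 1e-6, nrow(conn))
  bottom <- which(rowSums(touches) == 3L) # one triangular face on the plate
  tri_area <- vapply(bottom, function(e) {
    idx <- conn[e, ][touches[e, ]]
    u <- disc$nodes[idx[2], ] - disc$nodes[idx[1], ]
    w <- disc$nodes[idx[3], ] - disc$nodes[idx[1], ]
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    0.5 * sqrt(sum(cr^2))
  }, numeric(1))
  # endplate area share: triangles inside the NP boundary trace at the
  # plate plane (where the bulge factor is 1)
  geom <- attr(disc, "np_geom")
  if (!is.null(geom)) {
    tx <- vapply(bottom, function(e) {
      idx <- conn[e, ][touches[e, ]]
      mean(disc$nodes[idx, 1])
    }, numeric(1))
    ty <- vapply(bottom, function(e) {
      idx <- conn[e, ][touches[e, ]]
      mean(disc$nodes[idx, 2])
    }, numeric(1))
    rho <- sqrt((tx / geom$a)^2 + (ty / geom$b)^2)
    in_np <- rho <= sqrt(geom$f_area)
  } else {
    in_np <- bottom %in% disc$elsets$NP
  }
  list(area_share = sum(tri_area[in_np]) / sum(tri_area),
       volume_share = v_np / v_all)
}
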