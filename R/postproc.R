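# Evaluation quantities: principal strains, the principal-strain damage
# index, segmental range of motion and per-trajectory strain summaries.

#' Principal strains of symmetric strain tensors
#'
#' Accepts either an n x 6 matrix of tensor components (xx, yy, zz, xy, yz,
#' xz with engineering shear) or a single symmetric 3 x 3 tensor matrix.
#' Eigenvalues are returned sorted descending (e1 >= e2 >= e3).
#'
#' @param strain strain input as above.
#' @param tol asymmetry tolerance for 3 x 3 input.
#' @return n x 3 matrix with columns `e1`, `e2`, `e3`.
#' @export
principal_strains <- function(strain, tol = 1e-10) {
  if (is.matrix(strain) && nrow(strain) == 3 && ncol(strain) == 3) {
    if (max(abs(strain - t(strain))) > tol * max(1, max(abs(strain))))
      cf_domain_error("strain tensor is not symmetric")
    strain <- matrix(c(strain[1, 1], strain[2, 2], strain[3, 3],
                       2 * strain[1, 2], 2 * strain[2, 3], 2 * strain[1, 3]),
                     nrow = 1)
  }
  strain <- as.matrix(strain)
  if (ncol(strain) != 6) cf_domain_error("expect n x 6 strain components")
  keep <- stats::complete.cases(strain)
  out <- matrix(NA_real_, nrow(strain), 3,
                dimnames = list(NULL, c("e1", "e2", "e3")))
  if (any(keep)) out[keep, ] <- .principal_batch(strain[keep, , drop = FALSE])
  out
}

#' Nodal-averaged principal strains
#'
#' Volume-weighted average of element strain tensors at each node, then
#' principal decomposition (the surface-map variant of the per-element
#' measure).
#'
#' @param result a `solve_result`.
#' @param model the model that produced it.
#' @return n_nodes x 3 matrix of principal strains (NA at nodes that touch
#'   no solid element).
#' @export
nodal_principal_strains <- function(result, model) {
  mesh <- model$mesh
  acc <- matrix(0, nrow(mesh$nodes), 6)
  wt <- numeric(nrow(mesh$nodes))
  vol <- element_volumes(mesh)
  off <- block_offsets(mesh)
  for (bi in seq_along(mesh$blocks)) {
    b <- mesh$blocks[[bi]]
    if (!b$kind %in% names(KIND_ID) || nrow(b$conn) == 0) next
    ids <- off[bi] + seq_len(nrow(b$conn))
    for (e in seq_len(nrow(b$conn))) {
      nd <- b$conn[e, ]
      acc[nd, ] <- acc[nd, ] + rep(vol[ids[e]], length(nd)) %o%
        result$strain[ids[e], ]
      wt[nd] <- wt[nd] + vol[ids[e]]
    }
  }
  touched <- wt > 0
  acc[touched, ] <- acc[touched, ] / wt[touched]
  out <- matrix(NA_real_, nrow(mesh$nodes), 3,
                dimnames = list(NULL, c("e1", "e2", "e3")))
  out[touched, ] <- .principal_batch(acc[touched, , drop = FALSE])
  out
}

#' Damage thresholds for the principal-strain criterion
#'
#' @param tension_limit tensile principal-strain limit (default +0.015).
#' @param compression_limit compressive limit (default -0.020).
#' @return an object of class `damage_thresholds`.
#' @export
damage_thresholds <- function(tension_limit = 0.015,
                              compression_limit = -0.020) {
  if (!(tension_limit > 0) || !(compression_limit < 0))
    cf_domain_error("need tension_limit > 0 > compression_limit")
  structure(list(tension_limit = tension_limit,
                 compression_limit = compression_limit),
            class = "damage_thresholds")
}

#' Principal-strain damage index
#'
#' `Di = max(e1 / e_t, e3 / e_c)` with each ratio floored at zero: the
#' tensile ratio counts only when e1 > 0 and the compressive ratio only
#' when e3 < 0, so Di >= 0 always. An element is regarded as broken when
#' Di >= 1.
#'
#' @param ps principal strains: n x 3 matrix (columns e1, e2, e3) as from
#'   [principal_strains()], or a vector `c(e1, e3)` for a single element.
#' @param th a [damage_thresholds()].
#' @return numeric vector of damage indices.
#' @export
damage_index <- function(ps, th = damage_thresholds()) {
  if (is.null(dim(ps))) {
    if (length(ps) == 2) ps <- matrix(c(ps[1], NA, ps[2]), 1)
    else ps <- matrix(ps, 1)
  }
  e1 <- ps[, 1]; e3 <- ps[, ncol(ps)]
  pmax(pmax(e1, 0) / th$tension_limit,
       pmin(e3, 0) / th$compression_limit)
}

#' Per-region damage report
#'
#' Computes the damage index of every solid element, the maximum per
#' inspected element set and per vertebra, and broken flags (Di >= 1).
#'
#' @param result a `solve_result`.
#' @param model the model.
#' @param th a [damage_thresholds()].
#' @param sets element set names to inspect; default: every central body,
#'   screw trajectory and spacer-contacting endplate set (the regions the
#'   safety verdict examines).
#' @return an object of class `damage_report`.
#' @export
damage_report <- function(result, model, th = damage_thresholds(),
                          sets = NULL) {
  if (is.null(sets)) sets <- verdict_sets(model)
  ps <- principal_strains(result$strain)
  di <- damage_index(ps, th)
  rows <- lapply(sets, function(s) {
    ids <- model$mesh$elsets[[s]]
    if (is.null(ids) || !length(ids))
      cf_assembly_error("element set '%s' missing from model", s)
    dmax <- max(di[ids], na.rm = TRUE)
    data.frame(set = s, n_elem = length(ids), max_di = dmax,
               elem_at_max = ids[which.max(di[ids])],
               broken = dmax >= 1)
  })
  tab <- do.call(rbind, rows)
  structure(list(motion = if (!is.null(result$load_case))
    result$load_case$motion else NA_character_,
    thresholds = th, di = di, principal = ps, table = tab),
    class = "damage_report")
}

#' @export
print.damage_report <- function(x, ...) {
  cat(sprintf("<damage_report> motion: %s, max Di = %.3f (%s)\n",
              x$motion, max(x$table$max_di),
              if (any(x$table$broken)) "BROKEN elements present" else
                "all below 1"))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# element sets inspected by the safety verdict
verdict_sets <- function(model) {
  es <- names(model$mesh$elsets)
  c(grep("_central_body$", es, value = TRUE),
    grep("^trajectory_", es, value = TRUE),
    grep("^spacer_endplate_", es, value = TRUE))
}

# best-fit rigid rotation (Kabsch) of a landmark cloud under displacements
fit_rotation <- function(X, Xd) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Xd, 2, colMeans(Xd))
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# rotation vector (axis * angle, radians) from a rotation matrix
rotation_vector <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  ang <- acos(ca)
  if (ang < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  ax * ang
}

# landmark node ids of one vertebra (endplates + spinous process)
level_landmark_nodes <- function(model, level) {
  sets <- paste0(level, "_", c("endplate_sup", "endplate_inf",
                               "spinous_process"))
  ids <- sort(unique(unlist(model$mesh$nsets[sets], use.names = FALSE)))
  if (length(ids) < 3) cf_geometry_error("level %s has too few landmarks", level)
  X <- model$mesh$nodes[ids, , drop = FALSE]
  if (qr(sweep(X, 2, colMeans(X)))$rank < 2)
    cf_geometry_error("landmarks of level %s are collinear", level)
  ids
}

#' Segmental range of motion
#'
#' Best-fit rigid rotation of each vertebra's landmark cloud
#' (least-squares orthogonal fit), relative rotation
#' `R_upper %*% t(R_lower)`, projected on the motion axis and reported in
#' degrees.
#'
#' @param result a `solve_result`.
#' @param model the model.
#' @param junction junction label such as `"C5-C6"`.
#' @param motion motion label defining the projection axis; defaults to the
#'   motion of the solved load case.
#' @return rotation angle in degrees (signed along the motion axis).
#' @export
segment_rom <- function(result, model, junction, motion = NULL) {
  if (is.null(motion)) {
    if (is.null(result$load_case))
      cf_spec_error("motion must be given when the result has no load case")
    motion <- result$load_case$motion
  }
  lv <- model$info$levels
  i <- match(junction, model$info$junctions)
  if (is.na(i)) cf_spec_error("unknown junction '%s'", junction)
  axis <- motion_axis(motion)
  ang <- lapply(c(lv[i], lv[i + 1]), function(l) {
    ids <- level_landmark_nodes(model, l)
    X <- model$mesh$nodes[ids, , drop = FALSE]
    fit_rotation(X, X + result$displacements[ids, , drop = FALSE])
  })
  R_rel <- ang[[1]] %*% t(ang[[2]])
  rv <- rotation_vector(R_rel)
  sum(rv * axis) * 180 / pi
}

#' ROM table over junctions and motions
#'
#' @param results named list of `solve_result`s (names = motions).
#' @param model the model.
#' @param junctions junction labels (default: all).
#' @return data frame of ROM in degrees, one row per junction, one column
#'   per motion plus `flexion_extension` (sum of the two sagittal cases)
#'   when both are present.
#' @export
rom_table <- function(results, model, junctions = NULL) {
  if (is.null(junctions)) junctions <- model$info$junctions
  tab <- data.frame(junction = junctions)
  for (m in names(results)) {
    tab[[m]] <- vapply(junctions, function(j)
      segment_rom(results[[m]], model, j, m), numeric(1))
  }
  if (all(c("flexion", "extension") %in% names(results)))
    tab$flexion_extension <- abs(tab$flexion) + abs(tab$extension)
  tab
}

#' Per-trajectory strain summary
#'
#' For each screw trajectory set: extreme tensile and compressive principal
#' strains, maximum damage index, and the arc position of the extreme
#' element relative to the screw axis (anterior/posterior half along the
#' shaft, medial/lateral and superior/inferior side), localizing potential
#' screw-plowing concentrations.
#'
#' @param result a `solve_result`.
#' @param model the model.
#' @param th a [damage_thresholds()].
#' @return data frame with one row per screw trajectory.
#' @export
trajectory_report <- function(result, model, th = damage_thresholds()) {
  es <- grep("^trajectory_", names(model$mesh$elsets), value = TRUE)
  if (!length(es)) cf_assembly_error("model has no trajectory element sets")
  ps <- principal_strains(result$strain)
  di <- damage_index(ps, th)
  cent <- element_centroids(model$mesh)
  rows <- lapply(es, function(s) {
    ids <- model$mesh$elsets[[s]]
    if (!length(ids)) cf_assembly_error("trajectory set '%s' is empty", s)
    e1 <- ps[ids, 1]; e3 <- ps[ids, 3]
    imax <- ids[which.max(di[ids])]
    cc <- cent[ids, , drop = FALSE]
    ctr <- colMeans(cc)
    pos <- cent[imax, ]
    lab <- paste0(if (pos[2] >= ctr[2]) "anterior" else "posterior", "/",
                  if (abs(pos[1]) <= abs(ctr[1])) "medial" else "lateral", "/",
                  if (pos[3] >= ctr[3]) "superior" else "inferior")
    data.frame(trajectory = sub("^trajectory_", "", s),
               n_elem = length(ids),
               max_e1 = max(e1), min_e3 = min(e3),
               max_di = max(di[ids]), elem_at_max = imax,
               position = lab)
  })
  do.call(rbind, rows)
}

#' Fixation safety verdict over the four motions
#'
#' PASS iff the maximum damage index stays below one over the central
#' vertebra bodies, the screw-trajectory sets and the spacer-contacting
#' endplate sets in all four motions; otherwise FAIL, listing the offending
#' sets and motions.
#'
#' @param reports named list of [damage_report()]s, one per motion
#'   (`flexion`, `extension`, `lateral_flexion`, `rotation`).
#' @return an object of class `safety_verdict` with fields `pass`,
#'   `max_di`, `offenders`.
#' @export
safety_verdict <- function(reports) {
  missing <- setdiff(MOTIONS, names(reports))
  if (length(missing))
    cf_spec_error("damage reports missing for motions: %s",
                  paste(missing, collapse = ", "))
  offenders <- NULL
  dmax <- -Inf
  for (m in MOTIONS) {
    tab <- reports[[m]]$table
    dmax <- max(dmax, tab$max_di)
    bad <- tab[tab$broken, , drop = FALSE]
    if (nrow(bad))
      offenders <- rbind(offenders, cbind(motion = m, bad))
  }
  structure(list(pass = is.null(offenders), max_di = dmax,
                 offenders = offenders), class = "safety_verdict")
}

#' @export
print.safety_verdict <- function(x, ...) {
  cat(sprintf("<safety_verdict> %s (max Di = %.3f)\n",
              if (x$pass) "PASS" else "FAIL", x$max_di))
  if (!x$pass) print(x$offenders, row.names = FALSE)
  invisible(x)
}

#' Contact-slip plausibility check
#'
#' Mirrors the small-sliding sanity gate: every slave-node slip distance
#' must stay below one element length.
#'
#' @param result a `solve_result`.
#' @param model the model.
#' @param element_length reference element length in mm (defaults to the
#'   phantom mesh size).
#' @return list with `ok`, `max_slip`, `element_length`, `n_exceed`.
#' @export
contact_slip_check <- function(result, model, element_length = NULL) {
  if (is.null(element_length)) element_length <- model$info$spec$mesh_size
  if (is.null(result$contact) || !nrow(result$contact))
    return(list(ok = TRUE, max_slip = 0, element_length = element_length,
                n_exceed = 0L))
  sl <- result$contact$slip
  list(ok = all(sl < element_length), max_slip = max(sl),
       element_length = element_length,
       n_exceed = sum(sl >= element_length))
}
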