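# ACDF instrumentation: interbody spacers in the spanned disc spaces, an
# anterior plate, and two screws per spanned vertebra node-equivalenced with
# plate and bone.

#' Add the ACDF instrument construct to an assembled model
#'
#' Adds PEEK spacer solids in the spanned disc spaces (in place of NP/AF,
#' which are not generated there), one titanium plate solid of the requested
#' total length on the anterior faces, and two titanium screws per spanned
#' vertebra passing through the plate into the trabecular body. Screw nodes
#' are node-equivalenced (DOF-merged) with the nearest coincident plate or
#' bone nodes. Per-screw element sets `trajectory_<level>_<side>` collect
#' the bone elements within one screw diameter of the shaft axis, and
#' `spacer_endplate_<junction>_<upper|lower>` collect the trabecular
#' elements contacting each spacer.
#'
#' @param model a `spine_model` from [assemble_spine()].
#' @param inst an [instrument_spec()].
#' @return the updated model.
#' @export
generate_instrumentation <- function(model, inst) {
  spec <- model$info$spec
  lv <- model$info$levels
  jn <- model$info$junctions
  zb <- model$info$z_bottom
  tc <- model$info$t_cort
  gap <- model$info$gap
  ms <- spec$mesh_size
  h <- spec$body_height
  quad <- identical(model$info$order, "quadratic")

  span <- inst$plate_span
  if (!all(span %in% lv)) cf_spec_error("plate_span outside modeled levels")
  if (inst$plate_standoff < 0) cf_spec_error("plate_standoff must be >= 0")
  depth <- spec$body_depth[span]
  if (any(inst$screw_length > depth))
    cf_geometry_error("screw length %.1f mm exceeds body depth %.1f mm",
                      inst$screw_length, min(depth))

  # ---- spacers ----
  for (j in inst$spanned_junctions) {
    i <- match(j, jn)
    up <- lv[i]; lo <- lv[i + 1]
    a <- min(spec$body_width[c(up, lo)]) / 2
    b <- min(spec$body_depth[c(up, lo)]) / 2
    z0 <- zb[lo] + h[lo] + tc[lo]
    sp <- ellipse_tet_grid(a, b, gap[j], ms, z0 = z0, keep_rho = 0.7)
    spm <- fe_mesh(sp$nodes, list(list(kind = "tet4", conn = sp$conn)),
                   elsets = list(spacer = seq_len(nrow(sp$conn))))
    if (quad) spm <- quadratize_mesh(spm)
    pre <- paste0("spacer_", gsub("-", "", j), "_")
    n_old <- mesh_nelem(model$mesh)
    model <- model_append_mesh(model, spm, prefix = pre)
    ids <- model$mesh$elsets[[paste0(pre, "spacer")]]
    names(model$mesh$elsets)[names(model$mesh$elsets) == paste0(pre, "spacer")] <-
      paste0("spacer_", gsub("-", "", j))
    model$mat_name[ids] <- "PEEK"

    # spacer-contacting trabecular endplate element sets
    cent <- element_centroids(model$mesh)
    for (side in c("lower", "upper")) {
      levx <- if (side == "lower") lo else up
      zi <- if (side == "lower") zb[levx] + h[levx] else zb[levx]
      sets <- paste0(levx, "_", c("central_body", "exterior_body"))
      trab <- unlist(model$mesh$elsets[sets], use.names = FALSE)
      cc <- cent[trab, , drop = FALSE]
      ax <- spec$body_width[levx] / 2; bx <- spec$body_depth[levx] / 2
      rho <- sqrt((cc[, 1] / ax)^2 + (cc[, 2] / bx)^2)
      # first trabecular element layer under the actual spacer footprint
      near <- abs(cc[, 3] - zi) <= 1.0 * ms & rho <= 0.7
      model$mesh$elsets[[paste0("spacer_endplate_", gsub("-", "", j), "_",
                                side)]] <- trab[near]
    }
  }

  # ---- plate ----
  pw <- 0.8 * min(spec$body_width[span])
  pt <- 2.0
  y0 <- max(spec$body_depth[span] / 2 + vapply(span, function(l)
    cortical_thickness(spec, l), numeric(1))) + inst$plate_standoff
  z_top_first <- zb[span[1]] + h[span[1]]
  z_bot_last <- zb[span[length(span)]]
  zc <- (z_top_first + z_bot_last) / 2
  pz <- c(zc - inst$plate_length / 2, zc + inst$plate_length / 2)
  pb <- box_tet_grid(c(-pw / 2, pw / 2), c(y0, y0 + pt), pz, ms)
  pm <- fe_mesh(pb$nodes, list(list(kind = "tet4", conn = pb$conn)),
                nsets = list(plate_inner = which(abs(pb$nodes[, 2] - y0) < 1e-9)),
                elsets = list(plate = seq_len(nrow(pb$conn))))
  if (quad) pm <- quadratize_mesh(pm)
  model <- model_append_mesh(model, pm, prefix = "plate_")
  plate_ids <- model$mesh$elsets[["plate_plate"]]
  names(model$mesh$elsets)[names(model$mesh$elsets) == "plate_plate"] <- "plate"
  model$mat_name[plate_ids] <- "titanium"
  plate_nodes <- elset_nodes(model$mesh, plate_ids)

  # ---- screws ----
  r <- inst$screw_diameter / 2
  L <- inst$screw_length
  y_head <- y0 + pt
  cell <- min(ms, 1.2 * r)
  for (levx in span) {
    a <- spec$body_width[levx] / 2
    zmid0 <- zb[levx] + h[levx] / 2
    z_s <- min(max(zmid0, pz[1] + 2.5), pz[2] - 2.5)
    if (z_s < zb[levx] + r || z_s > zb[levx] + h[levx] - r)
      cf_geometry_error("screw at %s cannot engage both plate and body", levx)
    tip_y <- y_head - L * cos(inst$screw_convergence_deg * pi / 180)
    if (tip_y < -spec$body_depth[levx] / 2)
      cf_geometry_error("screw tip at %s exits the posterior cortex", levx)
    for (side in c("left", "right")) {
      x_s <- if (side == "left") -0.25 * spec$body_width[levx] else
        0.25 * spec$body_width[levx]
      # medially convergent axis: entry at the plate, tip toward midline
      th <- inst$screw_convergence_deg * pi / 180
      u_ax <- c(if (side == "left") sin(th) else -sin(th), -cos(th), 0)
      p0 <- c(x_s, y_head, z_s)
      # axial/radial coordinates of points relative to the screw axis
      axis_coords <- function(pts) {
        v1 <- pts[, 1] - p0[1]; v2 <- pts[, 2] - p0[2]; v3 <- pts[, 3] - p0[3]
        t_ax <- v1 * u_ax[1] + v2 * u_ax[2] + v3 * u_ax[3]
        rad <- sqrt(pmax(0, v1^2 + v2^2 + v3^2 - t_ax^2))
        list(t = t_ax, rad = rad)
      }

      # carve the screw hole: trabecular elements inside the screw volume
      # become part of the screw (titanium core set, removed from the bone
      # sets) -- the surgical drilling/boolean step
      cent <- element_centroids(model$mesh)
      core_ids <- integer(0)
      for (bs in paste0(levx, "_", c("central_body", "exterior_body"))) {
        ids0 <- model$mesh$elsets[[bs]]
        ac <- axis_coords(cent[ids0, , drop = FALSE])
        inside <- ac$rad <= r + 0.1 * ms & ac$t >= 0 & ac$t <= L + 0.1 * ms
        core_ids <- c(core_ids, ids0[inside])
        model$mesh$elsets[[bs]] <- ids0[!inside]
      }
      model$mesh$elsets[[paste0("screw_core_", levx, "_", side)]] <- core_ids
      for (se in grep("^spacer_endplate_", names(model$mesh$elsets),
                      value = TRUE))
        model$mesh$elsets[[se]] <- setdiff(model$mesh$elsets[[se]], core_ids)

      g <- ellipse_tet_grid(r, r, L, cell)
      e1 <- c(-u_ax[2], u_ax[1], 0) # in-plane normal to the axis
      e2 <- c(0, 0, 1)
      scr_nodes <- cbind(
        p0[1] + g$nodes[, 1] * e1[1] + g$nodes[, 3] * u_ax[1],
        p0[2] + g$nodes[, 1] * e1[2] + g$nodes[, 3] * u_ax[2],
        p0[3] + g$nodes[, 2] * e2[3])
      conn <- orient_tets(scr_nodes, g$conn)
      sm <- fe_mesh(scr_nodes, list(list(kind = "tet4", conn = conn)),
                    elsets = list(screw = seq_len(nrow(conn))))
      if (quad) sm <- quadratize_mesh(sm)
      pre <- paste0("screw_", levx, "_", side, "_")
      model <- model_append_mesh(model, sm, prefix = pre)
      ids <- model$mesh$elsets[[paste0(pre, "screw")]]
      names(model$mesh$elsets)[names(model$mesh$elsets) ==
                                 paste0(pre, "screw")] <-
        paste0("screw_", levx, "_", side)
      model$mat_name[ids] <- "titanium"

      # embed the screw into its hosts (plate, carved core, surrounding
      # trabecular bone): each screw node follows the linear interpolation
      # of its host tet, so load transfers shape-function-distributed along
      # the whole shaft instead of through a handful of point ties
      scr_node_ids <- elset_nodes(model$mesh, ids)
      host_elems <- sort(unique(c(
        plate_ids,
        model$mesh$elsets[[paste0("screw_core_", levx, "_", side)]],
        unlist(model$mesh$elsets[paste0(levx, "_", c("central_body",
                                                     "exterior_body"))],
               use.names = FALSE))))
      model <- embed_nodes(model, scr_node_ids, host_elems,
                           what = paste0("screw ", levx, " ", side))
      if (attr(model, "last_embed_count") < 8)
        cf_geometry_error("screw %s %s engages too few bone/plate nodes",
                          levx, side)

      # trajectory element set: bone within one diameter of the shaft axis
      cent <- element_centroids(model$mesh)
      bone_sets <- paste0(levx, "_", c("central_body", "exterior_body",
                                       "cortical"))
      bone <- unlist(model$mesh$elsets[bone_sets], use.names = FALSE)
      ac <- axis_coords(cent[bone, , drop = FALSE])
      in_tr <- ac$rad <= inst$screw_diameter & ac$t >= 0 & ac$t <= L + r
      model$mesh$elsets[[paste0("trajectory_", levx, "_", side)]] <- bone[in_tr]
    }
  }
  model$info$plate <- list(y_inner = y0, width = pw, thickness = pt, z = pz)
  model
}

#' Minimum plate-to-cortex gap at a level
#'
#' Distance from the plate inner face to the anterior cortical surface of a
#' spanned vertebra; equals the plate standoff at the anterior pole up to
#' surface discretization.
#'
#' @param model an instrumented `spine_model`.
#' @param level vertebra label.
#' @return minimum gap in mm.
#' @export
plate_gap <- function(model, level) {
  if (is.null(model$info$plate)) cf_assembly_error("model has no plate")
  plate_ids <- model$mesh$nsets[["plate_plate_inner"]]
  cortex <- model$mesh$nsets[[paste0(level, "_cortex_outer_side")]]
  if (is.null(plate_ids) || is.null(cortex))
    cf_assembly_error("missing plate or cortex node sets for %s", level)
  # anterior cortex nodes facing the plate at plate height
  pz <- range(model$mesh$nodes[plate_ids, 3])
  cx <- model$mesh$nodes[cortex, , drop = FALSE]
  sel <- cx[, 2] > 0 & cx[, 3] >= pz[1] & cx[, 3] <= pz[2]
  if (!any(sel)) cf_assembly_error("no anterior cortex nodes under plate at %s", level)
  cx <- cx[sel, , drop = FALSE]
  px <- model$mesh$nodes[plate_ids, , drop = FALSE]
  dmin <- Inf
  for (i in seq_len(nrow(cx))) {
    d <- sqrt((px[, 1] - cx[i, 1])^2 + (px[, 2] - cx[i, 2])^2 +
                (px[, 3] - cx[i, 3])^2)
    dmin <- min(dmin, min(d))
  }
  dmin
}
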