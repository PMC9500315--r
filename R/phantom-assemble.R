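# Full C2-T2 phantom assembly: vertebrae, discs, ligaments, instrumentation,
# constraints and contact definitions.

#' Assemble the full synthetic C2--T2 spine model
#'
#' Generates all vertebrae and discs, promotes the mesh to quadratic
#' elements, stitches disc surfaces to the adjacent cortical endplates,
#' attaches the six ligament groups as tension-only trusses, adds the ACDF
#' instrumentation (spacers, anterior plate, screws), defines
#' articular-facet contact pairs with friction coefficient 0.07 for the
#' non-instrumented junctions, a kinematic coupling on the C2 spinous
#' process, the C2 odontoid-adjacent facet patches, and the base fixation
#' node set on the inferior surface of the lowest vertebra.
#'
#' Geometry is deterministic for a fixed `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param inst an [instrument_spec()], or `NULL` for an uninstrumented spine.
#' @param order `"quadratic"` (tet10/wedge15 solids, default) or `"linear"`.
#' @param friction facet contact friction coefficient.
#' @return a `spine_model` (materials not yet assigned; see
#'   [assign_materials()]).
#' @export
assemble_spine <- function(spec, inst = instrument_spec(),
                           order = c("quadratic", "linear"),
                           friction = 0.07) {
  order <- match.arg(order)
  validate_phantom_spec(spec)
  lv <- spec$levels
  nl <- length(lv)
  jn <- spec$junctions
  t_cort <- vapply(lv, function(l) cortical_thickness(spec, l), numeric(1))
  h <- spec$body_height

  spanned <- if (is.null(inst)) character(0) else inst$spanned_junctions
  gap <- spec$disc_height
  if (length(spanned)) gap[spanned] <- inst$spacer_heights[spanned]

  # junction i sits between level i (upper) and i+1 (lower)
  z_bottom <- numeric(nl)
  names(z_bottom) <- lv
  z_bottom[nl] <- 0
  for (i in (nl - 1):1) {
    z_bottom[i] <- z_bottom[i + 1] + h[i + 1] + t_cort[i + 1] +
      gap[i] + t_cort[i]
  }

  # posterior-block extensions so facet surfaces sit `facet_gap` apart
  e_sup <- e_inf <- setNames(numeric(nl), lv)
  for (i in seq_len(nl - 1)) {
    span <- t_cort[i] + gap[i] + t_cort[i + 1]
    e <- pmax(0, (span - spec$facet_gap) / 2)
    e_inf[i] <- e
    e_sup[i + 1] <- e
  }

  parts <- list()
  prefixes <- character(0)
  for (i in seq_len(nl)) {
    vm <- generate_vertebra(spec, lv[i], post_ext_inf = e_inf[i],
                            post_ext_sup = e_sup[i])
    vm$nodes[, 3] <- vm$nodes[, 3] + z_bottom[i]
    parts[[length(parts) + 1L]] <- vm
    prefixes <- c(prefixes, paste0(lv[i], "_"))
  }
  disc_junctions <- setdiff(jn, spanned)
  for (j in disc_junctions) {
    i <- match(j, jn)
    z0 <- z_bottom[i + 1] + h[i + 1] + t_cort[i + 1]
    dspec <- spec
    dspec$disc_height[j] <- gap[j]
    dm <- generate_disc(dspec, j, z0 = z0)
    parts[[length(parts) + 1L]] <- dm
    prefixes <- c(prefixes, paste0(gsub("-", "", j), "_"))
  }
  mesh <- mesh_join(parts, prefixes)
  if (order == "quadratic") mesh <- quadratize_mesh(mesh)

  model <- spine_model(mesh, info = list(
    spec = spec, inst = inst, order = order, friction = friction,
    levels = lv, junctions = jn, spanned_junctions = spanned,
    z_bottom = z_bottom, gap = gap, t_cort = t_cort,
    e_sup = e_sup, e_inf = e_inf, seed = spec$seed))

  # posterior block to body ties
  for (i in seq_len(nl)) {
    face <- model$mesh$nsets[[paste0(lv[i], "_post_block_face")]]
    body <- level_bone_nodes(model, lv[i])
    model <- tie_nearest(model, face, body, capture = 2 * spec$mesh_size,
                         what = paste0(lv[i], " posterior block"))
  }
  # disc surfaces: coincident nodes were merged at join; any residue (e.g.
  # unequal adjacent body dimensions) is tied to the nearest endplate node
  for (j in disc_junctions) {
    i <- match(j, jn)
    pre <- paste0(gsub("-", "", j), "_")
    up_out <- model$mesh$nsets[[paste0(lv[i], "_endplate_inf_outer")]]
    lo_out <- model$mesh$nsets[[paste0(lv[i + 1], "_endplate_sup_outer")]]
    dsup <- setdiff(model$mesh$nsets[[paste0(pre, "disc_sup")]], up_out)
    dinf <- setdiff(model$mesh$nsets[[paste0(pre, "disc_inf")]], lo_out)
    if (length(dsup))
      model <- tie_nearest(model, dsup, up_out, capture = 2 * spec$mesh_size,
                           what = paste0(j, " disc superior surface"))
    if (length(dinf))
      model <- tie_nearest(model, dinf, lo_out, capture = 2 * spec$mesh_size,
                           what = paste0(j, " disc inferior surface"))
  }

  # articular facet contact for non-instrumented junctions
  for (j in disc_junctions) {
    i <- match(j, jn)
    model$contacts[[j]] <- list(
      name = j,
      master_surface = paste0(lv[i], "_facet_inf_surf"),
      slave_nset = paste0(lv[i + 1], "_facet_sup"),
      mu = friction)
  }

  # head coupling on the C2 spinous process
  spin <- model$mesh$nsets[["C2_spinous_process"]]
  if (!length(spin)) cf_assembly_error("missing C2 spinous process node set")
  model$couplings[["head"]] <- list(ref = colMeans(model$mesh$nodes[spin, , drop = FALSE]),
                                    nodes = spin)

  # base fixation on the inferior surface of the lowest vertebra
  base <- sort(unique(c(model$mesh$nsets[[paste0(lv[nl], "_endplate_inf")]],
                        model$mesh$nsets[[paste0(lv[nl], "_endplate_inf_outer")]],
                        model$mesh$nsets[[paste0(lv[nl], "_facet_inf")]])))
  model$mesh$nsets[["base"]] <- base

  model <- generate_ligaments(model)
  if (!is.null(inst)) model <- generate_instrumentation(model, inst)
  model
}

#' Set fixation level
#'
#' Replaces the `base` node set with the inferior surface of the requested
#' level (the lowest modeled vertebra by default; `"T1"` mirrors a fixation
#' one level higher).
#'
#' @param model a `spine_model`.
#' @param level vertebra label whose inferior surface is fixed.
#' @return the updated model.
#' @export
set_fix_level <- function(model, level) {
  lv <- model$info$levels
  if (!level %in% lv) cf_spec_error("unknown fixation level '%s'", level)
  base <- sort(unique(c(model$mesh$nsets[[paste0(level, "_endplate_inf")]],
                        model$mesh$nsets[[paste0(level, "_endplate_inf_outer")]],
                        model$mesh$nsets[[paste0(level, "_facet_inf")]])))
  model$mesh$nsets[["base"]] <- base
  # junctions below the fixed level no longer carry load; contacts there are
  # left in place (they simply stay inactive)
  model
}
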