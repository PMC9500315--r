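# Parametric specification of the synthetic C2-T2 phantom and of the ACDF
# instrument construct.

CERVICAL_LEVELS <- c("C2", "C3", "C4", "C5", "C6", "C7")
ALL_LEVELS <- c(CERVICAL_LEVELS, "T1", "T2")
ALL_JUNCTIONS <- paste0(ALL_LEVELS[-length(ALL_LEVELS)], "-", ALL_LEVELS[-1])

#' Specification of the synthetic spine phantom
#'
#' Describes a stylized parametric C2--T2 stack: each vertebra is an elliptic
#' trabecular body (split into a central and an exterior region) plus a
#' posterior block carrying spinous/articular landmarks, wrapped by a thin
#' cortical wedge layer (0.28 mm cervical, 0.24 mm thoracic). Discs are
#' concentric nucleus pulposus / anulus fibrosus cylinders whose nucleus
#' covers 25--50% of the endplate area and 40--50% of the disc volume.
#'
#' @param body_width,body_depth,body_height vertebral body dimensions in mm;
#'   scalars or named vectors per level (C2..T2).
#' @param disc_height disc heights in mm per junction (length 7, C2-C3 ..
#'   T1-T2). The three instrumented spaces default to the spacer heights.
#' @param np_area_fraction nucleus share of the endplate area, in
#'   \[0.25, 0.50\].
#' @param np_volume_fraction nucleus share of the disc volume, in
#'   \[0.40, 0.50\].
#' @param cortical_thickness_cervical,cortical_thickness_thoracic cortical
#'   shell thickness in mm.
#' @param mesh_size target element edge length in mm.
#' @param facet_gap initial clearance of the articular facet surfaces in mm.
#' @param jitter relative amplitude of interior-node geometric jitter (0
#'   disables it).
#' @param seed integer seed driving any geometric jitter.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_width = 16, body_depth = 18,
                         body_height = c(C2 = 10, C3 = 10, C4 = 10, C5 = 10,
                                         C6 = 10, C7 = 10, T1 = 12, T2 = 12),
                         disc_height = c(8, 8, 7, 4, 4, 4.5, 4.5),
                         np_area_fraction = 0.35,
                         np_volume_fraction = 0.45,
                         cortical_thickness_cervical = 0.28,
                         cortical_thickness_thoracic = 0.24,
                         mesh_size = 1.5,
                         facet_gap = 0.5,
                         jitter = 0,
                         seed = 1L) {
  expand <- function(x, def_names) {
    if (is.null(names(x))) x <- setNames(rep_len(x, length(def_names)), def_names)
    x[def_names]
  }
  spec <- list(
    levels = ALL_LEVELS,
    junctions = ALL_JUNCTIONS,
    body_width = expand(body_width, ALL_LEVELS),
    body_depth = expand(body_depth, ALL_LEVELS),
    body_height = expand(body_height, ALL_LEVELS),
    disc_height = setNames(rep_len(disc_height, 7L), ALL_JUNCTIONS),
    np_area_fraction = np_area_fraction,
    np_volume_fraction = np_volume_fraction,
    cortical_thickness_cervical = cortical_thickness_cervical,
    cortical_thickness_thoracic = cortical_thickness_thoracic,
    mesh_size = mesh_size,
    facet_gap = facet_gap,
    jitter = jitter,
    seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  lens <- c(spec$body_width, spec$body_depth, spec$body_height,
            spec$disc_height, spec$cortical_thickness_cervical,
            spec$cortical_thickness_thoracic, spec$mesh_size, spec$facet_gap)
  if (any(!is.finite(lens)) || any(lens <= 0))
    cf_spec_error("all phantom lengths must be positive and finite")
  if (spec$np_area_fraction < 0.25 || spec$np_area_fraction > 0.50)
    cf_spec_error("np_area_fraction %.3f outside [0.25, 0.50]",
                  spec$np_area_fraction)
  if (spec$np_volume_fraction < 0.40 || spec$np_volume_fraction > 0.50)
    cf_spec_error("np_volume_fraction %.3f outside [0.40, 0.50]",
                  spec$np_volume_fraction)
  if (spec$jitter < 0 || spec$jitter > 0.3)
    cf_spec_error("jitter must lie in [0, 0.3]")
  invisible(spec)
}

cortical_thickness <- function(spec, level) {
  if (startsWith(level, "C")) spec$cortical_thickness_cervical
  else spec$cortical_thickness_thoracic
}

#' Specification of the ACDF instrument construct
#'
#' Three interbody spacers, one anterior plate and two screws per spanned
#' vertebra (eight in total for the default C2--C5 span).
#'
#' @param spacer_heights spacer heights in mm for the spanned disc spaces.
#' @param screw_diameter,screw_length screw dimensions in mm.
#' @param screw_convergence_deg medial angulation of each screw in degrees
#'   (variable-angle screws converge toward the midline so the shaft and
#'   tip purchase in the denser central body).
#' @param plate_length total plate length in mm.
#' @param plate_span vertebra labels covered by the plate (contiguous).
#' @param plate_standoff gap between plate and anterior cortex in mm.
#' @param all_resected_span junctions whose anterior longitudinal ligament is
#'   resected (defaults to the plate span).
#' @return an object of class `instrument_spec`.
#' @export
instrument_spec <- function(spacer_heights = c(8, 8, 7),
                            screw_diameter = 4.0,
                            screw_length = 15.0,
                            screw_convergence_deg = 10,
                            plate_length = 55,
                            plate_span = c("C2", "C3", "C4", "C5"),
                            plate_standoff = 0,
                            all_resected_span = NULL) {
  if (screw_length <= 0 || screw_diameter <= 0)
    cf_spec_error("screw dimensions must be positive")
  if (screw_convergence_deg < 0 || screw_convergence_deg >= 45)
    cf_spec_error("screw_convergence_deg must lie in [0, 45)")
  if (plate_standoff < 0)
    cf_spec_error("plate_standoff must be non-negative")
  idx <- match(plate_span, ALL_LEVELS)
  if (anyNA(idx) || any(diff(idx) != 1L))
    cf_spec_error("plate_span must be contiguous vertebra labels")
  junctions <- paste0(plate_span[-length(plate_span)], "-", plate_span[-1])
  if (length(spacer_heights) != length(junctions))
    cf_spec_error("spacer count (%d) must equal spanned junction count (%d)",
                  length(spacer_heights), length(junctions))
  if (is.null(all_resected_span)) all_resected_span <- junctions
  structure(list(spacer_heights = setNames(spacer_heights, junctions),
                 screw_diameter = screw_diameter,
                 screw_length = screw_length,
                 screw_convergence_deg = screw_convergence_deg,
                 plate_length = plate_length,
                 plate_span = plate_span,
                 spanned_junctions = junctions,
                 plate_standoff = plate_standoff,
                 all_resected_span = all_resected_span),
            class = "instrument_spec")
}
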