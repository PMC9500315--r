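# Motion load cases: head-weight gravity on the C2 odontoid-adjacent facet
# patches plus an isometric-strength-derived torque applied through the
# kinematic coupling on the C2 spinous process.

#' Body parameters for head-weight estimation
#'
#' @param body_mass body mass in kg.
#' @param head_mass_fraction head share of body mass (default 0.0783).
#' @param g gravitational acceleration in m/s^2.
#' @return an object of class `body_params`.
#' @export
body_params <- function(body_mass = 39.97, head_mass_fraction = 0.0783,
                        g = 9.81) {
  if (!is.finite(body_mass) || body_mass <= 0)
    cf_domain_error("body_mass must be positive")
  if (!is.finite(head_mass_fraction) || head_mass_fraction <= 0 ||
      head_mass_fraction >= 1)
    cf_domain_error("head_mass_fraction must lie in (0, 1)")
  if (!is.finite(g) || g <= 0) cf_domain_error("g must be positive")
  structure(list(body_mass = body_mass,
                 head_mass_fraction = head_mass_fraction, g = g),
            class = "body_params")
}

#' Head-weight force in newtons
#'
#' `body_mass * head_mass_fraction * g`; the default body parameters give
#' the 30.7 N head weight of the reference case.
#'
#' @param body a [body_params()].
#' @return force in N.
#' @export
head_weight_force <- function(body = body_params()) {
  if (!inherits(body, "body_params")) cf_domain_error("need body_params")
  body$body_mass * body$head_mass_fraction * body$g
}

MOTIONS <- c("flexion", "extension", "lateral_flexion", "rotation")

#' Isometric cervical strength table
#'
#' Strength in N*mm per kg of head mass for each motion.
#'
#' @param flexion,extension,lateral_flexion,rotation strengths in N*mm/kg.
#' @return an object of class `isometric_strength_table`.
#' @export
isometric_strength_table <- function(flexion = 418, extension = 683,
                                     lateral_flexion = 542, rotation = 208) {
  s <- c(flexion = flexion, extension = extension,
         lateral_flexion = lateral_flexion, rotation = rotation)
  if (any(!is.finite(s)) || any(s < 0))
    cf_domain_error("strengths must be non-negative")
  structure(as.list(s), class = "isometric_strength_table")
}

#' Motion torque from isometric strength and head mass
#'
#' `strength * head_mass`, rounded to integer N*mm for reporting (pass
#' `round = FALSE` for the exact value).
#'
#' @param strength isometric strength in N*mm/kg.
#' @param head_mass head mass in kg (head-weight force / g).
#' @param round round to integer N*mm.
#' @return torque in N*mm.
#' @export
motion_torque <- function(strength, head_mass, round = TRUE) {
  if (any(strength < 0) || head_mass < 0)
    cf_domain_error("strength and head_mass must be non-negative")
  tq <- strength * head_mass
  if (round) base::round(tq) else tq
}

#' Torques for all four motions
#'
#' @param body a [body_params()].
#' @param table an [isometric_strength_table()].
#' @param round round to integer N*mm.
#' @return named numeric vector of torques in N*mm.
#' @export
motion_torque_table <- function(body = body_params(),
                                table = isometric_strength_table(),
                                round = TRUE) {
  hm <- head_weight_force(body) / body$g
  vapply(MOTIONS, function(m) motion_torque(table[[m]], hm, round), numeric(1))
}

# global anatomical axes of the phantom: x lateral, y anterior, z vertical
motion_axis <- function(motion) {
  switch(motion,
         flexion = c(-1, 0, 0),   # sagittal rotation, anterior-down
         extension = c(1, 0, 0),  # sagittal rotation, opposite sign
         lateral_flexion = c(0, 1, 0), # about the anteroposterior axis
         rotation = c(0, 0, 1),   # axial, about the vertical axis
         cf_spec_error("unknown motion '%s'", motion))
}

#' Build a motion load case
#'
#' Splits the head-weight gravity load 50/50 across the two C2
#' odontoid-adjacent facet node sets (equal nodal forces within each side,
#' acting in -z), applies the motion torque about the anatomical axis at the
#' kinematic-coupling reference point driving the C2 spinous process, and
#' fixes all translations of the base node set.
#'
#' @param model a `spine_model` with `C2_odontoid_facet_*` and `base` sets
#'   and the `head` coupling.
#' @param motion one of `"flexion"`, `"extension"`, `"lateral_flexion"`,
#'   `"rotation"`.
#' @param body a [body_params()].
#' @param table an [isometric_strength_table()].
#' @return an object of class `load_case`.
#' @export
build_load_case <- function(model, motion, body = body_params(),
                            table = isometric_strength_table()) {
  motion <- match.arg(motion, MOTIONS)
  left <- model$mesh$nsets[["C2_odontoid_facet_left"]]
  right <- model$mesh$nsets[["C2_odontoid_facet_right"]]
  base <- model$mesh$nsets[["base"]]
  if (is.null(left) || is.null(right))
    cf_assembly_error("model lacks the C2 odontoid facet node sets")
  if (is.null(base) || !length(base))
    cf_assembly_error("model lacks a base fixation node set")
  if (is.null(model$couplings[["head"]]))
    cf_assembly_error("model lacks the head kinematic coupling")

  hw <- head_weight_force(body)
  forces <- rbind(
    data.frame(node = left, dof = 3L, value = -hw / 2 / length(left)),
    data.frame(node = right, dof = 3L, value = -hw / 2 / length(right)))
  tq <- motion_torque(table[[motion]], hw / body$g, round = TRUE)
  structure(list(motion = motion,
                 gravity_force = hw,
                 torque = tq * motion_axis(motion),
                 torque_magnitude = tq,
                 coupling = "head",
                 forces = forces,
                 fixed_nset = "base"),
            class = "load_case")
}
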