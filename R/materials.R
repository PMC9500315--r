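# Bone mineral density to Young's modulus mapping and material assignment.
#
# BMD in mg/cc, moduli in MPa. Two law modes are provided:
#  * `as_used` (default): E = 10200 * (BMD/1000)^2.01 for BMD > 0 -- the
#    power law that reproduces every tabulated trabecular modulus in the
#    reference material table to the printed two decimals;
#  * `as_printed`: the four-branch piecewise form with branch thresholds
#    0.27 and 0.60 interpreted in g/cc (applied to BMD/1000).
# Both modes return the sentinel 0.001 MPa at BMD = 0.

#' Density--modulus law
#'
#' @param mode `"as_used"` (single 2.01 power law, default) or
#'   `"as_printed"` (piecewise form with a 2.2-power branch below 0.27 g/cc
#'   and a linear branch 5407*(BMD/1000) + 469 between 0.27 and 0.60 g/cc).
#' @return an object of class `density_modulus_law`.
#' @export
density_modulus_law <- function(mode = c("as_used", "as_printed")) {
  mode <- match.arg(mode)
  structure(list(mode = mode, density_units = "mg/cc",
                 output_units = "MPa"), class = "density_modulus_law")
}

#' Map bone mineral density to Young's modulus
#'
#' @param bmd bone mineral density in mg/cc (vectorized, must be >= 0).
#' @param law a [density_modulus_law()].
#' @return Young's modulus in MPa.
#' @examples
#' bmd_to_modulus(200.4, density_modulus_law("as_used")) # 403.10
#' @export
bmd_to_modulus <- function(bmd, law = density_modulus_law()) {
  if (!inherits(law, "density_modulus_law"))
    cf_domain_error("law must be a density_modulus_law")
  if (any(!is.finite(bmd)) || any(bmd < 0))
    cf_domain_error("bmd must be finite and non-negative (mg/cc)")
  x <- bmd / 1000 # g/cc
  E <- numeric(length(bmd))
  zero <- bmd == 0
  if (law$mode == "as_used") {
    E[!zero] <- 10200 * x[!zero]^2.01
  } else {
    b1 <- !zero & x < 0.27
    b2 <- x >= 0.27 & x <= 0.60
    b3 <- x > 0.60
    E[b1] <- 33900 * x[b1]^2.2
    E[b2] <- 5407 * x[b2] + 469
    E[b3] <- 10200 * x[b3]^2.01
  }
  E[zero] <- 0.001
  E
}

#' A linear-elastic material card
#'
#' @param name material name.
#' @param youngs_modulus Young's modulus in MPa (> 0, or the 0.001 sentinel).
#' @param poisson_ratio Poisson's ratio in (0, 0.5).
#' @return a one-row data frame.
#' @export
material_card <- function(name, youngs_modulus, poisson_ratio) {
  if (youngs_modulus <= 0)
    cf_domain_error("youngs_modulus must be positive (sentinel 0.001 at BMD=0)")
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5)
    cf_domain_error("poisson_ratio must lie in (0, 0.5)")
  data.frame(name = name, youngs_modulus = youngs_modulus,
             poisson_ratio = poisson_ratio)
}

#' Default constant material cards
#'
#' Cortical bone (1000 MPa, 0.30), nucleus pulposus (1.0, 0.49), anulus
#' fibrosus (3.4, 0.40), PEEK (4000, 0.35) and titanium (110000, 0.30).
#'
#' @return data frame of material cards.
#' @export
default_material_cards <- function() {
  rbind(material_card("cortical", 1000, 0.30),
        material_card("NP", 1.0, 0.49),
        material_card("AF", 3.4, 0.40),
        material_card("PEEK", 4000, 0.35),
        material_card("titanium", 110000, 0.30))
}

#' Default per-region bone mineral density table
#'
#' Central and exterior trabecular BMD (mg/cc) for every modeled vertebra;
#' the shipped values are the measured per-region densities of the reference
#' instrumented case.
#'
#' @return data frame with columns `region` (e.g. `"C2_central_body"`) and
#'   `bmd_mg_cc`.
#' @export
default_region_bmd <- function() {
  lev <- rep(ALL_LEVELS, each = 2)
  reg <- rep(c("central_body", "exterior_body"), times = 8)
  bmd <- c(200.4, 135.2, 242.1, 99.7, 319.2, 185.9, 301.3, 251.5,
           262.6, 141.8, 229.1, 124.7, 165.7, 55.1, 187.4, 140.4)
  data.frame(region = paste0(lev, "_", reg), bmd_mg_cc = bmd)
}

#' Read a per-region BMD list from CSV
#'
#' @param path CSV file with columns `region`, `bmd_mg_cc`.
#' @return data frame as [default_region_bmd()].
#' @export
read_region_bmd <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("region", "bmd_mg_cc") %in% names(df)))
    cf_format_error("BMD CSV must have columns region, bmd_mg_cc")
  df[, c("region", "bmd_mg_cc")]
}

#' Assign material properties to every element of a model
#'
#' Trabecular regions receive the density-mapped modulus with Poisson's
#' ratio 0.30 (the posterior block takes its level's exterior trabecular
#' modulus); the cortical shell, disc components and instruments take the
#' constant cards; ligament trusses keep the constants attached when they
#' were generated.
#'
#' @param model a `spine_model`.
#' @param bmd per-region BMD data frame (see [default_region_bmd()]).
#' @param law a [density_modulus_law()].
#' @param cards constant material cards (see [default_material_cards()]).
#' @return the model with `E`, `nu` and `mat_name` filled for all elements.
#' @export
assign_materials <- function(model, bmd = default_region_bmd(),
                             law = density_modulus_law(),
                             cards = default_material_cards()) {
  if (is.null(bmd) || nrow(bmd) == 0)
    cf_assembly_error("empty BMD list: every trabecular region needs an entry")
  card <- function(nm) {
    i <- match(nm, cards$name)
    if (is.na(i)) cf_assembly_error("unknown material name '%s'", nm)
    cards[i, ]
  }
  es <- model$mesh$elsets
  set_card <- function(model, ids, E, nu, nm) {
    model$E[ids] <- E
    model$nu[ids] <- nu
    model$mat_name[ids] <- nm
    model
  }
  missing <- character(0)
  for (lev in model$info$levels) {
    for (reg in c("central_body", "exterior_body")) {
      key <- paste0(lev, "_", reg)
      ids <- es[[key]]
      if (is.null(ids)) next
      row <- match(key, bmd$region)
      if (is.na(row)) { missing <- c(missing, key); next }
      E <- bmd_to_modulus(bmd$bmd_mg_cc[row], law)
      model <- set_card(model, ids, E, 0.30, paste0("trabecular_", key))
    }
    pb <- es[[paste0(lev, "_posterior_block")]]
    if (!is.null(pb)) {
      row <- match(paste0(lev, "_exterior_body"), bmd$region)
      if (is.na(row)) { missing <- c(missing, paste0(lev, "_exterior_body")) }
      else {
        E <- bmd_to_modulus(bmd$bmd_mg_cc[row], law)
        model <- set_card(model, pb, E, 0.30, paste0("posterior_", lev))
      }
    }
    co <- es[[paste0(lev, "_cortical")]]
    if (!is.null(co)) {
      cc <- card("cortical")
      model <- set_card(model, co, cc$youngs_modulus, cc$poisson_ratio,
                        "cortical")
    }
  }
  if (length(missing))
    cf_assembly_error("missing BMD entries for regions: %s",
                      paste(unique(missing), collapse = ", "))
  for (nm in names(es)) {
    if (grepl("_NP$", nm)) {
      cc <- card("NP")
      model <- set_card(model, es[[nm]], cc$youngs_modulus, cc$poisson_ratio, "NP")
    } else if (grepl("_AF$", nm)) {
      cc <- card("AF")
      model <- set_card(model, es[[nm]], cc$youngs_modulus, cc$poisson_ratio, "AF")
    }
  }
  for (nm in grep("^spacer_[A-Z]", names(es), value = TRUE)) {
    if (grepl("endplate", nm)) next
    cc <- card("PEEK")
    model <- set_card(model, es[[nm]], cc$youngs_modulus, cc$poisson_ratio, "PEEK")
  }
  inst_sets <- c("plate", grep("^screw_", names(es), value = TRUE))
  for (nm in inst_sets) {
    if (is.null(es[[nm]])) next
    cc <- card("titanium")
    model <- set_card(model, es[[nm]], cc$youngs_modulus, cc$poisson_ratio,
                      "titanium")
  }
  left <- which(is.na(model$E))
  if (length(left))
    cf_assembly_error("%d elements remain without a material card", length(left))
  model
}
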