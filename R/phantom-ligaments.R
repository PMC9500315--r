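# Ligament trusses: one tension-only 2-node truss per ligament unit per
# junction for ALL, PLL, ISL, SSL, ITL and LF, attached at parametric
# anatomical landmarks. ITL and LF are paired (left/right units).

#' Default ligament constants
#'
#' Young's modulus (MPa), Poisson's ratio and cross-section area (mm^2) for
#' the six modeled ligament groups: anterior/posterior longitudinal (ALL,
#' PLL), interspinal (ISL), supraspinal (SSL), intertransverse (ITL) and
#' ligamentum flavum (LF).
#'
#' @return data frame with columns `group`, `E`, `nu`, `area`.
#' @export
default_ligament_table <- function() {
  data.frame(group = c("ALL", "PLL", "ISL", "SSL", "ITL", "LF"),
             E = c(20, 70, 28, 28, 50, 50),
             nu = 0.3,
             area = c(38, 20, 35.5, 35.5, 10, 60))
}

# landmark nset suffixes per group and side
ligament_landmarks <- function(group) {
  if (group %in% c("ITL", "LF")) {
    list(paste0("lm_", group, c("_inf_L", "_sup_L")),
         paste0("lm_", group, c("_inf_R", "_sup_R")))
  } else {
    list(paste0("lm_", group, c("_inf", "_sup")))
  }
}

#' Attach ligament trusses to an assembled model
#'
#' Adds one truss per unit of each ligament group at every junction; ALL is
#' omitted across the resected span (the anterior longitudinal ligament is
#' resected where the plate is applied), and the supraspinal ligament is
#' partial (representable only where distinct from the interspinal
#' attachment; by default it is carried at every junction).
#'
#' @param model a `spine_model`.
#' @param table ligament constants as from [default_ligament_table()].
#' @param resected junction labels whose ALL is removed; defaults to the
#'   instrumented span recorded in the model.
#' @param ssl_junctions junctions carrying an SSL unit (default: all).
#' @return the updated model with a `ligaments` truss block and
#'   `lig_<group>_<junction>` element sets.
#' @export
generate_ligaments <- function(model, table = default_ligament_table(),
                               resected = NULL, ssl_junctions = NULL) {
  if (is.null(resected)) {
    resected <- if (!is.null(model$info$inst))
      model$info$inst$all_resected_span else character(0)
  }
  jn <- model$info$junctions
  lv <- model$info$levels
  if (is.null(ssl_junctions)) ssl_junctions <- jn
  conn <- NULL
  meta <- list()
  for (j in jn) {
    i <- match(j, jn)
    up <- lv[i]; lo <- lv[i + 1]
    for (g in table$group) {
      if (g == "ALL" && j %in% resected) next
      if (g == "SSL" && !j %in% ssl_junctions) next
      for (unit in ligament_landmarks(g)) {
        up_set <- paste0(up, "_", unit[1]) # upper vertebra inferior landmark
        lo_set <- paste0(lo, "_", unit[2]) # lower vertebra superior landmark
        n1 <- model$mesh$nsets[[up_set]]
        n2 <- model$mesh$nsets[[lo_set]]
        if (is.null(n1) || is.null(n2) || !length(n1) || !length(n2))
          cf_assembly_error("missing landmark for ligament %s at junction %s",
                            g, j)
        conn <- rbind(conn, c(n1[1], n2[1]))
        meta[[length(meta) + 1L]] <- list(group = g, junction = j)
      }
    }
  }
  if (is.null(conn)) return(model)
  storage.mode(conn) <- "integer"
  n_old <- mesh_nelem(model$mesh)
  m <- nrow(conn)
  model$mesh$blocks[[length(model$mesh$blocks) + 1L]] <-
    list(kind = "truss2", conn = conn)
  ids <- n_old + seq_len(m)
  grp <- vapply(meta, function(x) x$group, character(1))
  jnc <- vapply(meta, function(x) x$junction, character(1))
  row <- match(grp, table$group)
  model$E <- c(model$E, table$E[row])
  model$nu <- c(model$nu, table$nu[row])
  model$area <- c(model$area, table$area[row])
  model$mat_name <- c(model$mat_name, paste0("ligament_", grp))
  model$tension_only <- c(model$tension_only, rep(TRUE, m))
  for (k in unique(paste0("lig_", grp, "_", jnc))) {
    sel <- paste0("lig_", grp, "_", jnc) == k
    model$mesh$elsets[[k]] <- ids[sel]
  }
  for (g in unique(grp))
    model$mesh$elsets[[paste0("lig_", g)]] <- ids[grp == g]
  model
}

#' Ligament groups present at a junction
#'
#' @param model a `spine_model`.
#' @param junction junction label.
#' @return character vector of group names with at least one truss.
#' @export
ligament_groups_at <- function(model, junction) {
  pat <- paste0("^lig_([A-Z]+)_", junction, "$")
  hits <- grep(pat, names(model$mesh$elsets), value = TRUE)
  sort(unique(sub(pat, "\\1", hits)))
}
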