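# Run configuration: YAML schema with validation-first semantics. Units are
# fixed at mm / N / MPa / N*mm; configurations carrying other units are
# rejected rather than converted.

run_config_schema <- function() {
  list(
    phantom = names(formals(phantom_spec)),
    instrument = c(names(formals(instrument_spec)), "enabled"),
    bmd = c("file", "values"),
    law_mode = NULL,
    load = c("body_mass_kg", "head_fraction", "g", "strengths", "fix_level",
             "motions"),
    solver = c("rtol", "max_outer", "penalty_factor", "penetration_tol",
               "order", "validate"),
    output = c("dir", "write_fields"),
    seed = NULL,
    log_level = NULL)
}

#' Validate a run configuration
#'
#' Checks the configuration against the published schema before any
#' computation: unknown keys are rejected, required structure enforced, and
#' defaults filled in.
#'
#' @param cfg configuration list (as parsed from YAML).
#' @return validated configuration of class `run_config`.
#' @export
validate_run_config <- function(cfg) {
  schema <- run_config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    cf_spec_error("unknown configuration keys: %s",
                  paste(unknown, collapse = ", "))
  for (sec in names(schema)) {
    if (is.null(schema[[sec]]) || is.null(cfg[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad))
      cf_spec_error("unknown keys in section '%s': %s", sec,
                    paste(bad, collapse = ", "))
  }
  defaults <- list(law_mode = "as_used", seed = 1L, log_level = "info",
                   load = list(), solver = list(), output = list(),
                   phantom = list(), instrument = list(), bmd = NULL)
  cfg <- modifyList(defaults, cfg, keep.null = TRUE)
  if (!cfg$law_mode %in% c("as_used", "as_printed"))
    cf_spec_error("law_mode must be as_used or as_printed")
  ld <- cfg$load
  motions <- ld$motions %||% "all"
  if (identical(motions, "all") || "all" %in% motions) motions <- MOTIONS
  bad <- setdiff(motions, MOTIONS)
  if (length(bad)) cf_spec_error("unknown motions: %s", paste(bad, collapse = ", "))
  cfg$load$motions <- motions
  if (!is.null(ld$fix_level) && !ld$fix_level %in% ALL_LEVELS)
    cf_spec_error("fix_level must be a vertebra label")
  # resolve the BMD list now (validation-first: fail before any mesh work)
  cfg$bmd_table <- resolve_bmd(cfg$bmd)
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_bmd <- function(bmd) {
  if (is.null(bmd) || identical(bmd, "default")) return(default_region_bmd())
  if (!is.null(bmd$file)) return(read_region_bmd(bmd$file))
  if (!is.null(bmd$values)) {
    df <- do.call(rbind, lapply(bmd$values, function(v)
      data.frame(region = v$region, bmd_mg_cc = v$bmd_mg_cc)))
    return(df)
  }
  cf_spec_error("bmd section must provide 'file' or 'values'")
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) cf_format_error("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

# build the phantom / instrument specs from a config
config_phantom_spec <- function(cfg) {
  args <- cfg$phantom
  args$seed <- args$seed %||% cfg$seed
  do.call(phantom_spec, args)
}

config_instrument_spec <- function(cfg) {
  args <- cfg$instrument
  if (isFALSE(args$enabled)) return(NULL)
  args$enabled <- NULL
  do.call(instrument_spec, args)
}

config_body_params <- function(cfg) {
  ld <- cfg$load
  body_params(body_mass = ld$body_mass_kg %||% 39.97,
              head_mass_fraction = ld$head_fraction %||% 0.0783,
              g = ld$g %||% 9.81)
}

config_strength_table <- function(cfg) {
  s <- cfg$load$strengths
  if (is.null(s)) return(isometric_strength_table())
  do.call(isometric_strength_table, s)
}
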