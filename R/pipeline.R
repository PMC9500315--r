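# End-to-end pipeline: phantom -> materials -> loading -> solve (x motions)
# -> report, with a run manifest.

log_stage <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf("[cervifem] %s", sprintf(...)))
}

#' Run the full pipeline from a configuration
#'
#' Executes phantom generation, material assignment, load-case
#' construction, the static solve for every requested motion, and the
#' safety evaluation (damage indices, segmental ROM, trajectory summaries,
#' contact-slip plausibility). Outputs are written under the configured
#' directory and inventoried in a run manifest. The run is deterministic
#' for a fixed seed.
#'
#' @param config a `run_config` (see [read_run_config()]) or a path to a
#'   YAML configuration.
#' @param out_dir output directory; overrides the configuration.
#' @return a `run_manifest` with the verdict, key scalars and the file
#'   inventory (md5 checksums).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  cfg <- config
  out_dir <- out_dir %||% cfg$output$dir %||% tempfile("cervifem_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  t0 <- Sys.time()
  notes <- list()
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      cf_error("cervifem_stage_error", "stage '%s' failed: %s", name,
               conditionMessage(e))
    })
    notes[[name]] <<- sprintf("%.1f s", as.numeric(Sys.time() - st, units = "secs"))
    res
  }

  log_stage(cfg, "phantom: assembling synthetic spine")
  spec <- config_phantom_spec(cfg)
  inst <- config_instrument_spec(cfg)
  order <- cfg$solver$order %||% "quadratic"
  model <- stage("phantom", assemble_spine(spec, inst, order = order))
  if (!is.null(cfg$load$fix_level))
    model <- set_fix_level(model, cfg$load$fix_level)

  log_stage(cfg, "materials: density-modulus mapping (%s)", cfg$law_mode)
  law <- density_modulus_law(cfg$law_mode)
  model <- stage("materials",
                 assign_materials(model, cfg$bmd_table, law))

  body <- config_body_params(cfg)
  strengths <- config_strength_table(cfg)
  hw <- head_weight_force(body)
  torques <- motion_torque_table(body, strengths)
  log_stage(cfg, "loading: head weight %.1f N; torques %s N.mm", hw,
            paste(sprintf("%s=%d", names(torques), torques), collapse = ", "))

  sys <- stage("assemble", assemble_system(model))
  results <- list()
  reports <- list()
  slips <- list()
  for (m in cfg$load$motions) {
    log_stage(cfg, "solve: %s", m)
    lc <- build_load_case(model, m, body, strengths)
    res <- stage(paste0("solve_", m), solve_static(
      model, lc,
      rtol = cfg$solver$rtol %||% 1e-8,
      max_outer = cfg$solver$max_outer %||% 50,
      penalty_factor = cfg$solver$penalty_factor %||% 50,
      penetration_tol = cfg$solver$penetration_tol %||% 1e-3,
      system = sys))
    results[[m]] <- res
    reports[[m]] <- damage_report(res, model)
    slips[[m]] <- contact_slip_check(res, model)
    if (isTRUE(cfg$solver$validate) && !slips[[m]]$ok)
      cf_error("cervifem_validate_error",
               "motion %s: %d contact slips exceed one element length", m,
               slips[[m]]$n_exceed)
    if (isTRUE(cfg$output$write_fields))
      write_result_vtu(res, model, file.path(out_dir,
                                             sprintf("result_%s.vtu", m)))
  }

  log_stage(cfg, "report: ROM, trajectories, verdict")
  rom <- rom_table(results, model)
  write.csv(rom, file.path(out_dir, "rom.csv"), row.names = FALSE)
  traj <- do.call(rbind, lapply(names(results), function(m)
    cbind(motion = m, trajectory_report(results[[m]], model))))
  write.csv(traj, file.path(out_dir, "trajectory.csv"), row.names = FALSE)

  verdict <- if (all(MOTIONS %in% names(reports))) safety_verdict(reports)
  else structure(list(pass = NA, max_di = max(vapply(
    reports, function(r) max(r$table$max_di), numeric(1))),
    offenders = NULL), class = "safety_verdict")

  report <- list(
    verdict = if (isTRUE(verdict$pass)) "PASS" else if (isFALSE(verdict$pass))
      "FAIL" else "PARTIAL",
    max_damage_index = verdict$max_di,
    head_weight_N = hw,
    torques_Nmm = as.list(torques),
    motions = cfg$load$motions,
    damage = lapply(reports, function(r) {
      s <- r$table
      setNames(as.list(s$max_di), s$set)
    }),
    contact_slip = lapply(slips, function(s)
      list(max_slip_mm = s$max_slip, element_length_mm = s$element_length,
           ok = s$ok)),
    rom_deg = rom)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  model_path <- file.path(out_dir, "model.vtu")
  if (isTRUE(cfg$output$write_fields)) write_model(model, model_path)

  cfg_file <- file.path(out_dir, "config_resolved.yaml")
  cfg_plain <- unclass(cfg)
  cfg_plain$bmd_table <- NULL
  yaml::write_yaml(cfg_plain, cfg_file)

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  inventory <- data.frame(file = basename(files),
                          md5 = unname(tools::md5sum(files)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cervifem")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    verdict = report$verdict,
    max_damage_index = verdict$max_di,
    stages = notes,
    total = sprintf("%.1f s", as.numeric(Sys.time() - t0, units = "secs")),
    files = inventory)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  out <- structure(list(manifest = manifest, report = report,
                        verdict = verdict, rom = rom, trajectory = traj,
                        results = results, reports = reports, model = model,
                        out_dir = out_dir), class = "run_manifest")
  invisible(out)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> verdict: %s (max Di = %.3f), outputs in %s\n",
              x$report$verdict, x$report$max_damage_index, x$out_dir))
  invisible(x)
}
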