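#' Full pipeline configuration
#'
#' Validated configuration for [run_pipeline()]: phantom parameters,
#' material-mapping constants, ligament source, constructs, load cases,
#' solver tolerance and output directory. All randomness (the HU noise)
#' flows from the single `seed`.
#'
#' @param phantom list of [phantom_params()] arguments.
#' @param materials list of [mapping_constants()] arguments.
#' @param ligament_source `"eichenseer_shi"`, `"shi"` or `"yao"`.
#' @param breakpoint_strain elongation-law breakpoint strain.
#' @param variants construct variants to run.
#' @param cases stance load cases to run.
#' @param injured_side `"right"` or `"left"`.
#' @param solver_tol linear-solver residual tolerance.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return validated object of class `run_config`.
#' @export
run_config <- function(phantom = list(), materials = list(),
                       ligament_source = "eichenseer_shi",
                       breakpoint_strain = 0.10,
                       variants = c("USI", "BSI", "TSI"),
                       cases = c("bipedal", "right_one_leg", "left_one_leg"),
                       injured_side = "right", solver_tol = 1e-8,
                       out_dir = tempfile("pelvifem_run_"), seed = 1L) {
  cfg <- list(phantom = phantom, materials = materials,
              ligament_source = ligament_source,
              breakpoint_strain = breakpoint_strain,
              variants = variants, cases = cases,
              injured_side = injured_side, solver_tol = solver_tol,
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @export
validate_run_config <- function(config) {
  fail <- function(field, msg)
    stop(sprintf("config field '%s': %s", field, msg), call. = FALSE)
  # phantom / material fields validated by their own constructors, before
  # any compute happens
  tryCatch(do.call(phantom_params, config$phantom),
           error = function(e) fail("phantom", conditionMessage(e)))
  tryCatch(do.call(mapping_constants, config$materials),
           error = function(e) fail("materials", conditionMessage(e)))
  if (!config$ligament_source %in% c("eichenseer_shi", "shi", "yao"))
    fail("ligament_source", "unknown source")
  if (!is.numeric(config$breakpoint_strain) || config$breakpoint_strain <= 0)
    fail("breakpoint_strain", "must be > 0")
  bad <- setdiff(config$variants, c("USI", "BSI", "TSI"))
  if (length(bad)) fail("variants", paste("unknown:", paste(bad, collapse = ",")))
  bad <- setdiff(config$cases, names(stance_cases()))
  if (length(bad)) fail("cases", paste("unknown:", paste(bad, collapse = ",")))
  if (!config$injured_side %in% c("left", "right"))
    fail("injured_side", "must be 'left' or 'right'")
  if (!is.numeric(config$solver_tol) || config$solver_tol <= 0)
    fail("solver_tol", "must be > 0")
  invisible(config)
}

# canonical JSON serialisation of a config (used for the manifest hash);
# the output directory is bookkeeping, not part of the scientific identity
config_json <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full fixation-comparison pipeline
#'
#' Executes phantom generation, material mapping, ligament springs, FFP IIc
#' fracture, screw placement, all requested solves and report extraction;
#' writes the phantom mesh (MSH + VTU), the HU and material tables (CSV),
#' one solution VTU per variant and case, the gap and stress reports (CSV)
#' and a JSON run manifest with the config hash into `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return the [compare_constructs()] result, invisibly, with the manifest
#'   path attached.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  validate_run_config(config)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(phantom_params,
                    utils::modifyList(config$phantom,
                                      list(rng_seed = config$seed)))
  constants <- do.call(mapping_constants, config$materials)
  catalog <- stiffness_catalog(config$ligament_source,
                               config$breakpoint_strain)
  say("stage phantom: meshing at h = %g mm", params$target_edge_length)
  ph <- build_phantom(params)
  write_mesh_msh(ph$mesh, file.path(config$out_dir, "phantom.msh"))
  mf <- assign_materials(ph$mesh, ph$hu, constants)
  write_mesh_vtu(ph$mesh, file.path(config$out_dir, "phantom.vtu"),
                 cell_data = list(hu = ifelse(is.na(ph$hu$hu), -1, ph$hu$hu),
                                  E = ifelse(is.na(mf$E), -1, mf$E)))
  write_hu_csv(ph$hu, file.path(config$out_dir, "hu.csv"))
  utils::write.csv(mf, file.path(config$out_dir, "materials.csv"),
                   row.names = FALSE)
  say("stage compare: %d variants x %d cases", length(config$variants),
      length(config$cases))
  cmp <- compare_constructs(params, variants = config$variants,
                            cases = config$cases,
                            injured_side = config$injured_side,
                            catalog = catalog, constants = constants)
  utils::write.csv(cmp$gaps, file.path(config$out_dir, "gap_report.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$stresses,
                   file.path(config$out_dir, "stress_report.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$details,
                   file.path(config$out_dir, "gap_details.csv"),
                   row.names = FALSE)
  cj <- config_json(config)
  cfg_file <- file.path(config$out_dir, "config.json")
  writeLines(cj, cfg_file)
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   injured_side = config$injured_side,
                   variants = config$variants, cases = config$cases,
                   n_elements = nrow(ph$mesh$tets),
                   n_materials_used = attr(mf, "n_bins_used"),
                   timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  cmp$manifest_path <- file.path(config$out_dir, "manifest.json")
  invisible(cmp)
}
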