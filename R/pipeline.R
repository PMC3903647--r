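#' Pipeline configuration
#'
#' Assembles the full configuration of an end-to-end run: either a synthetic
#' landscape block or paths to rasters and presences, the scenario handling
#' mode, and the solver settings. Solver defaults are the standard design
#' values (100 runs, feature penalty 100, 1,000,000 iterations, 10,000
#' temperature decreases, adaptive temperature, no boundary-length term).
#'
#' @param seed Master seed for every random element.
#' @param n_rows,n_cols,nodata_fraction Synthetic grid parameters.
#' @param scenario_mode `"per_scenario"` or `"union"` feature handling.
#' @param solver A [solver_config()].
#' @param compare_levels Network levels for which distribution-only
#'   comparison ensembles are built and scored.
#' @param out_dir Output directory for artifacts.
#' @param input_dir Optional directory holding a landscape previously written
#'   with [write_landscape()]; when set, the synthetic block is ignored.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_rows = 60L, n_cols = 60L,
                            nodata_fraction = 0.05,
                            scenario_mode = c("per_scenario", "union"),
                            solver = solver_config(seed = seed),
                            compare_levels = c("MN1", "MN2", "MN3"),
                            out_dir = tempfile("shiftnet_run_"),
                            input_dir = NULL) {
  scenario_mode <- match.arg(scenario_mode)
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 nodata_fraction = nodata_fraction,
                 scenario_mode = scenario_mode, solver = solver,
                 compare_levels = compare_levels,
                 out_dir = out_dir, input_dir = input_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown solver fields are rejected; documented defaults apply to anything
#' omitted.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  solver_args <- y$solver %||% list()
  bad <- setdiff(names(solver_args), names(formals(solver_config)))
  if (length(bad))
    stop("unknown solver settings: ", paste(bad, collapse = ", "), call. = FALSE)
  args <- y[setdiff(names(y), "solver")]
  args$solver <- do.call(solver_config, solver_args)
  do.call(pipeline_config, args)
}

read_landscape_dir <- function(dir) {
  mpath <- file.path(dir, "landscape.yaml")
  if (!file.exists(mpath))
    stop("no landscape manifest (landscape.yaml) in ", dir, call. = FALSE)
  manifest <- yaml::read_yaml(mpath)
  pres <- utils::read.csv(file.path(dir, "presences.csv"))
  dims <- c(manifest$n_rows, manifest$n_cols)
  scens <- unlist(manifest$scenarios)
  species <- lapply(manifest$species, function(ms) {
    id <- ms$species_id
    fut <- lapply(scens, function(sc)
      read_asc(file.path(dir, paste0(id, "_future_", sc, ".asc"))))
    names(fut) <- scens
    p <- pres[pres$species_id == id, ]
    list(species_id = id, status = ms$status,
         present_climatic = read_asc(file.path(dir, paste0(id, "_present_climatic.asc"))),
         present_full = read_asc(file.path(dir, paste0(id, "_present_full.asc"))),
         future_climatic = fut,
         presences = rowcol_to_cell(p$row, p$col, dims))
  })
  names(species) <- vapply(species, `[[`, "", "species_id")
  mask <- !is.na(species[[1]]$present_climatic$values)
  structure(list(spec = grid_spec(dims[1], dims[2],
                                  cell_size = species[[1]]$present_climatic$cell_size,
                                  nodata_fraction = 1 - mean(mask)),
                 mask = mask, habitat = NULL, scenarios = scens,
                 species = species, seed = manifest$seed),
            class = "landscape")
}

#' Run the full monitoring-network design pipeline
#'
#' Executes simulate (or load) -> threshold -> classify -> assemble features
#' -> design nested networks -> quarter check -> niche comparison ->
#' distribution-only comparison and evaluation, writing all artifacts plus a
#' run manifest (config hash, seed, package version). Identical configuration
#' and seed give identical outputs.
#'
#' @param cfg A [pipeline_config()] or path to a YAML file.
#' @return Invisibly, a list with the landscape, classification, incidence,
#'   networks, quarter checks, niche table, and per-level evaluation reports.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stage <- "validate"
  result <- tryCatch({
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

    stage <- "simulate"
    land <- if (!is.null(cfg$input_dir)) read_landscape_dir(cfg$input_dir)
            else generate_landscape(
              grid_spec(cfg$n_rows, cfg$n_cols,
                        nodata_fraction = cfg$nodata_fraction),
              seed = cfg$seed)
    write_landscape(land, file.path(cfg$out_dir, "landscape"))

    stage <- "classify"
    cl <- classify_landscape(land)
    for (m in cl$class_maps)
      write_change_map(m, file.path(cfg$out_dir,
        sprintf("classes_%s_%s.asc", m$species_id, m$scenario_id)))

    stage <- "assemble"
    inc <- build_incidence(cl$class_maps, cl$full_bins,
                           scenario_mode = cfg$scenario_mode)
    statuses <- species_statuses(land)
    utils::write.csv(target_table_wide(statuses),
                     file.path(cfg$out_dir, "targets.csv"), row.names = FALSE)

    stage <- "design"
    nets <- design_nested(inc, statuses, cfg$solver)
    write_stations(nets, inc, file.path(cfg$out_dir, "stations.csv"))
    qc <- lapply(nets, quarter_check, full_bins = cl$full_bins)

    stage <- "niche"
    niche <- niche_comparison_table(land)
    utils::write.csv(niche, file.path(cfg$out_dir, "niche_comparison.csv"),
                     row.names = FALSE)

    stage <- "compare"
    inc_cur <- build_current_incidence(cl$climatic_bins, cl$full_bins)
    evals <- list()
    for (lev in cfg$compare_levels) {
      net <- nets[[lev]]
      dt <- distribution_only_targets(net, cl$climatic_bins, cl$full_bins)
      ens <- build_comparison_network(dt, inc_cur, length(net$stations),
                                      cfg$solver)
      tt <- build_targets(statuses, lev)
      tt_vec <- feature_targets(tt, inc)
      evals[[lev]] <- evaluate_against_stratified_targets(ens, inc, tt_vec)
    }
    summary_json <- list(
      n_stations = lapply(nets, function(n) length(n$stations)),
      quarter_check = qc,
      evaluation = lapply(evals, function(e)
        list(overall = as.list(e$overall),
             by_class = e$by_class))
    )
    jsonlite::write_json(summary_json,
                         file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)

    list(landscape = land, classification = cl, incidence = inc,
         networks = nets, quarter = qc, niche = niche, evaluations = evals)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  stage <- "manifest"
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  cfg_plain <- unclass(cfg)
  cfg_plain$solver <- unclass(cfg_plain$solver)
  cfg_plain$solver$cost_threshold <- cfg_plain$solver$cost_threshold %||% "none"
  cfg_plain$input_dir <- cfg_plain$input_dir %||% "none"
  yaml::write_yaml(cfg_plain, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("shiftnet")),
    outputs = list.files(cfg$out_dir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(result)
}
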