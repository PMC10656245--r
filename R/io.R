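#' Read and write pipeline tables
#'
#' All tabular interchange is UTF-8 CSV with a header row: censuses
#' (`year,season,area_id,species,age_class,count`), body masses
#' (`species,age_class,season,body_mass_g`), biomass plots
#' (`plot_id,x,y,community_id,biomass_kg_dm_per_100m2`), exclosure pairs
#' (`pair_id,community_id,inside_total_kg,outside_standing_kg`) and the
#' assessment report.
#'
#' @param path CSV file path.
#' @param x data.frame to write.
#' @return `read_table()` returns a data.frame; `write_table()` returns
#'   `path` invisibly.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname read_table
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

known_scenarios <- c("basic", "mer_plus30", "conservative_biomass",
                     "wildlife", "no_winter")

#' Validate a run configuration file
#'
#' Reads a YAML run configuration, resolves relative paths against the
#' config file's directory, fills defaults, and schema-checks it. All
#' problems (missing files, unknown keys, unknown scenario ids, bad
#' parameter values) are collected and reported in one aggregated error.
#'
#' Recognized keys: `inputs` (paths: `standing`, `classes`, `dem`,
#' `fsc_spring`, `fsc_winter`, `areas`, `census`), `scenarios` (list of
#' scenario ids), `parameters` (optional: `allometric_coefficient`,
#' `allometric_exponent`, `sustainable_utilization`, `spring_fsc_max`,
#' `winter_fsc_max`, `small_stock_summer_elev_max`, `biomass_adjustment`,
#' `productivity_ratio`, `marmot_density_per_km2`), `output_dir`, `seed`.
#'
#' @param path YAML file path.
#' @return validated config list of class `run_config`.
#' @export
validate_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  problems <- character()
  known_top <- c("inputs", "scenarios", "parameters", "output_dir", "seed")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra)) problems <- c(problems,
    paste0("unknown top-level key(s): ", paste(extra, collapse = ", ")))
  need_inputs <- c("standing", "classes", "dem", "fsc_spring", "fsc_winter",
                   "areas", "census")
  if (is.null(cfg$inputs)) {
    problems <- c(problems, "missing 'inputs' block")
  } else {
    miss <- setdiff(need_inputs, names(cfg$inputs))
    if (length(miss)) problems <- c(problems,
      paste0("missing input path(s): ", paste(miss, collapse = ", ")))
    for (k in intersect(need_inputs, names(cfg$inputs))) {
      p <- cfg$inputs[[k]]
      if (!grepl("^/", p)) p <- file.path(base, p)
      cfg$inputs[[k]] <- p
      if (!file.exists(p)) problems <- c(problems,
        paste0("input file for '", k, "' not found: ", p))
    }
  }
  if (is.null(cfg$scenarios)) cfg$scenarios <- "basic"
  bad_sc <- setdiff(unlist(cfg$scenarios), known_scenarios)
  if (length(bad_sc)) problems <- c(problems,
    paste0("unknown scenario id(s): ", paste(bad_sc, collapse = ", ")))
  par_defaults <- list(allometric_coefficient = 4.82,
                       allometric_exponent = 0.734,
                       sustainable_utilization = 0.40,
                       spring_fsc_max = 35, winter_fsc_max = 78,
                       small_stock_summer_elev_max = 4500,
                       biomass_adjustment = 0, productivity_ratio = 1,
                       marmot_density_per_km2 = 16.3)
  pars <- utils::modifyList(par_defaults,
                            if (is.null(cfg$parameters)) list() else cfg$parameters)
  extra_par <- setdiff(names(pars), names(par_defaults))
  if (length(extra_par)) problems <- c(problems,
    paste0("unknown parameter(s): ", paste(extra_par, collapse = ", ")))
  if (pars$sustainable_utilization <= 0 || pars$sustainable_utilization >= 1) {
    problems <- c(problems, "sustainable_utilization must be in (0, 1)")
  }
  cfg$parameters <- pars
  if (is.null(cfg$output_dir)) cfg$output_dir <- "output"
  if (!grepl("^/", cfg$output_dir)) {
    cfg$output_dir <- file.path(base, cfg$output_dir)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (length(problems)) {
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full assessment from a validated configuration
#'
#' Loads all inputs, runs every configured scenario and writes the CSV
#' report (`area_id,year,scenario,supply_mj,demand_livestock_mj,
#' demand_wildlife_mj,utilization_pct,class`), one utilization raster per
#' scenario, and a provenance record (config hash, seed, package version)
#' sufficient to rerun the analysis bit-compatibly.
#'
#' @param cfg a `run_config` from [validate_run_config()], or a path to one.
#' @return invisible list of [run_scenario()] results, one per scenario.
#' @export
run_assessment <- function(cfg) {
  if (is.character(cfg)) cfg <- validate_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  pars <- cfg$parameters
  allom <- allometric_params(pars$allometric_coefficient,
                             pars$allometric_exponent)
  profiles <- default_species_profiles(
    params = allom, marmot_density_per_km2 = pars$marmot_density_per_km2)
  inputs <- list(
    standing = read_raster(cfg$inputs$standing),
    classes = read_raster(cfg$inputs$classes),
    dem = read_raster(cfg$inputs$dem),
    fsc_spring = read_raster(cfg$inputs$fsc_spring),
    fsc_winter = read_raster(cfg$inputs$fsc_winter),
    areas = read_areas(cfg$inputs$areas),
    census = read_table(cfg$inputs$census),
    class_table = default_class_table(),
    community_params = default_community_params(pars$productivity_ratio),
    profiles = profiles,
    rules = accessibility_rules(
      spring_fsc_max = pars$spring_fsc_max,
      winter_fsc_max = pars$winter_fsc_max,
      small_stock_summer_elev_max = pars$small_stock_summer_elev_max)
  )
  crs_set <- unique(c(inputs$standing$crs, inputs$classes$crs, inputs$dem$crs,
                      inputs$fsc_spring$crs, inputs$fsc_winter$crs,
                      inputs$areas$crs))
  if (length(crs_set) > 1) {
    stop("mixed CRS across input bundle: ", paste(crs_set, collapse = ", "),
         call. = FALSE)
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  report <- list()
  for (sc in unlist(cfg$scenarios)) {
    config <- scenario_config(
      sc, sustainable_utilization = pars$sustainable_utilization,
      biomass_adjustment = if (sc == "conservative_biomass")
        pars$biomass_adjustment else 0)
    res <- run_scenario(inputs, config)
    results[[sc]] <- res
    rep <- res$results[, c("area_id", "year", "scenario", "supply_mj",
                           "demand_livestock_mj", "demand_wildlife_mj",
                           "utilization_pct", "class")]
    report[[sc]] <- rep
    write_raster(res$utilization,
                 file.path(cfg$output_dir, paste0("utilization_", sc, ".asc")))
  }
  write_table(do.call(rbind, report), file.path(cfg$output_dir, "report.csv"))
  prov <- list(package = "rangecap",
               version = as.character(utils::packageVersion("rangecap")),
               r_version = R.version.string,
               seed = cfg$seed,
               scenarios = unlist(cfg$scenarios),
               parameters = pars,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(cfg$output_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Write a synthetic input bundle to disk
#'
#' Materializes a [generate_bundle()] result as files (ASCII-grid rasters,
#' GeoJSON areas, CSV census/plots/exclosures and a ready-to-run YAML
#' config), so the file-based pipeline can be exercised end to end.
#'
#' @param bundle output of [generate_bundle()].
#' @param dir output directory (created if needed).
#' @return the path of the written YAML config.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(bundle$landscape$standing, file.path(dir, "standing.asc"))
  write_raster(bundle$landscape$classes, file.path(dir, "classes.asc"))
  write_raster(bundle$landscape$dem, file.path(dir, "dem.asc"))
  write_raster(bundle$landscape$fsc_spring, file.path(dir, "fsc_spring.asc"))
  write_raster(bundle$landscape$fsc_winter, file.path(dir, "fsc_winter.asc"))
  write_areas(bundle$areas, file.path(dir, "areas.geojson"))
  write_table(bundle$census, file.path(dir, "census.csv"))
  write_table(bundle$campaign$plots, file.path(dir, "plots.csv"))
  write_table(bundle$campaign$exclosures, file.path(dir, "exclosures.csv"))
  cfg <- list(
    inputs = list(standing = "standing.asc", classes = "classes.asc",
                  dem = "dem.asc", fsc_spring = "fsc_spring.asc",
                  fsc_winter = "fsc_winter.asc", areas = "areas.geojson",
                  census = "census.csv"),
    scenarios = list("basic"),
    parameters = list(productivity_ratio =
                        bundle$landscape$truth$config$productivity_ratio),
    output_dir = "output",
    seed = bundle$landscape$truth$seed
  )
  path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, path)
  path
}
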