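#' Scenario configuration
#'
#' The assessment is run under a small scenario set: `basic` (census demand
#' vs modeled supply), `mer_plus30` (30% higher energy requirements for all
#' livestock except yak, for altitude/low-temperature effects),
#' `conservative_biomass` (standing biomass lowered by a configured
#' adjustment, canonically half the biomass model's mean absolute error),
#' `wildlife` (adds marmot and wild-ungulate demand), and `no_winter`
#' (drops winter grazing from both demand and accessibility). Fields can be
#' overridden for composite scenarios.
#'
#' @param scenario_id one of the preset names above.
#' @param mer_factor livestock requirement multiplier.
#' @param mer_exempt_species species not scaled by `mer_factor`.
#' @param biomass_adjustment kg DM/ha subtracted from standing biomass.
#' @param include_wildlife include wild-herbivore demand.
#' @param include_winter_grazing include the winter season.
#' @param sustainable_utilization sustainability threshold as a fraction
#'   (default 0.40).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario_id = c("basic", "mer_plus30",
                                            "conservative_biomass",
                                            "wildlife", "no_winter"),
                            mer_factor = NULL, mer_exempt_species = "yak",
                            biomass_adjustment = NULL,
                            include_wildlife = NULL,
                            include_winter_grazing = NULL,
                            sustainable_utilization = 0.40) {
  scenario_id <- match.arg(scenario_id)
  stopifnot(sustainable_utilization > 0, sustainable_utilization < 1)
  cfg <- list(
    scenario_id = scenario_id,
    mer_factor = if (scenario_id == "mer_plus30") 1.3 else 1.0,
    mer_exempt_species = mer_exempt_species,
    biomass_adjustment = 0,
    include_wildlife = scenario_id == "wildlife",
    include_winter_grazing = scenario_id != "no_winter",
    sustainable_utilization = sustainable_utilization
  )
  if (!is.null(mer_factor)) cfg$mer_factor <- mer_factor
  if (!is.null(biomass_adjustment)) cfg$biomass_adjustment <- biomass_adjustment
  if (!is.null(include_wildlife)) cfg$include_wildlife <- include_wildlife
  if (!is.null(include_winter_grazing)) cfg$include_winter_grazing <- include_winter_grazing
  if (cfg$scenario_id == "conservative_biomass" && cfg$biomass_adjustment == 0) {
    warning("conservative_biomass scenario with adjustment 0; ",
            "set biomass_adjustment = 0.5 * mean validation MAE (kg DM/ha)",
            call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

#' Annual available energy per grazing area
#'
#' Sums MEC over the pixels of each grazing area that are accessible in at
#' least one season. A pixel's annual energy is counted once regardless of
#' how many seasons it is accessible (annual production basis).
#'
#' @param mec `rc_raster` of MEC (MJ/ha/year).
#' @param area_raster area-index raster from [rasterize_areas()].
#' @param masks list of seasonal masks ([accessible_mask()]); their union
#'   defines the ever-accessible pixels.
#' @return data.frame `area_id`, `supply_mj`, `accessible_ha`; areas with
#'   no accessible pixel get supply 0 with a warning.
#' @export
aggregate_available_energy <- function(mec, area_raster, masks) {
  stop_if_grid_mismatch(mec, area_raster, what = "MEC/area rasters")
  u <- mask_union(masks)
  stop_if_grid_mismatch(mec, u, what = "MEC/mask rasters")
  ids <- attr(area_raster, "area_id")
  idx <- area_raster$values
  acc <- u$values %in% 1 & is.finite(mec$values)
  px_ha <- rc_pixel_ha(mec)
  supply <- vapply(seq_along(ids), function(i) {
    sel <- acc & idx %in% i
    sum(mec$values[sel]) * px_ha
  }, 0)
  n_acc <- vapply(seq_along(ids), function(i) sum(acc & idx %in% i), 0L)
  if (any(n_acc == 0)) {
    warning("grazing area(s) with zero accessible pixels: ",
            paste(ids[n_acc == 0], collapse = ", "), call. = FALSE)
  }
  data.frame(area_id = ids, supply_mj = supply,
             accessible_ha = n_acc * px_ha, stringsAsFactors = FALSE)
}

#' Utilization intensity
#'
#' Percentage of available forage energy used: 100 * demand / supply. Zero
#' supply with positive demand yields `Inf` (reported as over-potential).
#'
#' @param demand_mj,supply_mj energies in MJ (non-negative).
#' @return percent (vectorized).
#' @export
utilization_rate <- function(demand_mj, supply_mj) {
  if (any(demand_mj < 0) || any(supply_mj < 0)) {
    stop("demand and supply must be non-negative", call. = FALSE)
  }
  out <- ifelse(supply_mj > 0, 100 * demand_mj / supply_mj,
                ifelse(demand_mj > 0, Inf, 0))
  out
}

#' Grazing potential
#'
#' Maximum stocking rate supported at full forage use: available energy per
#' hectare divided by one animal's annual requirement.
#'
#' @param mec_per_ha MJ/ha/year.
#' @param annual_mer MJ/animal/year (> 0).
#' @return animals/ha.
#' @export
grazing_potential <- function(mec_per_ha, annual_mer) {
  stopifnot(all(annual_mer > 0), all(mec_per_ha >= 0))
  mec_per_ha / annual_mer
}

#' Carrying capacity
#'
#' Sustainable stocking rate: grazing potential times the sustainable
#' utilization fraction (default 40%).
#'
#' @param potential animals/ha (>= 0).
#' @param sustainable_utilization fraction in (0, 1).
#' @return animals/ha.
#' @export
carrying_capacity <- function(potential, sustainable_utilization = 0.40) {
  stopifnot(all(potential >= 0))
  potential * sustainable_utilization
}

#' Classify a utilization rate
#'
#' `over_potential` above 100%, `unsustainable` strictly above the
#' sustainability threshold, `sustainable` otherwise (a rate exactly at the
#' threshold is sustainable).
#'
#' @param utilization_pct percent (>= 0; `Inf` allowed).
#' @param threshold sustainable fraction (default 0.40).
#' @return character vector of classes.
#' @export
classify_sustainability <- function(utilization_pct, threshold = 0.40) {
  stopifnot(all(utilization_pct >= 0))
  ifelse(utilization_pct > 100, "over_potential",
         ifelse(utilization_pct > 100 * threshold, "unsustainable",
                "sustainable"))
}

scenario_masks <- function(inputs, rules, include_winter = TRUE) {
  masks <- list(
    early_summer = accessible_mask("early_summer", "all",
                                   fsc = inputs$fsc_spring,
                                   area_raster = inputs$area_raster,
                                   areas_table = inputs$areas$table,
                                   rules = rules),
    high_summer_small = accessible_mask("high_summer", "small_stock",
                                        dem = inputs$dem,
                                        area_raster = inputs$area_raster,
                                        areas_table = inputs$areas$table,
                                        rules = rules),
    high_summer_large = accessible_mask("high_summer", "large_stock",
                                        area_raster = inputs$area_raster,
                                        areas_table = inputs$areas$table,
                                        rules = rules)
  )
  if (include_winter) {
    masks$winter <- accessible_mask("winter", "all", fsc = inputs$fsc_winter,
                                    area_raster = inputs$area_raster,
                                    areas_table = inputs$areas$table,
                                    rules = rules)
  }
  masks
}

vegetated_km2_by_area <- function(inputs,
                                  non_vegetated = c("non_vegetated", "water",
                                                    "snow_ice", "rock_scree")) {
  ct <- inputs$class_table
  veg_codes <- ct$code[!(ct$community_id %in% non_vegetated)]
  ids <- attr(inputs$area_raster, "area_id")
  idx <- inputs$area_raster$values
  veg <- inputs$classes$values %in% veg_codes
  km2 <- vapply(seq_along(ids), function(i) {
    sum(veg & idx %in% i) * rc_pixel_ha(inputs$classes) / 100
  }, 0)
  stats::setNames(km2, ids)
}

#' Run one carrying-capacity scenario
#'
#' Orchestrates the full assessment for one scenario: seasonal demand from
#' the census (with the scenario's requirement factor, exemptions and
#' optional wildlife demand), the MEC map (with the scenario's biomass
#' adjustment), seasonal accessibility masks, per-area annual supply,
#' utilization rates and sustainability classes, a utilization raster
#' (each area's mean rate painted onto its ever-accessible vegetated
#' pixels) and region-level aggregates over the assessed area.
#'
#' @param inputs named list: `standing` (kg DM/ha raster), `classes`,
#'   `class_table`, `community_params`, `dem`, `fsc_spring`, `fsc_winter`,
#'   `areas` ([rc_areas]), `census` (calendar seasons), `profiles`,
#'   `calendar`, `rules`; optionally a precomputed `area_raster`.
#' @param config a [scenario_config()].
#' @return list of class `assessment_result`: `results` (per area x year),
#'   `area_means` (per area, averaged over years), `region` (one row),
#'   `utilization` raster, `supply`, `mec`, `config`.
#' @export
run_scenario <- function(inputs, config = scenario_config("basic")) {
  profiles <- if (is.null(inputs$profiles)) default_species_profiles() else inputs$profiles
  calendar <- if (is.null(inputs$calendar)) season_calendar() else inputs$calendar
  rules <- if (is.null(inputs$rules)) accessibility_rules() else inputs$rules
  if (is.null(inputs$area_raster)) {
    inputs$area_raster <- rasterize_areas(inputs$areas, inputs$classes)
  }

  # -- supply side -----------------------------------------------------------
  mec <- build_mec_map(inputs$standing, inputs$classes,
                       params = inputs$community_params,
                       class_table = inputs$class_table,
                       adjustment = config$biomass_adjustment)
  masks <- scenario_masks(inputs, rules,
                          include_winter = config$include_winter_grazing)
  supply <- aggregate_available_energy(mec, inputs$area_raster, masks)

  # -- demand side -----------------------------------------------------------
  demand <- seasonal_area_demand(inputs$census, profiles, calendar)
  demand <- apply_mer_scenario(demand, factor = config$mer_factor,
                               exempt = config$mer_exempt_species)
  if (!config$include_winter_grazing) {
    demand <- demand[demand$season != "winter", , drop = FALSE]
  }
  years <- sort(unique(inputs$census$year))
  if (config$include_wildlife) {
    wkm2 <- vegetated_km2_by_area(inputs)
    wd <- wildlife_demand(wkm2, profiles, calendar)
    if (!config$include_winter_grazing) {
      wd <- wd[wd$season != "winter", , drop = FALSE]
    }
    if (nrow(wd)) {
      wd <- do.call(rbind, lapply(years, function(y) {
        wd$year <- y
        wd
      }))
      demand <- rbind(demand, wd)
    }
  }

  # -- per area x year accounting -------------------------------------------
  ids <- supply$area_id
  grid <- expand.grid(area_id = ids, year = years, stringsAsFactors = FALSE)
  sum_demand <- function(area, year, groups) {
    sel <- demand$area_id == area & demand$year == year &
      demand$group %in% groups
    sum(demand$energy_mj[sel])
  }
  grid$supply_mj <- supply$supply_mj[match(grid$area_id, supply$area_id)]
  grid$demand_livestock_mj <- mapply(sum_demand, grid$area_id, grid$year,
                                     MoreArgs = list(groups = "livestock"))
  grid$demand_wildlife_mj <- mapply(sum_demand, grid$area_id, grid$year,
                                    MoreArgs = list(groups = c("marmot",
                                                               "wild_ungulate")))
  total <- grid$demand_livestock_mj + grid$demand_wildlife_mj
  grid$utilization_pct <- utilization_rate(total, grid$supply_mj)
  grid$class <- classify_sustainability(grid$utilization_pct,
                                        config$sustainable_utilization)
  grid$scenario <- config$scenario_id

  # -- area means over years, utilization raster, region aggregates ---------
  mean_util <- stats::aggregate(grid$utilization_pct,
                                by = list(area_id = grid$area_id), FUN = mean)
  area_means <- data.frame(area_id = mean_util$area_id,
                           utilization_pct = mean_util$x,
                           stringsAsFactors = FALSE)
  area_means$class <- classify_sustainability(
    pmax(area_means$utilization_pct, 0), config$sustainable_utilization)

  u <- mask_union(masks)
  veg_codes <- inputs$class_table$code[
    !(inputs$class_table$community_id %in%
        c("non_vegetated", "water", "snow_ice", "rock_scree"))]
  assessed <- u$values %in% 1 & inputs$classes$values %in% veg_codes
  idx <- inputs$area_raster$values
  paint <- matrix(NA_real_, nrow(idx), ncol(idx))
  for (i in seq_along(ids)) {
    paint[assessed & idx %in% i] <-
      area_means$utilization_pct[area_means$area_id == ids[i]]
  }
  util_raster <- rc_set_values(mec, paint)
  px <- paint[is.finite(paint)]
  region <- data.frame(
    scenario = config$scenario_id,
    mean_utilization_pct = if (length(px)) mean(px) else NA_real_,
    pct_area_unsustainable = if (length(px))
      100 * mean(px > 100 * config$sustainable_utilization) else NA_real_,
    assessed_ha = length(px) * rc_pixel_ha(mec),
    utilization_min_pct = if (length(px)) min(px) else NA_real_,
    utilization_max_pct = if (length(px)) max(px) else NA_real_
  )

  structure(list(results = grid, area_means = area_means, region = region,
                 utilization = util_raster, supply = supply, mec = mec,
                 config = config),
            class = "assessment_result")
}

#' @export
print.assessment_result <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d areas x %d years\n", x$config$scenario_id,
              length(unique(x$results$area_id)),
              length(unique(x$results$year))))
  cat(sprintf("  region mean utilization: %.0f%%, unsustainable area: %.0f%%\n",
              x$region$mean_utilization_pct, x$region$pct_area_unsustainable))
  invisible(x)
}
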