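#' Synthetic landscape configuration
#'
#' Parameters of the self-contained synthetic study system used for testing
#' and closed-loop validation. Defaults emulate the statistical regime of a
#' cold high-mountain dryland: elevations 3000-6000 m, vegetation
#' communities arranged along the altitudinal gradient (riparian and salt
#' grass low, dwarf-shrub steppe mid, alpine grassland high, bare
#' rock/snow above), annual production magnitudes per community matching
#' regional survey means (riparian ~1700, Salix ~2000, salt grass ~640,
#' dwarf-shrub ~460, alpine ~900 kg DM/ha), reflectance bands carrying a
#' recoverable biomass signal around a bare-soil line, and fractional snow
#' cover increasing with elevation and deeper in winter than in spring.
#'
#' @param nx,ny grid size in pixels.
#' @param res pixel size, m (default 10).
#' @param elev_range range of elevation, m a.s.l.
#' @param elev_breaks community band edges (m): riparian belt below the
#'   first break, then salt grass, dwarf-shrub steppe, alpine grassland,
#'   and non-vegetated above the last break.
#' @param production_mean,production_sd named per-community annual
#'   production moments (kg DM/ha/year).
#' @param productivity_ratio annual production / standing biomass used to
#'   derive the standing-biomass raster from true production.
#' @param soil [soil_line()] of the synthetic scene.
#' @param band_noise_sd reflectance noise SD added to every band.
#' @param fsc_spring_range,fsc_winter_range elevations (m) at which spring /
#'   winter FSC ramps linearly from 0 to 100%.
#' @param fsc_noise_sd FSC noise SD (percentage points).
#' @param n_areas number of grazing areas (rectangular tiling).
#' @param n_winter_camps number of (lowest-elevation) areas given winter
#'   camps.
#' @param year calendar year stamped on generated censuses.
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(nx = 200, ny = 200, res = 10,
                             elev_range = c(3000, 6000),
                             elev_breaks = c(3350, 3650, 4450, 5250),
                             production_mean = c(riparian_grassland = 1729,
                                                 salix_riparian = 1982,
                                                 salt_grass = 641,
                                                 dwarf_shrub_steppe = 461,
                                                 alpine_grassland = 900),
                             production_sd = c(riparian_grassland = 260,
                                               salix_riparian = 280,
                                               salt_grass = 130,
                                               dwarf_shrub_steppe = 110,
                                               alpine_grassland = 180),
                             productivity_ratio = 1.5,
                             soil = soil_line(alpha = 1.2, beta = 0.04),
                             band_noise_sd = 0.008,
                             fsc_spring_range = c(3600, 4800),
                             fsc_winter_range = c(2900, 4100),
                             fsc_noise_sd = 4,
                             n_areas = 4, n_winter_camps = 2,
                             year = 2020) {
  stopifnot(all(production_sd >= 0), productivity_ratio > 0, n_areas >= 1,
            n_winter_camps <= n_areas, length(elev_breaks) == 4,
            !is.unsorted(elev_breaks))
  structure(as.list(environment()), class = "landscape_config")
}

# sum of random low-frequency sinusoids: a cheap smooth random field in [0,1]-ish
smooth_field <- function(nr, nc, n_waves = 6, amp = 1) {
  xs <- seq(0, 1, length.out = nc)
  ys <- seq(0, 1, length.out = nr)
  f <- matrix(0, nr, nc)
  for (i in seq_len(n_waves)) {
    fx <- stats::runif(1, 0.5, 3); fy <- stats::runif(1, 0.5, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + outer(ys, xs, function(y, x) sin(2 * pi * (fx * x + fy * y) + ph))
  }
  amp * f / n_waves
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic landscape with known ground truth
#'
#' Deterministic for a fixed seed. Produces co-registered rasters: DEM,
#' vegetation-community classes (elevation-correlated, riparian low and
#' alpine high), true annual production and derived standing biomass,
#' nine reflectance bands whose soil-adjusted/red-edge indices carry the
#' biomass signal, and spring/winter FSC fields increasing with elevation
#' (winter snowier than spring). The returned ground truth includes the true
#' MEC raster computed from the generator's own parameters.
#'
#' @param config a [landscape_config()].
#' @param seed integer RNG seed.
#' @return list: rasters (`dem`, `classes`, `production`, `standing`,
#'   `fsc_spring`, `fsc_winter`), `bands` (list of 9), `class_table`,
#'   `community_params`, `soil`, `truth` (list with `mec`, `production`,
#'   `config`, `seed`).
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1) {
  set.seed(seed)
  nr <- config$ny; nc <- config$nx
  grid <- rc_raster(matrix(0, nr, nc), res = config$res)

  # elevation: dominant south-north gradient plus smooth relief
  base <- matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)[nr:1, ]
  relief <- smooth_field(nr, nc, amp = 0.18)
  e01 <- clamp(0.85 * (1 - base) + relief + 0.08, 0, 1)  # row 1 = north = high
  dem_v <- config$elev_range[1] + diff(config$elev_range) * e01
  dem <- rc_set_values(grid, dem_v)

  # communities: altitudinal bands with relief jitter; riparian belt split
  # into grassland/Salix by a moisture field
  jitter <- dem_v + 60 * smooth_field(nr, nc, amp = 1)
  moisture <- smooth_field(nr, nc, amp = 1)
  br <- config$elev_breaks
  code <- matrix(4L, nr, nc)                        # dwarf-shrub steppe
  code[jitter < br[1] & moisture >= 0] <- 1L        # riparian grassland
  code[jitter < br[1] & moisture < 0] <- 2L         # Salix riparian
  code[jitter >= br[1] & jitter < br[2]] <- 3L      # salt grass
  code[jitter >= br[3] & jitter < br[4]] <- 5L      # alpine grassland
  code[jitter >= br[4]] <- 0L                       # rock / permanent snow
  classes <- rc_set_values(grid, code)

  # true annual production per community
  ct <- default_class_table()
  prod <- matrix(0, nr, nc)
  for (cid in names(config$production_mean)) {
    cd <- ct$code[ct$community_id == cid]
    sel <- code == cd
    prod[sel] <- pmax(stats::rnorm(sum(sel), config$production_mean[[cid]],
                                   config$production_sd[[cid]]), 0)
  }
  production <- rc_set_values(grid, prod)
  standing <- rc_set_values(grid, prod / config$productivity_ratio)

  # reflectance bands: soil brightness + vegetation signal + noise
  a <- config$soil$alpha; b <- config$soil$beta
  sdn <- config$band_noise_sd
  s <- clamp(0.22 + 0.025 * smooth_field(nr, nc, amp = 1) +
               matrix(stats::rnorm(nr * nc, 0, 0.01), nr, nc), 0.10, 0.35)
  vfrac <- clamp(prod / 2000, 0, 1)
  noise <- function() matrix(stats::rnorm(nr * nc, 0, sdn), nr, nc)
  bands <- list(
    B3  = clamp(0.90 * s - 0.040 * vfrac + noise(), 0.001, 1),
    B4  = clamp(s - 0.060 * vfrac + noise(), 0.001, 1),
    B5  = clamp(s + 0.020 + 0.040 * vfrac + noise(), 0.001, 1),
    B6  = clamp(s + 0.030 + 0.120 * vfrac + noise(), 0.001, 1),
    B7  = clamp(a * s + b - 0.020 + 0.170 * vfrac + noise(), 0.001, 1),
    B8  = clamp(a * s + b + 0.200 * vfrac + noise(), 0.001, 1),
    B8a = clamp(a * s + b + 0.190 * vfrac + noise(), 0.001, 1),
    B11 = clamp(0.30 - 0.120 * vfrac + noise(), 0.001, 1),
    B12 = clamp(0.24 - 0.100 * vfrac + noise(), 0.001, 1)
  )
  bands <- lapply(bands, function(m) rc_set_values(grid, m))

  # fractional snow cover: linear altitudinal ramp + noise, winter > spring
  ramp <- function(range) {
    clamp(100 * (dem_v - range[1]) / diff(range) +
            matrix(stats::rnorm(nr * nc, 0, config$fsc_noise_sd), nr, nc),
          0, 100)
  }
  fsc_spring <- rc_set_values(grid, ramp(config$fsc_spring_range))
  fsc_winter <- rc_set_values(grid, ramp(config$fsc_winter_range))

  params <- default_community_params(productivity_ratio = config$productivity_ratio)
  mec_true <- build_mec_map(standing, classes, params = params,
                            class_table = ct)
  list(dem = dem, classes = classes, production = production,
       standing = standing, fsc_spring = fsc_spring, fsc_winter = fsc_winter,
       bands = bands, class_table = ct, community_params = params,
       soil = config$soil,
       truth = list(mec = mec_true, production = production,
                    config = config, seed = seed))
}

#' Generate a synthetic grazing-area system
#'
#' Tiles the landscape extent into non-overlapping rectangular grazing
#' areas and flags the lowest-elevation areas (valley pastures) as having
#' winter camps, with camp points at the area centroids.
#'
#' @param config a [landscape_config()].
#' @param landscape output of [generate_landscape()] (for elevations).
#' @return an [rc_areas] object.
#' @export
generate_grazing_system <- function(config, landscape) {
  n <- config$n_areas
  k1 <- floor(sqrt(n))
  while (n %% k1 != 0) k1 <- k1 - 1
  k2 <- n / k1  # k1 rows x k2 cols of rectangles
  W <- config$nx * config$res; H <- config$ny * config$res
  polys <- list(); ids <- character(n)
  cx <- numeric(n); cy <- numeric(n)
  m <- 0
  for (i in seq_len(k1)) {
    for (j in seq_len(k2)) {
      m <- m + 1
      x0 <- (j - 1) * W / k2; x1 <- j * W / k2
      y0 <- (i - 1) * H / k1; y1 <- i * H / k1
      ids[m] <- sprintf("area_%02d", m)
      polys[[m]] <- cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
      cx[m] <- (x0 + x1) / 2; cy[m] <- (y0 + y1) / 2
    }
  }
  names(polys) <- ids
  tab <- data.frame(area_id = ids, has_winter_camp = FALSE,
                    camp_x = cx, camp_y = cy, stringsAsFactors = FALSE)
  # winter camps in the lowest-lying areas
  ar <- rasterize_areas(rc_areas(tab, polys, crs = landscape$dem$crs),
                        landscape$dem)
  mean_elev <- vapply(seq_along(ids), function(i) {
    mean(landscape$dem$values[ar$values %in% i])
  }, 0)
  tab$has_winter_camp[order(mean_elev)[seq_len(config$n_winter_camps)]] <- TRUE
  rc_areas(tab, polys, crs = landscape$dem$crs)
}

#' Generate a census that hits target utilization rates
#'
#' Inverts the demand model: for each grazing area, chooses integer herd
#' sizes (a fixed sheep/goat/yak composition split into adult/young classes)
#' whose annual energy requirement approximates the target utilization
#' fraction of the area's true annual supply. Animals in winter-camp areas
#' are present in all three seasons; areas without winter camps carry their
#' herd in the two summer seasons only. Integer rounding makes the achieved
#' utilization differ from the target by at most a few animals' worth of
#' energy.
#'
#' @param config a [landscape_config()].
#' @param landscape output of [generate_landscape()].
#' @param areas output of [generate_grazing_system()].
#' @param target_utilization named fraction per `area_id` (e.g. 0.4), or a
#'   single value recycled to all areas.
#' @param species_weights herd composition by headcount share.
#' @param age_split adult/young share of each species' headcount.
#' @param profiles,calendar,rules energy/accessibility parameter sets.
#' @return census data.frame (`year`, `season`, `area_id`, `species`,
#'   `age_class`, `count`) with attributes `target` (named vector) and
#'   `true_supply_mj`.
#' @export
generate_census <- function(config, landscape, areas, target_utilization = 0.4,
                            species_weights = c(sheep = 0.55, goat = 0.38,
                                                yak = 0.07),
                            age_split = c(adult = 0.8, young = 0.2),
                            profiles = default_species_profiles(),
                            calendar = season_calendar(),
                            rules = accessibility_rules()) {
  stopifnot(all(target_utilization >= 0),
            abs(sum(species_weights) - 1) < 1e-8,
            abs(sum(age_split) - 1) < 1e-8)
  area_raster <- rasterize_areas(areas, landscape$classes)
  inputs <- list(dem = landscape$dem, fsc_spring = landscape$fsc_spring,
                 fsc_winter = landscape$fsc_winter, areas = areas,
                 area_raster = area_raster)
  masks <- scenario_masks(inputs, rules, include_winter = TRUE)
  supply <- aggregate_available_energy(landscape$truth$mec, area_raster, masks)
  ids <- supply$area_id
  target <- if (length(target_utilization) == 1) {
    stats::setNames(rep(target_utilization, length(ids)), ids)
  } else target_utilization[ids]
  daily <- daily_requirement_table(profiles, calendar)
  rate <- function(sp, age, season) {
    daily$mj_per_day[daily$species == sp & daily$age_class == age &
                       daily$season == season]
  }
  out <- list()
  for (i in seq_along(ids)) {
    has_camp <- areas$table$has_winter_camp[areas$table$area_id == ids[i]]
    seasons <- if (has_camp) calendar$season else
      setdiff(calendar$season, "winter")
    # annual energy of one "composition unit" of herd
    unit <- 0
    for (sp in names(species_weights)) for (ag in names(age_split)) {
      unit <- unit + species_weights[[sp]] * age_split[[ag]] *
        sum(vapply(seasons, function(se) {
          rate(sp, ag, se) * season_days(calendar, se)
        }, 0))
    }
    n_total <- unname(target[ids[i]]) * supply$supply_mj[i] / unit
    for (sp in names(species_weights)) for (ag in names(age_split)) {
      count <- floor(n_total * species_weights[[sp]] * age_split[[ag]] + 0.5)
      if (count == 0) next
      out[[length(out) + 1]] <- data.frame(
        year = config$year, season = seasons, area_id = ids[i],
        species = sp, age_class = ag, count = count, stringsAsFactors = FALSE)
    }
  }
  census <- if (length(out)) do.call(rbind, out) else
    data.frame(year = integer(), season = character(), area_id = character(),
               species = character(), age_class = character(),
               count = integer(), stringsAsFactors = FALSE)
  rownames(census) <- NULL
  attr(census, "target") <- target
  attr(census, "true_supply_mj") <- stats::setNames(supply$supply_mj, ids)
  census
}

#' Generate a synthetic field campaign
#'
#' Stratified random biomass plots (observed value = true pixel standing
#' biomass in kg DM/100 m^2 plus Gaussian noise), exclosure pairs encoding
#' the configured productivity ratio, and fresh/dry calibration pairs.
#'
#' @param landscape output of [generate_landscape()].
#' @param n_per_class named plot counts per community (default emulates a
#'   relative-abundance stratification: 50 dwarf-shrub, 30 riparian, 30
#'   alpine, 15 salt grass).
#' @param plot_noise_sd plot measurement noise SD, kg DM/100 m^2.
#' @param n_exclosures number of exclosure pairs.
#' @param exclosure_noise_sd multiplicative (log-scale) SD of pair ratios.
#' @param n_fresh_dry number of fresh/dry pairs.
#' @param dry_fraction true dry/fresh slope.
#' @param seed RNG seed.
#' @return list: `plots` (data.frame `plot_id`, `x`, `y`, `community_id`,
#'   `biomass_kg_dm_per_100m2`, plus true values), `exclosures`
#'   (`pair_id`, `community_id`, `inside_total_kg`, `outside_standing_kg`),
#'   `fresh_dry` (`fresh_kg`, `dry_kg`).
#' @export
generate_field_campaign <- function(landscape,
                                    n_per_class = c(dwarf_shrub_steppe = 50,
                                                    riparian_grassland = 30,
                                                    alpine_grassland = 30,
                                                    salt_grass = 15),
                                    plot_noise_sd = 0.5,
                                    n_exclosures = 10,
                                    exclosure_noise_sd = 0.05,
                                    n_fresh_dry = 67,
                                    dry_fraction = 0.4,
                                    seed = 1) {
  set.seed(seed)
  ct <- landscape$class_table
  code <- landscape$classes$values
  cc <- rc_coords(landscape$classes)
  standing_100m2 <- landscape$standing$values / 100  # kg DM/ha -> kg DM/100 m^2
  plots <- list()
  for (cid in names(n_per_class)) {
    cd <- ct$code[ct$community_id == cid]
    avail <- which(code == cd)
    if (length(avail) < n_per_class[[cid]]) {
      stop(sprintf("class %s has only %d pixels, %d plots requested",
                   cid, length(avail), n_per_class[[cid]]), call. = FALSE)
    }
    sel <- sample(avail, n_per_class[[cid]])
    plots[[cid]] <- data.frame(
      x = cc$x[sel], y = cc$y[sel], community_id = cid,
      true_kg_dm_per_100m2 = standing_100m2[sel],
      biomass_kg_dm_per_100m2 = pmax(
        standing_100m2[sel] + stats::rnorm(length(sel), 0, plot_noise_sd), 0),
      stringsAsFactors = FALSE)
  }
  plots <- do.call(rbind, plots)
  plots <- cbind(plot_id = sprintf("plot_%03d", seq_len(nrow(plots))), plots)
  rownames(plots) <- NULL

  ratio <- landscape$truth$config$productivity_ratio
  veg <- which(code %in% ct$code[ct$community_id %in%
                                   names(landscape$truth$config$production_mean)])
  sel <- sample(veg, n_exclosures)
  outside <- pmax(standing_100m2[sel], 0.2)
  inside <- outside * ratio * exp(stats::rnorm(n_exclosures, 0,
                                               exclosure_noise_sd))
  exclosures <- data.frame(
    pair_id = sprintf("excl_%02d", seq_len(n_exclosures)),
    community_id = ct$community_id[match(code[sel], ct$code)],
    inside_total_kg = inside, outside_standing_kg = outside,
    stringsAsFactors = FALSE)

  fresh <- stats::runif(n_fresh_dry, 0.5, 8)
  dry <- pmax(dry_fraction * fresh + stats::rnorm(n_fresh_dry, 0, 0.15), 0.01)
  list(plots = plots, exclosures = exclosures,
       fresh_dry = data.frame(fresh_kg = fresh, dry_kg = dry))
}

#' Extract index values at plot locations
#'
#' @param indices named list of index `rc_raster`s.
#' @param plots data.frame with `x`, `y` (map coordinates).
#' @return data.frame of index values, one row per plot.
#' @export
extract_at_plots <- function(indices, plots) {
  template <- indices[[1]]
  nr <- nrow(template$values)
  col <- floor((plots$x - template$xmin) / template$res) + 1L
  row <- nr - floor((plots$y - template$ymin) / template$res)
  as.data.frame(lapply(indices, function(r) r$values[cbind(row, col)]))
}

#' Generate the complete synthetic input bundle
#'
#' Convenience wrapper producing everything one assessment run needs:
#' landscape rasters, grazing areas, a target-utilization census and a
#' field campaign, assembled into the `inputs` list consumed by
#' [run_scenario()].
#'
#' @param config a [landscape_config()].
#' @param seed RNG seed used for every stochastic stage.
#' @param target_utilization per-area (or scalar) utilization targets.
#' @return list with `inputs` (for [run_scenario()]), `landscape`, `areas`,
#'   `census`, `campaign`.
#' @export
generate_bundle <- function(config = landscape_config(), seed = 1,
                            target_utilization = 0.4) {
  landscape <- generate_landscape(config, seed = seed)
  areas <- generate_grazing_system(config, landscape)
  census <- generate_census(config, landscape, areas,
                            target_utilization = target_utilization)
  campaign <- generate_field_campaign(landscape, seed = seed + 1)
  inputs <- list(standing = landscape$standing, classes = landscape$classes,
                 class_table = landscape$class_table,
                 community_params = landscape$community_params,
                 dem = landscape$dem, fsc_spring = landscape$fsc_spring,
                 fsc_winter = landscape$fsc_winter, areas = areas,
                 census = census)
  list(inputs = inputs, landscape = landscape, areas = areas, census = census,
       campaign = campaign)
}
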