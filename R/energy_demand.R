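#' Field metabolic rate of a free-ranging herbivore
#'
#' Daily metabolizable energy expenditure from allometric scaling of body
#' mass: ME = a * BM^b / 1000 (MJ/day, BM in grams). Strictly increasing in
#' body mass; doubling the mass multiplies the rate by 2^b.
#'
#' @param body_mass_g body mass in grams (vectorized, must be >= 0).
#' @param params [allometric_params()].
#' @return MJ/day.
#' @export
field_metabolic_rate <- function(body_mass_g, params = allometric_params()) {
  if (any(!is.finite(body_mass_g)) || any(body_mass_g < 0)) {
    stop("body mass must be finite and non-negative", call. = FALSE)
  }
  params$coefficient * body_mass_g^params$exponent / 1000
}

#' Invert the field-metabolic-rate equation
#'
#' Body mass (grams) implied by a daily metabolizable energy requirement;
#' the closed-form inverse BM = (1000 * ME / a)^(1/b). Used to back-derive
#' the default body-mass table from reference daily requirements.
#'
#' @param mj_per_day daily requirement in MJ/day (>= 0).
#' @inheritParams field_metabolic_rate
#' @return body mass in grams.
#' @export
invert_field_metabolic_rate <- function(mj_per_day, params = allometric_params()) {
  if (any(!is.finite(mj_per_day)) || any(mj_per_day < 0)) {
    stop("daily requirement must be finite and non-negative", call. = FALSE)
  }
  (1000 * mj_per_day / params$coefficient)^(1 / params$exponent)
}

#' Daily energy requirement table
#'
#' Daily metabolizable energy requirement (MJ/day) for every eligible
#' (species, age class, season) cell, evaluated at the end-of-season body
#' mass. Cells where the species does not graze (cattle and camels outside
#' high summer) are absent from the table.
#'
#' @param profiles [default_species_profiles()] or a modified copy.
#' @param calendar [season_calendar()].
#' @param species optional subset of species ids.
#' @return data.frame `species`, `age_class`, `season`, `mj_per_day`.
#' @export
daily_requirement_table <- function(profiles = default_species_profiles(),
                                    calendar = season_calendar(),
                                    species = NULL) {
  bm <- profiles$body_mass
  if (!is.null(species)) bm <- bm[bm$species %in% species, , drop = FALSE]
  keep <- mapply(is_eligible, species = bm$species, season = bm$season,
                 MoreArgs = list(profiles = profiles))
  bm <- bm[keep, , drop = FALSE]
  bad <- !is.finite(bm$body_mass_g) | bm$body_mass_g <= 0
  if (any(bad)) {
    stop("missing or non-positive body mass for eligible cell(s): ",
         paste(sprintf("%s/%s/%s", bm$species[bad], bm$age_class[bad],
                       bm$season[bad]), collapse = ", "), call. = FALSE)
  }
  data.frame(species = bm$species, age_class = bm$age_class, season = bm$season,
             mj_per_day = field_metabolic_rate(bm$body_mass_g,
                                               profiles$allometry),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annual energy requirement of a year-round grazer
#'
#' Sum over seasons of daily requirement times season length, for species
#' kept on the pastures the whole year. Species grazing only part of the
#' year (cattle, camels) have no annual requirement; use the seasonal table.
#'
#' @param species,age_class the animal class.
#' @inheritParams daily_requirement_table
#' @return MJ/year (scalar).
#' @export
annual_requirement <- function(species, age_class = "adult",
                               profiles = default_species_profiles(),
                               calendar = season_calendar()) {
  missing_seasons <- setdiff(calendar$season, profiles$eligibility[[species]])
  if (length(missing_seasons)) {
    stop(sprintf(
      "'%s' does not graze year-round (absent in %s); use seasonal totals",
      species, paste(missing_seasons, collapse = ", ")), call. = FALSE)
  }
  daily <- daily_requirement_table(profiles, calendar, species = species)
  daily <- daily[daily$age_class == age_class, , drop = FALSE]
  if (nrow(daily) != nrow(calendar)) {
    stop(sprintf("no body mass for %s/%s in every season", species, age_class),
         call. = FALSE)
  }
  sum(daily$mj_per_day * season_days(calendar, daily$season))
}

validate_census <- function(census, profiles, require_area = TRUE) {
  need <- c("year", "season", "species", "age_class", "count")
  if (require_area) need <- c(need, "area_id")
  miss <- setdiff(need, names(census))
  if (length(miss)) stop("census lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  bad_sp <- setdiff(unique(census$species), profiles$species$species)
  if (length(bad_sp)) stop("unknown species in census: ",
                           paste(bad_sp, collapse = ", "), call. = FALSE)
  if (any(census$count < 0 | census$count != round(census$count))) {
    stop("census counts must be non-negative integers", call. = FALSE)
  }
  invisible(census)
}

#' Seasonal energy demand per grazing area
#'
#' Sums, for every (year, season, grazing area), headcount times daily
#' requirement times season length over all census records. Demand is
#' additive over records, so disjoint censuses can be computed separately
#' and summed.
#'
#' @param census data.frame with columns `year`, `season`, `area_id`,
#'   `species`, `age_class`, `count` (seasons in calendar terms:
#'   `early_summer`, `high_summer`, `winter`).
#' @inheritParams daily_requirement_table
#' @return demand table: data.frame `year`, `season`, `area_id`, `group`
#'   (`"livestock"`), `species`, `energy_mj`.
#' @export
seasonal_area_demand <- function(census, profiles = default_species_profiles(),
                                 calendar = season_calendar()) {
  empty <- data.frame(year = integer(), season = character(),
                      area_id = character(), group = character(),
                      species = character(), energy_mj = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(census)) return(empty)
  validate_census(census, profiles)
  bad_season <- setdiff(unique(census$season), calendar$season)
  if (length(bad_season)) {
    stop("census seasons not in calendar: ", paste(bad_season, collapse = ", "),
         call. = FALSE)
  }
  daily <- daily_requirement_table(profiles, calendar)
  key <- function(d) paste(d$species, d$age_class, d$season, sep = "\r")
  rate <- daily$mj_per_day[match(key(census), key(daily))]
  if (anyNA(rate)) {
    off <- census[is.na(rate), c("species", "age_class", "season")]
    stop("no daily requirement for census cell(s): ",
         paste(unique(sprintf("%s/%s/%s", off$species, off$age_class,
                              off$season)), collapse = ", "), call. = FALSE)
  }
  energy <- census$count * rate * season_days(calendar, census$season)
  agg <- stats::aggregate(
    energy,
    by = list(year = census$year, season = census$season,
              area_id = census$area_id, species = census$species),
    FUN = sum
  )
  data.frame(year = agg$year, season = agg$season, area_id = agg$area_id,
             group = "livestock", species = agg$species, energy_mj = agg$x,
             stringsAsFactors = FALSE)
}

#' Small livestock units (SLU)
#'
#' Headcount of small livestock (sheep and goats) plus large livestock (yak,
#' cattle, camels) times three, summed over the supplied census records.
#'
#' @param census census records (any grouping; typically one year x season).
#' @param profiles species profiles carrying the size classes.
#' @return integer SLU count.
#' @export
small_livestock_units <- function(census,
                                  profiles = default_species_profiles()) {
  if (!nrow(census)) return(0L)
  sz <- profiles$species$size_class[match(census$species,
                                          profiles$species$species)]
  if (anyNA(sz)) {
    stop("species without a livestock size class: ",
         paste(unique(census$species[is.na(sz)]), collapse = ", "),
         call. = FALSE)
  }
  as.integer(sum(census$count * ifelse(sz == "large", 3L, 1L)))
}

#' Impute winter census records from summer/winter stocking ratios
#'
#' Winter surveys exist for a few reference years only. For every other year
#' the winter headcount per species (and age class) is imputed as the summer
#' count times the mean winter/summer ratio over the reference years,
#' rounded half-up to an integer. Species never observed in winter get ratio
#' 0 with a warning. Years with observed winter counts pass through
#' unchanged (`imputed = FALSE`).
#'
#' @param census records with `season` in `{"summer", "winter"}` (all-age or
#'   per-age rows; ratios are pooled over age classes per species).
#' @param reference_years years whose winter counts are observed (default
#'   2015-2017).
#' @return census data.frame with winter rows for all years and a logical
#'   `imputed` column.
#' @export
impute_winter_census <- function(census, reference_years = c(2015, 2016, 2017)) {
  stopifnot(all(c("year", "season", "species", "count") %in% names(census)))
  census$imputed <- FALSE
  ref <- census[census$year %in% reference_years, , drop = FALSE]
  ratio_of <- function(sp) {
    # no winter record at all (as opposed to a counted zero) -> NA -> warned
    if (!any(ref$season == "winter" & ref$species == sp)) return(NA_real_)
    r <- vapply(reference_years, function(y) {
      s <- sum(ref$count[ref$year == y & ref$season == "summer" &
                           ref$species == sp])
      w <- sum(ref$count[ref$year == y & ref$season == "winter" &
                           ref$species == sp])
      if (s > 0) w / s else NA_real_
    }, 0)
    r <- r[is.finite(r)]
    if (!length(r)) return(NA_real_)
    mean(r)
  }
  species <- unique(census$species)
  ratios <- vapply(species, ratio_of, 0)
  never_winter <- is.na(ratios) | ratios == 0
  if (any(is.na(ratios))) {
    warning("species never observed in winter reference years, ratio set to 0: ",
            paste(species[is.na(ratios)], collapse = ", "), call. = FALSE)
    ratios[is.na(ratios)] <- 0
  }
  years_obs_winter <- unique(census$year[census$season == "winter"])
  todo <- setdiff(unique(census$year), years_obs_winter)
  extra <- lapply(todo, function(y) {
    s <- census[census$year == y & census$season == "summer", , drop = FALSE]
    if (!nrow(s)) return(NULL)
    s$season <- "winter"
    s$count <- floor(s$count * ratios[s$species] + 0.5)  # round half-up
    s$imputed <- TRUE
    s
  })
  out <- rbind(census, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Energy demand of wild herbivores
#'
#' Wild herbivores (marmots, argali, ibex) graze without grazing-area
#' restrictions; their population is density times total vegetated area,
#' distributed over grazing areas in proportion to each area's vegetated
#' hectares. Seasonal energy is individuals times the field metabolic rate
#' at the seasonal body mass times the days active in that season (marmot
#' hibernation gives 0 active winter days).
#'
#' @param vegetated_km2 named numeric vector: vegetated km^2 per `area_id`.
#' @inheritParams daily_requirement_table
#' @return demand table rows with `group` `"marmot"`/`"wild_ungulate"`.
#' @export
wildlife_demand <- function(vegetated_km2,
                            profiles = default_species_profiles(),
                            calendar = season_calendar()) {
  stopifnot(length(vegetated_km2) > 0, !is.null(names(vegetated_km2)))
  sp <- profiles$species[profiles$species$wildlife, , drop = FALSE]
  total_km2 <- sum(vegetated_km2)
  share <- vegetated_km2 / total_km2
  out <- list()
  for (i in seq_len(nrow(sp))) {
    dens <- sp$density_per_km2[i]
    if (is.na(dens)) {
      stop("wildlife species without configured density: ", sp$species[i],
           call. = FALSE)
    }
    if (dens == 0) next
    active <- profiles$active_days[[sp$species[i]]]
    if (is.null(active)) {
      stop("wildlife species without active-day configuration: ",
           sp$species[i], call. = FALSE)
    }
    n_total <- dens * total_km2
    for (season in calendar$season) {
      days <- active[[season]]
      if (is.null(days) || days == 0) next
      bm <- profile_body_mass(profiles, sp$species[i], "adult", season)
      if (is.na(bm)) {
        stop(sprintf("missing body mass for %s in %s", sp$species[i], season),
             call. = FALSE)
      }
      e_total <- n_total * field_metabolic_rate(bm, profiles$allometry) * days
      out[[length(out) + 1]] <- data.frame(
        year = NA_integer_, season = season, area_id = names(vegetated_km2),
        group = sp$wildlife_group[i], species = sp$species[i],
        energy_mj = e_total * as.numeric(share), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(year = integer(), season = character(),
                      area_id = character(), group = character(),
                      species = character(), energy_mj = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Scale livestock demand for the elevated-requirement scenario
#'
#' Multiplies the energy of non-exempt livestock entries by a factor
#' (default scenario: 1.3, i.e. 30% higher requirements from altitude and
#' low-temperature effects). Exempt species (default: yak) and all wildlife
#' entries are left unchanged.
#'
#' @param demand a demand table from [seasonal_area_demand()] (optionally
#'   with wildlife rows appended).
#' @param factor multiplicative factor (> 0).
#' @param exempt species ids not scaled.
#' @return demand table with scaled `energy_mj`.
#' @export
apply_mer_scenario <- function(demand, factor = 1.3, exempt = "yak") {
  stopifnot(factor > 0)
  scale <- demand$group == "livestock" & !(demand$species %in% exempt)
  demand$energy_mj[scale] <- demand$energy_mj[scale] * factor
  demand
}
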