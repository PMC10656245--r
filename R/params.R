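#' Allometric field-metabolic-rate parameters
#'
#' Parameters of the allometric prediction of daily metabolizable energy
#' expenditure of free-ranging mammals, ME = a * BM^b / 1000, with body mass
#' BM in grams and ME in MJ/day. The defaults (a = 4.82, b = 0.734) are the
#' published field-metabolic-rate coefficients for free-ranging mammals used
#' throughout this package.
#'
#' @param coefficient multiplier a (> 0).
#' @param exponent power b (0 < b < 1).
#' @return list of class `allometric_params`.
#' @export
allometric_params <- function(coefficient = 4.82, exponent = 0.734) {
  stopifnot(coefficient > 0, exponent > 0, exponent < 1)
  structure(list(coefficient = coefficient, exponent = exponent,
                 mass_unit = "g", output_unit = "MJ/day"),
            class = "allometric_params")
}

#' Seasonal grazing calendar
#'
#' The transhumance year is split into three grazing seasons: early summer
#' (May-June, 61 days), high summer (July-September, 92 days) and winter
#' (October-April, 212 days), a non-leap-year partition summing to 365 days.
#' Winter is attributed to the preceding growing-season year (an early-spring
#' winter census counts toward the previous year).
#'
#' @param days named integer vector of day counts per season.
#' @return data.frame `season`, `days`, `months` of class `season_calendar`.
#' @export
season_calendar <- function(days = c(early_summer = 61L, high_summer = 92L,
                                     winter = 212L)) {
  stopifnot(sum(days) == 365L,
            setequal(names(days), c("early_summer", "high_summer", "winter")))
  months <- c(early_summer = "May-Jun", high_summer = "Jul-Sep",
              winter = "Oct-Apr")
  out <- data.frame(season = names(days), days = as.integer(days),
                    months = months[names(days)], stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("season_calendar", "data.frame")
  out
}

season_names <- function(calendar) calendar$season

season_days <- function(calendar, season) {
  i <- match(season, calendar$season)
  if (anyNA(i)) stop("unknown season: ", paste(season[is.na(i)], collapse = ", "),
                     call. = FALSE)
  calendar$days[i]
}

#' Reference daily energy requirements per species, age class and season
#'
#' Daily metabolizable energy requirements (MJ/day) of the Big Pamir
#' livestock species at end-of-season body masses, for animals older and
#' younger than one year. Cattle and camels graze in the study system during
#' high summer only, so only that cell is defined for them. These values
#' anchor the default body-mass table (see [default_species_profiles()]).
#'
#' @return data.frame `species`, `age_class`, `season`, `mj_per_day`.
#' @export
reference_daily_mer <- function() {
  rows <- rbind(
    c("goat",  "adult", "early_summer", 10.87), c("goat",  "young", "early_summer",  8.25),
    c("goat",  "adult", "high_summer",  13.67), c("goat",  "young", "high_summer",  11.11),
    c("goat",  "adult", "winter",        8.86), c("goat",  "young", "winter",        6.14),
    c("sheep", "adult", "early_summer", 11.96), c("sheep", "young", "early_summer",  9.79),
    c("sheep", "adult", "high_summer",  14.68), c("sheep", "young", "high_summer",  12.51),
    c("sheep", "adult", "winter",       10.03), c("sheep", "young", "winter",        7.83),
    c("yak",   "adult", "early_summer", 38.42), c("yak",   "young", "early_summer", 17.28),
    c("yak",   "adult", "high_summer",  42.80), c("yak",   "young", "high_summer",  20.60),
    c("yak",   "adult", "winter",       35.41), c("yak",   "young", "winter",       13.75),
    c("cattle", "adult", "high_summer", 40.18),
    c("camel",  "adult", "high_summer", 77.49)
  )
  data.frame(species = rows[, 1], age_class = rows[, 2], season = rows[, 3],
             mj_per_day = as.numeric(rows[, 4]), stringsAsFactors = FALSE)
}

#' Default species profiles
#'
#' Builds the per-species parameter set used by the energy-demand module:
#' end-of-season body masses per age class, small/large size class for
#' small-livestock-unit (SLU) accounting, seasonal grazing eligibility,
#' exemption from the elevated-requirement scenario (yak, being
#' evolutionarily adapted to the cold high-altitude environment), and
#' wildlife attributes (habitat-wide density, days active per season).
#'
#' Livestock body masses are back-derived from the reference daily
#' requirements by inverting the allometric equation, which makes the daily
#' requirement table reproduce those values exactly while remaining fully
#' overridable with field-weighed masses. Wild-ungulate densities and masses
#' are synthetic placeholders (no regional values are bundled); their default
#' density is 0 so they only enter the assessment when configured. Marmots
#' hibernate: they are active May-September (61 + 92 days) and inactive in
#' winter.
#'
#' @param params [allometric_params()] used for the body-mass inversion.
#' @param calendar [season_calendar()].
#' @param marmot_density_per_km2 long-tailed marmot density on vegetated
#'   habitat (default 16.3 individuals/km^2, from regional observations).
#' @param argali_density_per_km2,ibex_density_per_km2 wild-ungulate densities
#'   (defaults 0; synthetic placeholders, not survey values).
#' @return list of class `species_profiles` with elements `species`
#'   (attributes table) and `body_mass` (per species x age class x season).
#' @export
default_species_profiles <- function(params = allometric_params(),
                                     calendar = season_calendar(),
                                     marmot_density_per_km2 = 16.3,
                                     argali_density_per_km2 = 0,
                                     ibex_density_per_km2 = 0) {
  ref <- reference_daily_mer()
  bm <- data.frame(
    species = ref$species, age_class = ref$age_class, season = ref$season,
    body_mass_g = invert_field_metabolic_rate(ref$mj_per_day, params),
    stringsAsFactors = FALSE
  )
  # wildlife masses (g): marmot pre/post-summer fattening; ungulate placeholders
  bm <- rbind(bm, data.frame(
    species = c("marmot", "marmot",
                "argali", "argali", "argali", "ibex", "ibex", "ibex"),
    age_class = "adult",
    season = c("early_summer", "high_summer",
               "early_summer", "high_summer", "winter",
               "early_summer", "high_summer", "winter"),
    body_mass_g = c(4000, 6500, 80000, 90000, 75000, 50000, 60000, 45000),
    stringsAsFactors = FALSE
  ))
  species <- data.frame(
    species = c("goat", "sheep", "yak", "cattle", "camel",
                "marmot", "argali", "ibex"),
    size_class = c("small", "small", "large", "large", "large", NA, NA, NA),
    wildlife = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    wildlife_group = c(NA, NA, NA, NA, NA,
                       "marmot", "wild_ungulate", "wild_ungulate"),
    mer_scenario_exempt = c(FALSE, FALSE, TRUE, FALSE, FALSE,
                            FALSE, FALSE, FALSE),
    density_per_km2 = c(NA, NA, NA, NA, NA, marmot_density_per_km2,
                        argali_density_per_km2, ibex_density_per_km2),
    stringsAsFactors = FALSE
  )
  elig <- list(
    goat = calendar$season, sheep = calendar$season, yak = calendar$season,
    cattle = "high_summer", camel = "high_summer",
    marmot = c("early_summer", "high_summer"),
    argali = calendar$season, ibex = calendar$season
  )
  active <- list(  # wildlife days active per season (hibernation)
    marmot = c(early_summer = 61, high_summer = 92, winter = 0),
    argali = c(early_summer = 61, high_summer = 92, winter = 212),
    ibex   = c(early_summer = 61, high_summer = 92, winter = 212)
  )
  structure(list(species = species, body_mass = bm, eligibility = elig,
                 active_days = active, allometry = params),
            class = "species_profiles")
}

profile_body_mass <- function(profiles, species, age_class, season) {
  bm <- profiles$body_mass
  i <- bm$species == species & bm$age_class == age_class & bm$season == season
  if (!any(i)) return(NA_real_)
  bm$body_mass_g[which(i)[1]]
}

is_eligible <- function(profiles, species, season) {
  el <- profiles$eligibility[[species]]
  !is.null(el) && season %in% el
}

#' Default vegetation-community forage parameters
#'
#' Forage quality (metabolizable energy per kg dry matter, from laboratory
#' analyses of regional community samples), the fraction of standing biomass
#' physically consumable by livestock (0.5 for woody dwarf-shrub deserts and
#' steppes, 0.8 for all other communities), and the productivity ratio
#' (annual aboveground production / standing biomass, from exclosure pairs).
#' The default productivity ratio of 1 means the biomass raster is already
#' expressed as annual production; replace it with an exclosure-derived
#' estimate when working from standing-biomass maps.
#'
#' @param productivity_ratio single value or named vector per community.
#' @return data.frame `community_id`, `forage_quality`, `consumable_fraction`,
#'   `productivity_ratio`.
#' @export
default_community_params <- function(productivity_ratio = 1) {
  ids <- c("riparian_grassland", "salix_riparian", "salt_grass",
           "dwarf_shrub_steppe", "alpine_grassland")
  pr <- if (length(productivity_ratio) == 1) rep(productivity_ratio, 5)
        else productivity_ratio[ids]
  stopifnot(all(is.finite(pr)), all(pr > 0))
  data.frame(
    community_id = ids,
    forage_quality = c(9.4, 9.4, 9.1, 6.3, 9.1),       # MJ/kg DM
    consumable_fraction = c(0.8, 0.8, 0.8, 0.5, 0.8),
    productivity_ratio = as.numeric(pr),
    stringsAsFactors = FALSE
  )
}

#' Canonical land-cover class table
#'
#' Maps integer raster class codes to community ids. Code 0 is reserved for
#' non-vegetated cover (water, snow and ice, rock and scree), which is
#' excluded from all forage accounting.
#'
#' @return data.frame `code`, `community_id`.
#' @export
default_class_table <- function() {
  data.frame(
    code = 0:5,
    community_id = c("non_vegetated", "riparian_grassland", "salix_riparian",
                     "salt_grass", "dwarf_shrub_steppe", "alpine_grassland"),
    stringsAsFactors = FALSE
  )
}

#' Big Pamir livestock census totals
#'
#' All-age livestock headcounts per species for the Western Big Pamir grazing
#' system, summer and winter seasons of the survey years 2006 and 2010-2020
#' (winter attributed to the preceding growing season; cattle counted in one
#' year and assumed constant; camels first recorded in 2016). Winter counts
#' of species that do not overwinter on the pastures (cattle, camels) are 0.
#'
#' @return data.frame `year`, `season` ("summer"/"winter"), `species`,
#'   `count`.
#' @export
bigpamir_census <- function() {
  years <- c(2006, 2010:2020)
  counts <- list(
    goat   = list(s = c(1059, 3663, 4054, 3886, 4982, 5490, 5151, 4547, 4555, 5349, 4801, 5596),
                  w = c(205, 451, 438, 413, 722, 350, 504, 770, 770, 917, 760, 875)),
    sheep  = list(s = c(6525, 8101, 7344, 8046, 11017, 10093, 10306, 9187, 9033, 9321, 8110, 9576),
                  w = c(1017, 1070, 938, 1023, 1404, 3177, 3966, 4295, 4295, 2070, 1871, 2214)),
    yak    = list(s = c(683, 905, 949, 915, 1081, 936, 966, 907, 978, 764, 726, 849),
                  w = c(106, 114, 102, 86, 118, 145, 233, 205, 205, 138, 123, 146)),
    cattle = list(s = rep(982, 12), w = rep(0, 12)),
    camel  = list(s = c(0, 0, 0, 0, 0, 0, 0, 30, 30, 17, 31, 22), w = rep(0, 12))
  )
  do.call(rbind, lapply(names(counts), function(sp) {
    data.frame(year = rep(years, 2),
               season = rep(c("summer", "winter"), each = length(years)),
               species = sp,
               count = c(counts[[sp]]$s, counts[[sp]]$w),
               stringsAsFactors = FALSE)
  }))
}

#' Community biomass productivity reference table
#'
#' Total yearly aboveground biomass productivity (kg DM/ha) averaged per
#' vegetation community for 2016-2020 in the Big Pamir study region, from
#' the remote-sensing biomass model combined with exclosure-derived
#' productivity ratios.
#'
#' @return data.frame `community_id`, one column per year `y2016`...`y2020`.
#' @export
bigpamir_productivity <- function() {
  data.frame(
    community_id = c("riparian_grassland", "salix_riparian", "salt_grass",
                     "dwarf_shrub_steppe", "alpine_grassland"),
    y2016 = c(1609, 1900, 679, 535, 941),
    y2017 = c(1745, 1964, 715, 556, 1005),
    y2018 = c(1762, 1994, 636, 420, 881),
    y2019 = c(1866, 2030, 624, 435, 887),
    y2020 = c(1663, 2023, 553, 357, 787),
    stringsAsFactors = FALSE
  )
}

#' Mean metabolizable energy content per community (reference)
#'
#' Modeled mean yearly MEC available to herbivores (MJ/ha, 2016-2020
#' average) per vegetation community in the Big Pamir study region.
#'
#' @return named numeric vector (MJ/ha/year).
#' @export
bigpamir_mec_means <- function() {
  c(riparian_grassland = 12967, salix_riparian = 14866, salt_grass = 4682,
    dwarf_shrub_steppe = 1428, alpine_grassland = 6573)
}
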