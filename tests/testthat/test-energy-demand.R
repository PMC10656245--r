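test_that("field metabolic rate follows the allometric law", {
  expect_equal(field_metabolic_rate(0), 0)
  expect_equal(field_metabolic_rate(1000), 4.82 * 1000^0.734 / 1000,
               tolerance = 1e-12)
  expect_equal(field_metabolic_rate(1000), 0.7675, tolerance = 1e-4)
  # strictly increasing, and doubling mass scales the rate by 2^0.734
  bm <- c(500, 2000, 40000, 250000)
  expect_true(all(diff(field_metabolic_rate(bm)) > 0))
  expect_equal(field_metabolic_rate(2 * bm) / field_metabolic_rate(bm),
               rep(2^0.734, length(bm)), tolerance = 1e-12)
  expect_error(field_metabolic_rate(-1), "non-negative")
})

test_that("allometric inversion round-trips and matches a root-finding oracle", {
  me <- c(8.86, 14.68, 42.80)
  expect_equal(field_metabolic_rate(invert_field_metabolic_rate(me)), me,
               tolerance = 1e-10)
  # independent oracle: numeric root of fmr(bm) - 14.68 = 0
  root <- uniroot(function(bm) field_metabolic_rate(bm) - 14.68,
                  c(1e3, 1e6), tol = 1e-8)$root
  expect_equal(invert_field_metabolic_rate(14.68), root, tolerance = 1e-5)
  expect_equal(root / 1000, 55.8, tolerance = 0.01)  # ~55.8 kg adult sheep
})

test_that("daily requirement table reproduces reference dailies and eligibility", {
  ref <- reference_daily_mer()
  d <- daily_requirement_table(species = unique(ref$species))
  key <- function(x) paste(x$species, x$age_class, x$season)
  expect_setequal(key(d), key(ref))
  expect_equal(d$mj_per_day[match(key(ref), key(d))], ref$mj_per_day,
               tolerance = 1e-10)
  # cattle and camels graze high summer only
  expect_false(any(d$species %in% c("cattle", "camel") &
                     d$season != "high_summer"))
})

test_that("missing body mass for an eligible cell names the cell", {
  p <- default_species_profiles()
  p$body_mass$body_mass_g[p$body_mass$species == "goat" &
                            p$body_mass$season == "winter" &
                            p$body_mass$age_class == "adult"] <- NA
  expect_error(daily_requirement_table(p), "goat/adult/winter")
})

test_that("annual requirements match published annual sums within rounding", {
  expect_equal(annual_requirement("yak"), 13789, tolerance = 2 / 13789)
  expect_equal(annual_requirement("sheep"), 4207, tolerance = 2 / 4207)
  expect_equal(annual_requirement("goat"), 3798, tolerance = 2 / 3798)
  expect_error(annual_requirement("cattle"), "seasonal")
})

test_that("seasonal area demand sums count x daily x days and is additive", {
  d <- seasonal_area_demand(tiny_census(count = 10))
  expect_equal(nrow(d), 1)
  expect_equal(d$energy_mj, 10 * 14.68 * 92, tolerance = 1e-6)
  # empty census
  expect_equal(nrow(seasonal_area_demand(tiny_census()[0, ])), 0)
  # symmetry: identical herds in two areas give identical demand
  two <- rbind(tiny_census(area_id = "A"), tiny_census(area_id = "B"))
  dd <- seasonal_area_demand(two)
  expect_equal(dd$energy_mj[dd$area_id == "A"], dd$energy_mj[dd$area_id == "B"])
  # additivity over disjoint censuses
  a <- tiny_census(species = "goat", count = 7)
  b <- tiny_census(species = "yak", count = 3, season = "winter")
  both <- seasonal_area_demand(rbind(a, b))
  expect_equal(sum(both$energy_mj),
               sum(seasonal_area_demand(a)$energy_mj) +
                 sum(seasonal_area_demand(b)$energy_mj))
  expect_error(seasonal_area_demand(tiny_census(species = "llama")),
               "unknown species")
})

test_that("small livestock units weight large stock by three", {
  expect_equal(small_livestock_units(bigpamir_records(2006, "summer")), 12579L)
  expect_equal(small_livestock_units(bigpamir_records(2016, "summer")), 19491L)
  zero <- bigpamir_records(2006, "summer"); zero$count <- 0
  expect_equal(small_livestock_units(zero), 0L)
  expect_equal(small_livestock_units(zero[0, ]), 0L)
})

test_that("winter imputation uses the mean winter/summer ratio per species", {
  mk <- function(year, season, count) {
    data.frame(year = year, season = season, species = "sheep",
               age_class = "all", area_id = "A", count = count,
               stringsAsFactors = FALSE)
  }
  cen <- rbind(mk(2015, "summer", 10), mk(2015, "winter", 2),
               mk(2016, "summer", 10), mk(2016, "winter", 4),
               mk(2017, "summer", 10), mk(2017, "winter", 6),
               mk(2018, "summer", 1000))
  out <- impute_winter_census(cen)
  imp <- out[out$year == 2018 & out$season == "winter", ]
  expect_equal(imp$count, 400)  # mean ratio (0.2+0.4+0.6)/3 = 0.4
  expect_true(imp$imputed)
  # observed winters pass through unchanged
  expect_false(any(out$imputed[out$year %in% 2015:2017]))
  expect_equal(sum(out$season == "winter" & out$year == 2016), 1)
  # constant ratio 0.5 on summer 100 -> 50
  cen2 <- rbind(mk(2015, "summer", 100), mk(2015, "winter", 50),
                mk(2016, "summer", 200), mk(2016, "winter", 100),
                mk(2017, "summer", 40), mk(2017, "winter", 20),
                mk(2019, "summer", 100))
  out2 <- impute_winter_census(cen2)
  expect_equal(out2$count[out2$year == 2019 & out2$season == "winter"], 50)
})

test_that("species never observed in winter impute zero with a warning", {
  mk <- function(year, season, sp, count) {
    data.frame(year = year, season = season, species = sp, age_class = "all",
               area_id = "A", count = count, stringsAsFactors = FALSE)
  }
  cen <- rbind(mk(2015, "summer", "camel", 30), mk(2016, "summer", "camel", 30),
               mk(2017, "summer", "camel", 30), mk(2015, "winter", "sheep", 5),
               mk(2015, "summer", "sheep", 10), mk(2016, "summer", "sheep", 10),
               mk(2016, "winter", "sheep", 5), mk(2017, "summer", "sheep", 10),
               mk(2017, "winter", "sheep", 5), mk(2018, "summer", "camel", 30))
  expect_warning(out <- impute_winter_census(cen), "camel")
  expect_equal(out$count[out$year == 2018 & out$season == "winter" &
                           out$species == "camel"], 0)
})

test_that("wildlife demand scales with density, mass and active days", {
  p <- default_species_profiles(marmot_density_per_km2 = 16.3)
  cal <- season_calendar()
  wd <- wildlife_demand(c(A = 10), profiles = p, calendar = cal)
  marm <- wd[wd$group == "marmot", ]
  # 163 marmots, active in the two summer seasons only (hibernation)
  expect_setequal(marm$season, c("early_summer", "high_summer"))
  bm_es <- p$body_mass$body_mass_g[p$body_mass$species == "marmot" &
                                     p$body_mass$season == "early_summer"]
  expect_equal(marm$energy_mj[marm$season == "early_summer"],
               163 * field_metabolic_rate(bm_es) * 61, tolerance = 1e-10)
  # distribution proportional to vegetated area
  wd2 <- wildlife_demand(c(A = 3, B = 7), profiles = p)
  m2 <- wd2[wd2$group == "marmot" & wd2$season == "high_summer", ]
  expect_equal(m2$energy_mj[m2$area_id == "A"] /
                 m2$energy_mj[m2$area_id == "B"], 3 / 7, tolerance = 1e-10)
  # zero active days -> no demand rows
  p0 <- p; p0$active_days$marmot[] <- 0
  expect_equal(nrow(wildlife_demand(c(A = 10), profiles = p0)), 0)
})

test_that("the elevated-requirement scenario spares exempt species and wildlife", {
  sheep <- seasonal_area_demand(tiny_census(species = "sheep"))
  yak <- seasonal_area_demand(tiny_census(species = "yak"))
  expect_equal(apply_mer_scenario(sheep, 1.3)$energy_mj, sheep$energy_mj * 1.3)
  expect_equal(apply_mer_scenario(yak, 1.3)$energy_mj, yak$energy_mj)
  expect_equal(apply_mer_scenario(sheep, 1.0)$energy_mj, sheep$energy_mj)
  wl <- wildlife_demand(c(A = 10))
  expect_equal(apply_mer_scenario(wl, 1.3)$energy_mj, wl$energy_mj)
  # all-exempt herd: identity
  mixed <- rbind(sheep, yak)
  expect_equal(apply_mer_scenario(mixed, 1.3, exempt = c("sheep", "yak")),
               mixed)
})
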