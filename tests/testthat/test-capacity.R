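test_that("utilization, potential, capacity and classification arithmetic", {
  expect_equal(utilization_rate(100, 100), 100)
  expect_equal(utilization_rate(40, 100), 40)
  expect_equal(utilization_rate(0, 100), 0)
  expect_equal(utilization_rate(10, 0), Inf)
  expect_equal(utilization_rate(0, 0), 0)
  expect_error(utilization_rate(-1, 10), "non-negative")
  expect_equal(grazing_potential(4207, 4207), 1)
  expect_equal(carrying_capacity(1), 0.4)
  expect_equal(carrying_capacity(0), 0)
  expect_equal(classify_sustainability(c(39, 40, 40.01, 77, 100, 101, Inf)),
               c("sustainable", "sustainable", "unsustainable",
                 "unsustainable", "unsustainable", "over_potential",
                 "over_potential"))
})

test_that("community-level potential and capacity reproduce published cells", {
  mec <- bigpamir_mec_means()
  yak <- annual_requirement("yak")
  sheep <- annual_requirement("sheep")
  goat <- annual_requirement("goat")
  expect_equal(grazing_potential(mec[["riparian_grassland"]], yak), 0.94,
               tolerance = 0.01 / 0.94)
  expect_equal(grazing_potential(mec[["dwarf_shrub_steppe"]], sheep), 0.34,
               tolerance = 0.01 / 0.34)
  expect_equal(carrying_capacity(
    grazing_potential(mec[["alpine_grassland"]], goat)), 0.69,
    tolerance = 0.01 / 0.69)
  expect_equal(carrying_capacity(
    grazing_potential(mec[["salix_riparian"]], goat)), 1.57,
    tolerance = 0.01 / 1.57)
  # round trips hold to machine precision
  pot <- grazing_potential(mec[["salt_grass"]], sheep)
  expect_equal(pot * sheep, mec[["salt_grass"]], tolerance = 1e-12)
  expect_equal(carrying_capacity(pot) / pot, 0.4, tolerance = 1e-12)
})

test_that("area supply counts each accessible pixel's annual energy once", {
  g <- one_area_grid(matrix(0, 10, 10))
  mec <- rc_set_values(g$grid, matrix(1000, 10, 10))  # MJ/ha on 0.01-ha pixels
  full <- rc_set_values(g$grid, matrix(1, 10, 10))
  s <- aggregate_available_energy(mec, g$area_raster, list(full))
  expect_equal(s$supply_mj, 1000 * 1)  # 1 ha fully accessible
  # a pixel accessible in two seasons still counts once
  s2 <- aggregate_available_energy(mec, g$area_raster, list(full, full))
  expect_equal(s2$supply_mj, s$supply_mj)
  # half masked everywhere -> half the energy
  half <- rc_set_values(g$grid, matrix(rep(c(1, 0), 50), 10, 10))
  s3 <- aggregate_available_energy(mec, g$area_raster, list(half))
  expect_equal(s3$supply_mj, 500)
  # empty mask -> zero supply with warning
  none <- rc_set_values(g$grid, matrix(0, 10, 10))
  expect_warning(s4 <- aggregate_available_energy(mec, g$area_raster,
                                                  list(none)),
                 "zero accessible")
  expect_equal(s4$supply_mj, 0)
})

test_that("two-community area supply matches a counting oracle", {
  grid <- rc_raster(matrix(0, 4, 4), res = 10)
  cls <- rc_set_values(grid, matrix(c(rep(1, 8), rep(4, 8)), 4, 4))
  standing <- rc_set_values(grid, matrix(1000, 4, 4))
  mec <- build_mec_map(standing, cls)
  areas <- rc_areas(data.frame(area_id = "A", has_winter_camp = TRUE),
                    list(A = cbind(c(0, 40, 40, 0), c(0, 0, 40, 40))))
  ar <- rasterize_areas(areas, grid)
  full <- rc_set_values(grid, matrix(1, 4, 4))
  s <- aggregate_available_energy(mec, ar, list(full))
  oracle <- 8 * 0.01 * (1000 * 0.8 * 9.4) + 8 * 0.01 * (1000 * 0.5 * 6.3)
  expect_equal(s$supply_mj, oracle, tolerance = 1e-10)
})

test_that("scenario runs are linear in demand and monotone in supply", {
  b <- small_bundle()
  basic <- run_scenario(b$inputs, scenario_config("basic"))
  # exact 1.3x for a sheep-only census (no exempt species present)
  sheep_only <- b$census[b$census$species == "sheep", ]
  inp <- b$inputs; inp$census <- sheep_only
  base_s <- run_scenario(inp, scenario_config("basic"))
  plus_s <- run_scenario(inp, scenario_config("mer_plus30"))
  expect_equal(plus_s$results$utilization_pct,
               1.3 * base_s$results$utilization_pct, tolerance = 1e-12)
  # yak-only herds are exempt from the scenario
  yak_only <- b$census[b$census$species == "yak", ]
  inp$census <- yak_only
  expect_equal(run_scenario(inp, scenario_config("mer_plus30"))$results$utilization_pct,
               run_scenario(inp, scenario_config("basic"))$results$utilization_pct,
               tolerance = 1e-12)
  # conservative biomass lowers supply, raises utilization everywhere
  cons <- run_scenario(b$inputs,
                       scenario_config("conservative_biomass",
                                       biomass_adjustment = 40))
  expect_true(all(cons$supply$supply_mj <= basic$supply$supply_mj))
  expect_true(all(cons$results$utilization_pct >=
                    basic$results$utilization_pct))
  # wildlife adds demand, never supply
  wild <- run_scenario(b$inputs, scenario_config("wildlife"))
  expect_equal(wild$supply$supply_mj, basic$supply$supply_mj)
  expect_true(all(wild$results$utilization_pct >=
                    basic$results$utilization_pct))
  expect_true(all(wild$results$demand_wildlife_mj > 0))
  # zero-density wildlife config collapses to the basic scenario
  p0 <- default_species_profiles(marmot_density_per_km2 = 0)
  inp0 <- b$inputs; inp0$profiles <- p0
  wild0 <- run_scenario(inp0, scenario_config("wildlife"))
  expect_equal(wild0$results$utilization_pct, basic$results$utilization_pct,
               tolerance = 1e-12)
})

test_that("dropping winter grazing zeroes winter-only demand", {
  b <- small_bundle()
  wc <- b$areas$table$area_id[b$areas$table$has_winter_camp][1]
  winter_census <- data.frame(year = 2020, season = "winter", area_id = wc,
                              species = "sheep", age_class = "adult",
                              count = 100, stringsAsFactors = FALSE)
  inp <- b$inputs; inp$census <- winter_census
  nw <- run_scenario(inp, scenario_config("no_winter"))
  expect_equal(sum(nw$results$demand_livestock_mj), 0)
  expect_equal(sum(nw$results$utilization_pct), 0)
  with_w <- run_scenario(inp, scenario_config("basic"))
  expect_gt(sum(with_w$results$demand_livestock_mj), 0)
})

test_that("region aggregates summarize the assessed pixels", {
  b <- small_bundle()
  res <- run_scenario(b$inputs, scenario_config("basic"))
  u <- rc_values(res$utilization)
  px <- u[is.finite(u)]
  expect_equal(res$region$mean_utilization_pct, mean(px))
  expect_equal(res$region$pct_area_unsustainable, 100 * mean(px > 40))
  expect_equal(res$region$assessed_ha, length(px) * 0.01)
  expect_true(res$region$utilization_min_pct <= res$region$utilization_max_pct)
  # painted rates match the per-area means
  ar <- rasterize_areas(b$areas, b$landscape$classes)
  for (i in seq_along(res$area_means$area_id)) {
    sel <- is.finite(u) & ar$values %in% i
    if (any(sel)) {
      expect_equal(unique(u[sel]), res$area_means$utilization_pct[i])
    }
  }
})
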