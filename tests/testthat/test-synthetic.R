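test_that("landscape generation is bit-reproducible under a fixed seed", {
  cfg <- landscape_config(nx = 40, ny = 40)
  a <- generate_landscape(cfg, seed = 9)
  b <- generate_landscape(cfg, seed = 9)
  expect_identical(rc_values(a$dem), rc_values(b$dem))
  expect_identical(rc_values(a$standing), rc_values(b$standing))
  expect_identical(rc_values(a$fsc_winter), rc_values(b$fsc_winter))
  expect_identical(lapply(a$bands, rc_values), lapply(b$bands, rc_values))
  c2 <- generate_landscape(cfg, seed = 10)
  expect_false(identical(rc_values(a$standing), rc_values(c2$standing)))
})

test_that("generated landscape honours the configured structure", {
  b <- small_bundle()
  ls <- b$landscape
  cfg <- ls$truth$config
  dem <- rc_values(ls$dem); code <- rc_values(ls$classes)
  expect_true(all(dem >= cfg$elev_range[1] & dem <= cfg$elev_range[2]))
  # elevation-correlated communities: riparian sits below alpine
  expect_lt(mean(dem[code == 1]), mean(dem[code == 5]))
  expect_lt(mean(dem[code == 5]), mean(dem[code == 0]))
  # per-community production means within 3 SE of configuration
  prod <- rc_values(ls$production)
  ct <- ls$class_table
  for (cid in names(cfg$production_mean)) {
    sel <- code == ct$code[ct$community_id == cid]
    n <- sum(sel)
    se <- cfg$production_sd[[cid]] / sqrt(n)
    expect_lt(abs(mean(prod[sel]) - cfg$production_mean[[cid]]), 3 * se + 1)
  }
  # winter snowier than spring on average
  expect_gt(mean(rc_values(ls$fsc_winter)), mean(rc_values(ls$fsc_spring)))
  # bands carry a recoverable biomass signal
  idx <- compute_vegetation_indices(ls$bands, ls$soil)
  veg <- code > 0
  expect_gt(cor(rc_values(idx$WDVI)[veg], prod[veg]), 0.6)
})

test_that("grazing system tiles the extent with configured winter camps", {
  b <- small_bundle()
  cfg <- b$landscape$truth$config
  expect_equal(nrow(b$areas$table), cfg$n_areas)
  expect_equal(sum(b$areas$table$has_winter_camp), cfg$n_winter_camps)
  ar <- rasterize_areas(b$areas, b$landscape$dem)
  expect_true(all(is.finite(rc_values(ar))))  # polygons cover the grid
  # single-area degenerate case covers everything
  cfg1 <- landscape_config(nx = 20, ny = 20, n_areas = 1, n_winter_camps = 1)
  ls1 <- generate_landscape(cfg1, seed = 2)
  ar1 <- rasterize_areas(generate_grazing_system(cfg1, ls1), ls1$dem)
  expect_true(all(rc_values(ar1) == 1))
  # winter camps sit in the lowest-lying areas
  dem <- rc_values(b$landscape$dem)
  elev <- vapply(seq_len(cfg$n_areas), function(i) {
    mean(dem[rc_values(ar) %in% i])
  }, 0)
  expect_true(all(rank(elev)[b$areas$table$has_winter_camp] <=
                    cfg$n_winter_camps))
})

test_that("census generation closes the loop on target utilization", {
  # pipeline consistency at any size: assessed utilization equals the
  # demand implied by the (rounded) census over the true supply
  b <- small_bundle()
  res <- run_scenario(b$inputs, scenario_config("basic"))
  dem <- seasonal_area_demand(b$census)
  supply_true <- attr(b$census, "true_supply_mj")
  for (id in names(supply_true)) {
    expect_equal(res$results$utilization_pct[res$results$area_id == id],
                 100 * sum(dem$energy_mj[dem$area_id == id]) /
                   supply_true[[id]],
                 tolerance = 1e-10)
  }
  # at full size the integer-herd rounding stays well under a point
  d <- default_bundle()
  res_d <- run_scenario(d$inputs, scenario_config("basic"))
  target <- attr(d$census, "target")
  err <- res_d$results$utilization_pct - 100 * target[res_d$results$area_id]
  expect_true(all(abs(err) < 2))
  # zero target -> empty census
  empty <- generate_census(d$landscape$truth$config, d$landscape, d$areas,
                           target_utilization = 0)
  expect_equal(nrow(empty), 0)
  # doubling the target about doubles the herd SLU
  c1 <- generate_census(d$landscape$truth$config, d$landscape, d$areas,
                        target_utilization = 0.3)
  c2 <- generate_census(d$landscape$truth$config, d$landscape, d$areas,
                        target_utilization = 0.6)
  hs <- function(x) x[x$season == "high_summer", ]
  expect_equal(small_livestock_units(hs(c2)) / small_livestock_units(hs(c1)),
               2, tolerance = 0.05)
  # areas without winter camps carry no winter herd
  no_camp <- d$areas$table$area_id[!d$areas$table$has_winter_camp]
  expect_false(any(d$census$area_id %in% no_camp &
                     d$census$season == "winter"))
})

test_that("field campaign stratification, noise and exclosure encoding", {
  b <- small_bundle()
  camp <- generate_field_campaign(b$landscape, plot_noise_sd = 0, seed = 4)
  # zero noise -> plot values equal the true raster values
  expect_equal(camp$plots$biomass_kg_dm_per_100m2,
               camp$plots$true_kg_dm_per_100m2, tolerance = 1e-12)
  counts <- table(camp$plots$community_id)
  expect_equal(counts[["dwarf_shrub_steppe"]], 50)
  expect_equal(counts[["riparian_grassland"]], 30)
  expect_equal(counts[["alpine_grassland"]], 30)
  expect_equal(counts[["salt_grass"]], 15)
  # configured productivity ratio recovered within 5%
  camp2 <- generate_field_campaign(b$landscape, seed = 6)
  r <- productivity_ratio(camp2$exclosures)$ratio
  expect_equal(r, b$landscape$truth$config$productivity_ratio,
               tolerance = 0.05)
  # fresh-dry pairs recover the configured dry fraction
  fd <- fit_fresh_dry_model(camp2$fresh_dry$fresh_kg, camp2$fresh_dry$dry_kg)
  expect_equal(fd$slope, 0.4, tolerance = 0.1)
  expect_gt(fd$r2, 0.8)
  # over-requesting plots in a class fails loudly
  expect_error(generate_field_campaign(b$landscape,
                                       n_per_class = c(salt_grass = 1e6)),
               "salt_grass")
})
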