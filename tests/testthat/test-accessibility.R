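mask_fixture <- function() {
  # 1 x 4 strip, two areas (left with winter camp), varying FSC / elevation
  grid <- rc_raster(matrix(0, 1, 4), res = 10)
  areas <- rc_areas(
    data.frame(area_id = c("wc", "nc"), has_winter_camp = c(TRUE, FALSE)),
    list(wc = cbind(c(0, 20, 20, 0), c(0, 0, 10, 10)),
         nc = cbind(c(20, 40, 40, 20), c(0, 0, 10, 10)))
  )
  list(grid = grid, areas = areas,
       area_raster = rasterize_areas(areas, grid),
       fsc = rc_set_values(grid, matrix(c(34, 35, 77, 90), 1)),
       dem = rc_set_values(grid, matrix(c(4499, 4500, 4600, 3000), 1)))
}

test_that("seasonal masks implement the snow, elevation and camp rules", {
  f <- mask_fixture()
  es <- accessible_mask("early_summer", "all", fsc = f$fsc,
                        area_raster = f$area_raster,
                        areas_table = f$areas$table)
  # strict 'below 35%': 34 in, 35 out
  expect_equal(as.vector(rc_values(es)), c(1, 0, 0, 0))
  hs_small <- accessible_mask("high_summer", "small_stock", dem = f$dem,
                              area_raster = f$area_raster,
                              areas_table = f$areas$table)
  # strict 'below 4500 m': 4499 in, 4500 and 4600 out
  expect_equal(as.vector(rc_values(hs_small)), c(1, 0, 0, 1))
  hs_large <- accessible_mask("high_summer", "large_stock",
                              area_raster = f$area_raster,
                              areas_table = f$areas$table)
  # winter-use areas excluded for large stock, no elevation cap
  expect_equal(as.vector(rc_values(hs_large)), c(0, 0, 1, 1))
  wi <- accessible_mask("winter", "all", fsc = f$fsc,
                        area_raster = f$area_raster,
                        areas_table = f$areas$table)
  # winter needs a camp AND mean FSC below 78%
  expect_equal(as.vector(rc_values(wi)), c(1, 1, 0, 0))
})

test_that("snowbound landscapes and threshold degeneracies behave", {
  f <- mask_fixture()
  all_snow <- rc_set_values(f$grid, matrix(100, 1, 4))
  for (season in c("early_summer", "winter")) {
    m <- accessible_mask(season, "all", fsc = all_snow,
                         area_raster = f$area_raster,
                         areas_table = f$areas$table)
    expect_equal(sum(rc_values(m), na.rm = TRUE), 0)
  }
  # no restrictions at all -> every in-area pixel accessible
  open_rules <- accessibility_rules(spring_fsc_max = 100, winter_fsc_max = 100,
                                    small_stock_summer_elev_max = Inf,
                                    winter_requires_winter_camp = FALSE,
                                    high_summer_excludes_winter_areas_for_large_stock = FALSE)
  for (args in list(list("early_summer", "all"),
                    list("high_summer", "small_stock"),
                    list("high_summer", "large_stock"),
                    list("winter", "all"))) {
    m <- accessible_mask(args[[1]], args[[2]], fsc = f$fsc, dem = f$dem,
                         area_raster = f$area_raster,
                         areas_table = f$areas$table, rules = open_rules)
    expect_equal(as.vector(rc_values(m)), rep(1, 4))
  }
})

test_that("masks are monotone in their thresholds", {
  b <- small_bundle()
  ar <- rasterize_areas(b$areas, b$landscape$dem)
  for (th in list(c(20, 35), c(35, 60), c(60, 95))) {
    lo <- accessible_mask("early_summer", "all", fsc = b$landscape$fsc_spring,
                          area_raster = ar, areas_table = b$areas$table,
                          rules = accessibility_rules(spring_fsc_max = th[1]))
    hi <- accessible_mask("early_summer", "all", fsc = b$landscape$fsc_spring,
                          area_raster = ar, areas_table = b$areas$table,
                          rules = accessibility_rules(spring_fsc_max = th[2]))
    expect_true(all(rc_values(hi) >= rc_values(lo), na.rm = TRUE))
  }
  for (el in list(c(4000, 4500), c(4500, 5500))) {
    lo <- accessible_mask("high_summer", "small_stock", dem = b$landscape$dem,
                          area_raster = ar, areas_table = b$areas$table,
                          rules = accessibility_rules(small_stock_summer_elev_max = el[1]))
    hi <- accessible_mask("high_summer", "small_stock", dem = b$landscape$dem,
                          area_raster = ar, areas_table = b$areas$table,
                          rules = accessibility_rules(small_stock_summer_elev_max = el[2]))
    expect_true(all(rc_values(hi) >= rc_values(lo), na.rm = TRUE))
  }
})

test_that("winter ignores the DEM and large-stock high summer ignores FSC", {
  f <- mask_fixture()
  wi1 <- accessible_mask("winter", "all", fsc = f$fsc, dem = f$dem,
                         area_raster = f$area_raster,
                         areas_table = f$areas$table)
  wi2 <- accessible_mask("winter", "all", fsc = f$fsc,
                         dem = rc_set_values(f$grid, matrix(9000, 1, 4)),
                         area_raster = f$area_raster,
                         areas_table = f$areas$table)
  expect_equal(rc_values(wi1), rc_values(wi2))
  hl1 <- accessible_mask("high_summer", "large_stock", fsc = f$fsc,
                         area_raster = f$area_raster,
                         areas_table = f$areas$table)
  hl2 <- accessible_mask("high_summer", "large_stock",
                         fsc = rc_set_values(f$grid, matrix(100, 1, 4)),
                         area_raster = f$area_raster,
                         areas_table = f$areas$table)
  expect_equal(rc_values(hl1), rc_values(hl2))
})

test_that("the mask union marks pixels accessible in any season", {
  g <- one_area_grid(matrix(0, 1, 3))
  m1 <- rc_set_values(g$grid, matrix(c(1, 0, 0), 1))
  m2 <- rc_set_values(g$grid, matrix(c(0, 1, 0), 1))
  u <- mask_union(list(m1, m2))
  expect_equal(as.vector(rc_values(u)), c(1, 1, 0))
})
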