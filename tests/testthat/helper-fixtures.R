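# Shared fixtures, built once per test run.

# A small synthetic study system (80 x 80 pixels at 10 m, 4 grazing areas).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_bundle(landscape_config(nx = 80, ny = 80),
                                seed = 42, target_utilization = 0.4)
    }
    cache
  }
})

# Full-size system (200 x 200 pixels): herds are large enough that
# integer-rounding effects on utilization are well below one point.
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_bundle(landscape_config(), seed = 101,
                                target_utilization = 0.4)
    }
    cache
  }
})

# Census table with one row per species/age/season/area, calendar seasons.
tiny_census <- function(species = "sheep", age_class = "adult",
                        season = "high_summer", area_id = "A", count = 10,
                        year = 2020) {
  data.frame(year = year, season = season, area_id = area_id,
             species = species, age_class = age_class, count = count,
             stringsAsFactors = FALSE)
}

# All-age census records per (year, season) from the bundled survey table.
bigpamir_records <- function(year, season) {
  cen <- bigpamir_census()
  x <- cen[cen$year == year & cen$season == season, , drop = FALSE]
  x$age_class <- "all"
  x
}

# Drop a duplicated closing vertex for ring comparison.
close_ring_pts <- function(p) {
  if (isTRUE(all.equal(p[1, ], p[nrow(p), ]))) p[-nrow(p), , drop = FALSE] else p
}

# 3 x 3 single-area geometry for mask tests: area raster with one id.
one_area_grid <- function(values = matrix(0, 3, 3), res = 10) {
  grid <- rc_raster(values, res = res)
  W <- ncol(values) * res; H <- nrow(values) * res
  areas <- rc_areas(
    data.frame(area_id = "A", has_winter_camp = TRUE,
               stringsAsFactors = FALSE),
    list(A = cbind(c(0, W, W, 0), c(0, 0, H, H)))
  )
  list(grid = grid, areas = areas,
       area_raster = rasterize_areas(areas, grid))
}
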