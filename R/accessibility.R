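#' Seasonal accessibility rules
#'
#' Thresholds governing which pixels livestock can reach in each season of
#' the transhumance year: in early summer (May-June) grazing occurs where
#' mean fractional snow cover (FSC) is below 35%; in high summer small stock
#' (sheep, goats) stays below 4500 m a.s.l. while large stock (yak, cattle)
#' has no elevation cap but avoids the winter-use areas; in winter
#' (October-April) grazing is limited to areas with winter camps and mean
#' winter FSC below 78%. All comparisons are strict ("below"), so boundary
#' pixels exactly at a threshold are excluded; every threshold is
#' configurable.
#'
#' @param spring_fsc_max early-summer FSC threshold, percent (default 35).
#' @param winter_fsc_max winter FSC threshold, percent (default 78).
#' @param small_stock_summer_elev_max high-summer elevation cap for small
#'   stock, m a.s.l. (default 4500).
#' @param winter_requires_winter_camp restrict winter grazing to areas with
#'   winter camps (default TRUE).
#' @param high_summer_excludes_winter_areas_for_large_stock exclude
#'   winter-camp areas from large-stock high-summer grazing (default TRUE).
#' @return list of class `accessibility_rules`.
#' @export
accessibility_rules <- function(spring_fsc_max = 35, winter_fsc_max = 78,
                                small_stock_summer_elev_max = 4500,
                                winter_requires_winter_camp = TRUE,
                                high_summer_excludes_winter_areas_for_large_stock = TRUE) {
  stopifnot(spring_fsc_max >= 0, spring_fsc_max <= 100,
            winter_fsc_max >= 0, winter_fsc_max <= 100)
  structure(list(
    spring_fsc_max = spring_fsc_max,
    winter_fsc_max = winter_fsc_max,
    small_stock_summer_elev_max = small_stock_summer_elev_max,
    winter_requires_winter_camp = winter_requires_winter_camp,
    high_summer_excludes_winter_areas_for_large_stock =
      high_summer_excludes_winter_areas_for_large_stock
  ), class = "accessibility_rules")
}

#' Seasonal accessibility mask
#'
#' Boolean raster of pixels a species group can graze in a season, applying
#' the [accessibility_rules()] to fractional snow cover, elevation and
#' grazing-area attributes. Pixels outside every grazing area are `NA`.
#' The winter mask depends only on FSC and winter-camp attributes (never on
#' the DEM); the high-summer large-stock mask depends only on area
#' attributes (never on FSC).
#'
#' @param season `"early_summer"`, `"high_summer"` or `"winter"`.
#' @param species_group `"small_stock"`, `"large_stock"` or `"all"` (for
#'   early summer and winter, where the rule does not distinguish groups).
#' @param fsc `rc_raster` of seasonal mean FSC in percent (spring composite
#'   for early summer, winter mean for winter; unused in high summer).
#' @param dem `rc_raster` of elevation (m a.s.l.; used for high-summer
#'   small stock only).
#' @param area_raster area-index raster from [rasterize_areas()].
#' @param areas_table data.frame with `area_id`, `has_winter_camp`.
#' @param rules an [accessibility_rules()].
#' @return `rc_raster` with values 1 (accessible), 0 (not), `NA` (outside
#'   all grazing areas).
#' @export
accessible_mask <- function(season, species_group = "all", fsc = NULL,
                            dem = NULL, area_raster, areas_table,
                            rules = accessibility_rules()) {
  stopifnot(inherits(area_raster, "rc_raster"))
  season <- match.arg(season, c("early_summer", "high_summer", "winter"))
  species_group <- match.arg(species_group,
                             c("all", "small_stock", "large_stock"))
  ids <- attr(area_raster, "area_id")
  idx <- area_raster$values
  in_area <- is.finite(idx)
  camp_by_idx <- areas_table$has_winter_camp[match(ids, areas_table$area_id)]
  if (anyNA(camp_by_idx)) {
    stop("area raster indices not all present in areas table", call. = FALSE)
  }
  pixel_has_camp <- matrix(FALSE, nrow(idx), ncol(idx))
  pixel_has_camp[in_area] <- camp_by_idx[idx[in_area]]

  ok <- matrix(FALSE, nrow(idx), ncol(idx))
  if (season == "early_summer") {
    if (is.null(fsc)) stop("early-summer mask requires an FSC raster", call. = FALSE)
    stop_if_grid_mismatch(area_raster, fsc, what = "area/FSC rasters")
    ok <- fsc$values < rules$spring_fsc_max
  } else if (season == "high_summer") {
    if (species_group == "small_stock") {
      if (is.null(dem)) stop("high-summer small-stock mask requires a DEM", call. = FALSE)
      stop_if_grid_mismatch(area_raster, dem, what = "area/DEM rasters")
      ok <- dem$values < rules$small_stock_summer_elev_max
    } else if (species_group == "large_stock") {
      ok[] <- TRUE
      if (rules$high_summer_excludes_winter_areas_for_large_stock) {
        ok <- ok & !pixel_has_camp
      }
    } else {
      stop("high-summer accessibility differs by species group; ",
           "request 'small_stock' or 'large_stock'", call. = FALSE)
    }
  } else { # winter
    if (is.null(fsc)) stop("winter mask requires a winter-mean FSC raster", call. = FALSE)
    stop_if_grid_mismatch(area_raster, fsc, what = "area/FSC rasters")
    ok <- fsc$values < rules$winter_fsc_max
    if (rules$winter_requires_winter_camp) ok <- ok & pixel_has_camp
  }
  ok[is.na(ok)] <- FALSE
  out <- matrix(NA_real_, nrow(idx), ncol(idx))
  out[in_area] <- as.double(ok[in_area])
  rc_set_values(area_raster, out)
}

#' Union of seasonal masks
#'
#' Pixels accessible in at least one of the supplied masks (the annual
#' supply basis: a pixel's annual production is counted once however many
#' seasons it can be reached in).
#'
#' @param masks list of mask rasters from [accessible_mask()].
#' @return `rc_raster` mask (1/0/`NA`).
#' @export
mask_union <- function(masks) {
  stopifnot(length(masks) >= 1)
  template <- masks[[1]]
  acc <- Reduce(`|`, lapply(masks, function(m) m$values %in% 1))
  out <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  in_any <- Reduce(`|`, lapply(masks, function(m) is.finite(m$values)))
  out[in_any] <- as.double(acc[in_any])
  rc_set_values(template, out)
}
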