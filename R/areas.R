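#' Grazing-area polygon sets
#'
#' Grazing areas are the informal seasonal management units livestock is
#' attributed to. An `rc_areas` object holds one simple (unholed) polygon per
#' area together with its attributes: `area_id`, `has_winter_camp` and an
#' optional camp point. Areas must be pairwise non-overlapping; they are the
#' zonal units for all supply/demand accounting.
#'
#' @param table data.frame with columns `area_id` (character, unique) and
#'   `has_winter_camp` (logical); optional `camp_x`, `camp_y`.
#' @param polygons named list (names = `area_id`) of n x 2 coordinate
#'   matrices (closed or open rings, map units).
#' @param crs CRS label shared with the rasters.
#' @return object of class `rc_areas`.
#' @export
rc_areas <- function(table, polygons, crs = "local-metric") {
  stopifnot(is.data.frame(table),
            all(c("area_id", "has_winter_camp") %in% names(table)),
            !anyDuplicated(table$area_id),
            setequal(names(polygons), table$area_id))
  for (p in polygons) {
    stopifnot(is.matrix(p), ncol(p) == 2, nrow(p) >= 3)
  }
  table$area_id <- as.character(table$area_id)
  structure(list(table = table, polygons = polygons[table$area_id], crs = crs),
            class = "rc_areas")
}

#' @export
print.rc_areas <- function(x, ...) {
  cat(sprintf("rc_areas: %d grazing areas (%d with winter camp), crs '%s'\n",
              nrow(x$table), sum(x$table$has_winter_camp), x$crs))
  invisible(x)
}

close_ring <- function(p) {
  if (!isTRUE(all.equal(p[1, ], p[nrow(p), ]))) p <- rbind(p, p[1, ])
  p
}

#' Rasterize grazing areas by pixel centre
#'
#' Every pixel is assigned to the single polygon containing its centre
#' (even-odd rule via [mgcv::in.out()]). Overlapping polygons are an error:
#' grazing areas are exclusive management units and must partition the
#' landscape they cover.
#'
#' @param areas an [rc_areas] object.
#' @param grid an `rc_raster` defining the target grid.
#' @return `rc_raster` of integer area indices (1-based, ordered as
#'   `areas$table$area_id`), `NA` outside all areas, with attribute
#'   `area_id` carrying the index-to-id mapping.
#' @export
rasterize_areas <- function(areas, grid) {
  stopifnot(inherits(areas, "rc_areas"), inherits(grid, "rc_raster"))
  if (!identical(areas$crs, grid$crs)) {
    stop("CRS mismatch between areas and grid", call. = FALSE)
  }
  cc <- rc_coords(grid)
  pts <- cbind(as.vector(cc$x), as.vector(cc$y))
  idx <- rep(NA_integer_, nrow(pts))
  for (i in seq_along(areas$polygons)) {
    inside <- mgcv::in.out(close_ring(areas$polygons[[i]]), pts)
    clash <- inside & !is.na(idx)
    if (any(clash)) {
      stop(sprintf("grazing areas overlap: '%s' and '%s' both contain pixel centres",
                   areas$table$area_id[idx[which(clash)[1]]],
                   areas$table$area_id[i]), call. = FALSE)
    }
    idx[inside] <- i
  }
  out <- rc_set_values(grid, matrix(as.double(idx), nrow(grid$values), ncol(grid$values)))
  attr(out, "area_id") <- areas$table$area_id
  out
}

#' Accessible hectares per grazing area
#'
#' Zonal summary of a boolean accessibility mask: counts accessible pixels
#' per area and converts to hectares using the pixel size.
#'
#' @param mask `rc_raster` with values 1/0/`NA` (accessible / not / outside).
#' @param area_raster integer area-index raster from [rasterize_areas()].
#' @return data.frame `area_id`, `hectares`.
#' @export
seasonal_accessible_area <- function(mask, area_raster) {
  stop_if_grid_mismatch(mask, area_raster, what = "mask/area rasters")
  ids <- attr(area_raster, "area_id")
  idx <- area_raster$values
  acc <- mask$values %in% 1
  counts <- vapply(seq_along(ids), function(i) sum(acc & idx %in% i), 0L)
  data.frame(area_id = ids, hectares = counts * rc_pixel_ha(mask),
             stringsAsFactors = FALSE)
}

#' Read and write grazing areas as GeoJSON
#'
#' Each area is a GeoJSON `Feature` with a `Polygon` geometry and properties
#' `area_id`, `has_winter_camp` and (if present) the camp point coordinates.
#' The CRS label is stored in a top-level `crs_label` member.
#'
#' @param areas an [rc_areas] object.
#' @param path output file path (`.geojson`).
#' @export
write_areas <- function(areas, path) {
  feats <- lapply(seq_len(nrow(areas$table)), function(i) {
    p <- close_ring(areas$polygons[[i]])
    props <- list(area_id = areas$table$area_id[i],
                  has_winter_camp = areas$table$has_winter_camp[i])
    if (all(c("camp_x", "camp_y") %in% names(areas$table))) {
      props$camp_x <- areas$table$camp_x[i]
      props$camp_y <- areas$table$camp_y[i]
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(p)),
                                                   function(j) as.numeric(p[j, ])))))
  })
  obj <- list(type = "FeatureCollection", crs_label = areas$crs, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_areas
#' @export
read_areas <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- obj$features
  ids <- vapply(feats, function(f) f$properties$area_id, "")
  camps <- vapply(feats, function(f) isTRUE(f$properties$has_winter_camp), TRUE)
  polygons <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
  })
  names(polygons) <- ids
  tab <- data.frame(area_id = ids, has_winter_camp = camps,
                    stringsAsFactors = FALSE)
  if (!is.null(feats[[1]]$properties$camp_x)) {
    tab$camp_x <- vapply(feats, function(f) as.numeric(f$properties$camp_x), 0)
    tab$camp_y <- vapply(feats, function(f) as.numeric(f$properties$camp_y), 0)
  }
  crs <- if (!is.null(obj$crs_label)) obj$crs_label else "local-metric"
  rc_areas(tab, polygons, crs = crs)
}
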