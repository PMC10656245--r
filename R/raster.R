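#' Lightweight georeferenced raster grid
#'
#' `rc_raster` is the package's in-memory raster container: a numeric matrix
#' with a square-pixel georeference (origin, cell size, CRS label). Row 1 of
#' the matrix is the northernmost row, matching the on-disk row order of the
#' ESRI ASCII grid format used by [read_raster()]/[write_raster()]. Missing
#' cells are `NA`.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xmin,ymin coordinates of the lower-left corner of the grid (map
#'   units, metres for all synthetic data in this package).
#' @param res pixel size in map units (square pixels).
#' @param crs free-text CRS label; all layers of one analysis must share it.
#' @return an object of class `rc_raster`.
#' @export
rc_raster <- function(values, xmin = 0, ymin = 0, res = 10, crs = "local-metric") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.finite(res), res > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res, crs = crs),
    class = "rc_raster"
  )
}

#' @export
print.rc_raster <- function(x, ...) {
  cat(sprintf(
    "rc_raster: %d rows x %d cols, res %g, origin (%g, %g), crs '%s'\n",
    nrow(x$values), ncol(x$values), x$res, x$xmin, x$ymin, x$crs
  ))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: min %g, mean %g, max %g (%d NA)\n",
                min(v), mean(v), max(v), sum(!is.finite(x$values))))
  }
  invisible(x)
}

#' @rdname rc_raster
#' @param x an `rc_raster`.
#' @export
rc_values <- function(x) x$values

#' Replace the cell values of a raster, keeping its georeference
#'
#' @param x an `rc_raster`.
#' @param values matrix of identical dimensions.
#' @return an `rc_raster` on the same grid.
#' @export
rc_set_values <- function(x, values) {
  values <- as.matrix(values)
  stopifnot(all(dim(values) == dim(x$values)))
  x$values <- values
  storage.mode(x$values) <- "double"
  x
}

#' Cell-centre coordinates of a raster
#'
#' @param x an `rc_raster`.
#' @return list with matrices `x` and `y` of cell-centre coordinates.
#' @export
rc_coords <- function(x) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  xs <- x$xmin + (seq_len(nc) - 0.5) * x$res
  ys <- x$ymin + (nr - seq_len(nr) + 0.5) * x$res   # row 1 = north
  list(x = matrix(rep(xs, each = nr), nr, nc),
       y = matrix(rep(ys, times = nc), nr, nc))
}

#' Pixel area in hectares
#' @param x an `rc_raster`.
#' @export
rc_pixel_ha <- function(x) x$res^2 / 1e4

#' Test that two rasters share the same grid
#' @param a,b `rc_raster` objects.
#' @export
rc_same_grid <- function(a, b) {
  all(dim(a$values) == dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$res), c(b$xmin, b$ymin, b$res))) &&
    identical(a$crs, b$crs)
}

stop_if_grid_mismatch <- function(..., what = "rasters") {
  rs <- list(...)
  for (i in seq_along(rs)[-1]) {
    if (!rc_same_grid(rs[[1]], rs[[i]])) {
      stop(sprintf("%s are not co-registered (grid %d differs from grid 1)",
                   what, i), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster persistence. The `.asc` format stores the grid header
#' (ncols, nrows, lower-left corner, cell size, nodata value) followed by
#' rows from north to south; a sidecar `.prj`-like text file (`<path>.crs`)
#' carries the CRS label. Round-trip is value-exact at the printed precision
#' (`digits = 15`).
#'
#' @param path file path (conventionally ending in `.asc`).
#' @param nodata numeric value written for `NA` cells.
#' @return `read_raster()` returns an `rc_raster`; `write_raster()` returns
#'   `path` invisibly.
#' @export
write_raster <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "rc_raster"))
  v <- x$values
  v[!is.finite(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x$xmin),
    sprintf("yllcorner %.10g", x$ymin),
    sprintf("cellsize %.10g", x$res),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(v, 1, function(r) paste(formatC(r, digits = 15, format = "g"),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(x$crs, paste0(path, ".crs"))
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  ln <- readLines(path)
  hdr <- ln[1:6]
  val <- function(key) {
    m <- grep(paste0("^", key, "\\b"), hdr, ignore.case = TRUE, value = TRUE)
    if (!length(m)) stop("malformed ASCII grid header: missing ", key, call. = FALSE)
    as.numeric(strsplit(trimws(m[1]), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  nodata <- val("NODATA_value")
  body <- scan(text = paste(ln[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(body) == nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  crs_path <- paste0(path, ".crs")
  crs <- if (file.exists(crs_path)) readLines(crs_path)[1] else "local-metric"
  rc_raster(m, xmin = val("xllcorner"), ymin = val("yllcorner"),
            res = val("cellsize"), crs = crs)
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Assigns to every target cell the value of the source cell covering its
#' centre; values are preserved exactly (no interpolation), which is the
#' behaviour needed when transferring coarse fractional-snow-cover fields
#' (e.g. 500 m satellite composites) onto the 10 m analysis grid.
#'
#' @param src source `rc_raster` (any resolution).
#' @param target `rc_raster` defining the output grid (values ignored).
#' @return `rc_raster` on the target grid.
#' @export
resample_nearest <- function(src, target) {
  if (!identical(src$crs, target$crs)) {
    stop("CRS mismatch between source and target grids", call. = FALSE)
  }
  cc <- rc_coords(target)
  nr <- nrow(src$values); nc <- ncol(src$values)
  col <- floor((cc$x - src$xmin) / src$res) + 1L
  row <- nr - floor((cc$y - src$ymin) / src$res)
  inside <- col >= 1L & col <= nc & row >= 1L & row <= nr
  if (!any(inside)) stop("source and target extents are disjoint", call. = FALSE)
  out <- matrix(NA_real_, nrow(target$values), ncol(target$values))
  out[inside] <- src$values[cbind(row[inside], col[inside])]
  rc_set_values(target, out)
}
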