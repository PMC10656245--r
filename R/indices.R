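#' Bare-soil line parameters
#'
#' Slope and intercept of the soil line in red/NIR reflectance space, used
#' by the soil-adjusted indices (WDVI, SACRI, MSACRI). There are no
#' defaults: the soil line is scene-specific and must be supplied.
#'
#' @param alpha slope (> 0).
#' @param beta intercept (reflectance units).
#' @export
soil_line <- function(alpha, beta) {
  stopifnot(is.finite(alpha), alpha > 0, is.finite(beta))
  structure(list(alpha = alpha, beta = beta), class = "soil_line")
}

index_band_requirements <- list(
  WDVI = c("B8", "B4"),
  WDVI_SA = c("B8", "B4", "B3"),
  RatioB8aB3 = c("B8a", "B3"),
  NDRE1 = c("B8", "B7"),
  NDRE2 = c("B8", "B8a"),
  MTCI = c("B6", "B5", "B4"),
  SACRI = c("B8", "B11"),
  MSACRI = c("B11", "B12")
)

safe_div <- function(num, den) {
  out <- num / den
  out[!is.finite(out)] <- NA_real_  # division by zero -> nodata
  out
}

#' Vegetation indices for dryland biomass modelling
#'
#' Computes the eight indices used as predictors of standing biomass from
#' co-registered surface-reflectance bands: the soil-adjusted weighted
#' difference vegetation index (WDVI) and its green/red-corrected variant,
#' a green/near-infrared band ratio, two red-edge normalized differences
#' (NDRE), the MERIS terrestrial chlorophyll index (MTCI), and two
#' soil-adjusted corner indices in the short-wave infrared (SACRI, MSACRI).
#' Pixels with a zero denominator become `NA`.
#'
#' @param bands named list of reflectance matrices or `rc_raster`s; names
#'   from `B3, B4, B5, B6, B7, B8, B8a, B11, B12` (all grids identical).
#' @param soil a [soil_line()] (required for WDVI/WDVI_SA/SACRI/MSACRI).
#' @param which indices to compute (default: all eight).
#' @return named list of matrices (or `rc_raster`s, matching the input type).
#' @export
compute_vegetation_indices <- function(bands, soil = NULL,
                                       which = names(index_band_requirements)) {
  as_mat <- function(b) if (inherits(b, "rc_raster")) rc_values(b) else as.matrix(b)
  is_rast <- inherits(bands[[1]], "rc_raster")
  template <- if (is_rast) bands[[1]] else NULL
  B <- lapply(bands, as_mat)
  which <- match.arg(which, names(index_band_requirements), several.ok = TRUE)
  needs_soil <- c("WDVI", "WDVI_SA", "SACRI", "MSACRI")
  if (any(which %in% needs_soil) && is.null(soil)) {
    stop("soil line required for ", paste(intersect(which, needs_soil),
                                          collapse = ", "), call. = FALSE)
  }
  for (ix in which) {
    miss <- setdiff(index_band_requirements[[ix]], names(B))
    if (length(miss)) {
      stop(sprintf("index %s requires missing band(s): %s", ix,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  a <- soil$alpha; b <- soil$beta
  calc <- list(
    WDVI = function() B$B8 - a * B$B4,
    WDVI_SA = function() (B$B8 - a * B$B4) -
      0.45 * safe_div(B$B4 - B$B3, B$B4 + B$B3),
    RatioB8aB3 = function() safe_div(B$B8a, B$B3),
    NDRE1 = function() safe_div(B$B8 - B$B7, B$B8 + B$B7),
    NDRE2 = function() safe_div(B$B8 - B$B8a, B$B8 + B$B8a),
    MTCI = function() safe_div(B$B6 - B$B5, B$B5 + B$B4),
    SACRI = function() safe_div(a * (B$B8 - B$B11 - b),
                                a * B$B8 + B$B11 - a * b),
    MSACRI = function() 5 * safe_div(a * (B$B11 - a * B$B12 - b),
                                     a * B$B11 + B$B12 + a * b)
  )
  out <- lapply(which, function(ix) calc[[ix]]())
  names(out) <- which
  if (is_rast) out <- lapply(out, function(m) rc_set_values(template, m))
  out
}
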