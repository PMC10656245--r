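#' Build the metabolizable-energy-content (MEC) map
#'
#' Converts a standing-biomass raster into the annual forage energy
#' available to herbivores per hectare. Per vegetated pixel:
#'
#'   MEC = max(standing - adjustment, 0) * productivity_ratio(class)
#'         * consumable_fraction(class) * forage_quality(class)
#'
#' in MJ/ha/year, with standing biomass in kg DM/ha. Non-vegetated classes
#' (water, snow and ice, rock and scree) contribute 0; classes missing from
#' the parameter table are an error. The `adjustment` implements the
#' conservative-biomass scenario (biomass lowered by half of the model's
#' mean absolute error) and is subtracted from standing biomass before the
#' productivity ratio is applied.
#'
#' @param standing `rc_raster` of standing biomass (kg DM/ha). Supply annual
#'   production directly by leaving `productivity_ratio = 1` in `params`.
#' @param classes `rc_raster` of integer class codes.
#' @param params community parameter table ([default_community_params()]).
#' @param class_table code-to-community mapping ([default_class_table()]).
#' @param adjustment kg DM/ha subtracted from standing biomass (>= 0).
#' @param non_vegetated community ids treated as non-vegetated (MEC 0).
#' @return `rc_raster` of MEC in MJ/ha/year; `NA` where either input is `NA`.
#' @export
build_mec_map <- function(standing, classes, params = default_community_params(),
                          class_table = default_class_table(),
                          adjustment = 0,
                          non_vegetated = c("non_vegetated", "water",
                                            "snow_ice", "rock_scree")) {
  stopifnot(inherits(standing, "rc_raster"), inherits(classes, "rc_raster"),
            adjustment >= 0)
  stop_if_grid_mismatch(standing, classes, what = "biomass/class rasters")
  code <- classes$values
  present <- sort(unique(code[is.finite(code)]))
  community <- class_table$community_id[match(present, class_table$code)]
  if (anyNA(community)) {
    stop("class code(s) missing from class table: ",
         paste(present[is.na(community)], collapse = ", "), call. = FALSE)
  }
  veg <- setdiff(community, non_vegetated)
  missing_params <- setdiff(veg, params$community_id)
  if (length(missing_params)) {
    stop("vegetated class(es) without community parameters: ",
         paste(missing_params, collapse = ", "), call. = FALSE)
  }
  biomass <- pmax(standing$values - adjustment, 0)
  mec <- matrix(NA_real_, nrow(code), ncol(code))
  for (i in seq_along(present)) {
    sel <- code == present[i] & is.finite(code) & is.finite(standing$values)
    if (community[i] %in% non_vegetated) {
      mec[sel] <- 0
    } else {
      p <- params[params$community_id == community[i], ]
      mec[sel] <- biomass[sel] * p$productivity_ratio *
        p$consumable_fraction * p$forage_quality
    }
  }
  rc_set_values(standing, mec)
}

#' Mean MEC per community from productivity tables
#'
#' Non-spatial form of the MEC computation for community-level summaries:
#' mean annual production per community (kg DM/ha/year) times consumable
#' fraction times forage quality. Used to reproduce community-mean energy
#' availability from tabulated productivity values.
#'
#' @param productivity data.frame with `community_id` and one or more
#'   year columns of annual production (kg DM/ha).
#' @param params community parameter table.
#' @return data.frame `community_id`, `mean_production`, `mec_mj_ha`.
#' @export
community_mec_means <- function(productivity,
                                params = default_community_params()) {
  yr_cols <- setdiff(names(productivity), "community_id")
  prod_mean <- rowMeans(productivity[, yr_cols, drop = FALSE])
  i <- match(productivity$community_id, params$community_id)
  if (anyNA(i)) {
    stop("communities without parameters: ",
         paste(productivity$community_id[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    community_id = productivity$community_id,
    mean_production = prod_mean,
    mec_mj_ha = prod_mean * params$consumable_fraction[i] *
      params$forage_quality[i],
    stringsAsFactors = FALSE
  )
}
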