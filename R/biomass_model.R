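#' Linear fresh-to-dry biomass conversion
#'
#' Ordinary least squares of dry mass on fresh mass, used to convert
#' fresh-weighed clip plots to kg dry matter where on-site air drying was
#' not possible.
#'
#' @param fresh,dry paired masses (same units), n >= 3.
#' @return list of class `fresh_dry_model`: `slope`, `intercept`, `r2`, `n`,
#'   and `convert(fresh)`.
#' @export
fit_fresh_dry_model <- function(fresh, dry) {
  stopifnot(length(fresh) == length(dry))
  ok <- is.finite(fresh) & is.finite(dry)
  fresh <- fresh[ok]; dry <- dry[ok]
  if (length(fresh) < 3) stop("need at least 3 fresh/dry pairs", call. = FALSE)
  if (stats::sd(fresh) == 0) stop("degenerate design: all fresh values equal",
                                  call. = FALSE)
  fit <- stats::lm(dry ~ fresh)
  cf <- stats::coef(fit)
  structure(list(
    slope = unname(cf[2]), intercept = unname(cf[1]),
    r2 = summary(fit)$r.squared, n = length(fresh),
    convert = function(x) unname(cf[1] + cf[2] * x)
  ), class = "fresh_dry_model")
}

#' Error metrics of a biomass regression
#'
#' Root mean squared error, mean absolute error and mean bias of predictions
#' against observations, their relative forms (percent of the observation
#' mean), and R^2 = 1 - SSE/SST. Relative metrics are `NA` (with a warning)
#' when the observation mean is 0.
#'
#' @param obs,pred equal-length numeric vectors, n >= 2.
#' @return one-row data.frame: `r2`, `rmse`, `rmse_rel`, `mae`, `mae_rel`,
#'   `bias`, `bias_rel`, `obs_mean`, `obs_sd`, `n`.
#' @export
regression_metrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2)
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  err <- pred - obs
  m <- mean(obs)
  rel <- function(x) {
    if (m == 0) NA_real_ else 100 * x / m
  }
  if (m == 0) warning("observation mean is 0; relative metrics undefined",
                      call. = FALSE)
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  bias <- mean(err)
  sst <- sum((obs - m)^2)
  r2 <- if (sst > 0) 1 - sum(err^2) / sst else NA_real_
  data.frame(r2 = r2, rmse = rmse, rmse_rel = rel(rmse),
             mae = mae, mae_rel = rel(mae),
             bias = bias, bias_rel = rel(bias),
             obs_mean = m, obs_sd = stats::sd(obs), n = length(obs))
}

#' Random-forest standing-biomass model
#'
#' Fits an ensemble-of-trees regression (500 trees, other parameters at
#' their defaults) predicting standing biomass from the eight vegetation
#' indices at the field-plot locations. Predictions are clamped at 0 (no
#' negative biomass).
#'
#' @param features data.frame/matrix of index values at the plots (finite).
#' @param biomass observed standing biomass (kg DM/100 m^2).
#' @param n_trees ensemble size (default 500).
#' @param seed RNG seed for the tree fitting.
#' @return object of class `biomass_model` with `fit` and `predict(newdata)`.
#' @export
fit_biomass_model <- function(features, biomass, n_trees = 500, seed = 1) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(biomass))
  bad <- !stats::complete.cases(features) | !is.finite(biomass)
  if (any(bad)) {
    stop("non-finite feature/biomass values at plot row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (nrow(features) < 20) stop("need at least 20 plots", call. = FALSE)
  set.seed(seed)
  fit <- randomForest::randomForest(x = features, y = biomass,
                                    ntree = n_trees)
  structure(list(
    fit = fit, feature_names = names(features),
    predict = function(newdata) {
      newdata <- as.data.frame(newdata)[, names(features), drop = FALSE]
      pmax(stats::predict(fit, newdata), 0)
    }
  ), class = "biomass_model")
}

#' Predict a standing-biomass raster from index rasters
#'
#' @param model a [fit_biomass_model()] object.
#' @param indices named list of index `rc_raster`s (or matrices on one grid).
#' @return `rc_raster` of predicted biomass (same units as training data);
#'   pixels with any `NA` index become `NA`.
#' @export
predict_biomass_raster <- function(model, indices) {
  template <- indices[[1]]
  stopifnot(inherits(template, "rc_raster"))
  mats <- lapply(indices, rc_values)
  X <- as.data.frame(lapply(mats, as.vector))
  ok <- stats::complete.cases(X)
  pred <- rep(NA_real_, nrow(X))
  if (any(ok)) pred[ok] <- model$predict(X[ok, , drop = FALSE])
  rc_set_values(template, matrix(pred, nrow(template$values),
                                 ncol(template$values)))
}

#' Repeated spatial cross-validation of the biomass model
#'
#' Estimates out-of-sample error by k-fold cross-validation with spatially
#' blocked folds: each repeat clusters the plot coordinates into k groups by
#' k-means and holds out one cluster at a time, so validation plots are
#' spatially separated from training plots. Held-out predictions are pooled
#' into one metric set per repeat; metrics are averaged over repeats.
#' Repeat r uses seed `seed + r`, making results invariant to plot ordering.
#'
#' @param features per-plot index values.
#' @param biomass observed biomass.
#' @param coords n x 2 matrix of projected plot coordinates.
#' @param k folds per repeat (default 10).
#' @param repeats number of repeats (default 100).
#' @param seed base RNG seed.
#' @param n_trees forest size per fold model.
#' @return averaged [regression_metrics()] row with an extra `repeats`
#'   column; attribute `"per_repeat"` holds the repeat-level metrics.
#' @export
spatial_cross_validate <- function(features, biomass, coords, k = 10,
                                   repeats = 100, seed = 1, n_trees = 500) {
  features <- as.data.frame(features)
  coords <- as.matrix(coords)
  n <- nrow(features)
  stopifnot(length(biomass) == n, nrow(coords) == n)
  if (k > n) stop("k exceeds the number of plots", call. = FALSE)
  # canonical plot order: results do not depend on input row permutation
  ord <- order(coords[, 1], coords[, 2], biomass)
  features <- features[ord, , drop = FALSE]
  biomass <- biomass[ord]
  coords <- coords[ord, , drop = FALSE]
  per_rep <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    km <- stats::kmeans(coords, centers = k, nstart = 3, iter.max = 50)
    fold <- km$cluster
    pred <- rep(NA_real_, n)
    for (f in sort(unique(fold))) {
      hold <- fold == f
      set.seed(seed + r)
      fit <- randomForest::randomForest(x = features[!hold, , drop = FALSE],
                                        y = biomass[!hold], ntree = n_trees)
      pred[hold] <- pmax(stats::predict(fit, features[hold, , drop = FALSE]), 0)
    }
    per_rep[[r]] <- regression_metrics(biomass, pred)
  }
  per_rep <- do.call(rbind, per_rep)
  out <- as.data.frame(lapply(per_rep, mean))
  out$n <- n
  out$repeats <- repeats
  attr(out, "per_repeat") <- per_rep
  out
}

#' Exclosure-derived productivity ratio
#'
#' Ratio of annual aboveground production (end-of-season clip inside an
#' exclosure) to standing biomass in the identically sized grazed area
#' outside, averaged over exclosure pairs. The ratio converts a
#' standing-biomass map into annual production. Pooling is global by
#' default; per-community ratios are available where enough pairs survive.
#'
#' @param pairs data.frame with `community_id`, `inside_total_kg`,
#'   `outside_standing_kg`.
#' @param pooling `"global"` (one ratio) or `"community"`.
#' @return data.frame `community_id` (or `"all"`), `ratio`, `n_pairs`.
#' @export
productivity_ratio <- function(pairs, pooling = c("global", "community")) {
  pooling <- match.arg(pooling)
  stopifnot(all(c("inside_total_kg", "outside_standing_kg") %in% names(pairs)))
  drop <- !is.finite(pairs$outside_standing_kg) | pairs$outside_standing_kg <= 0
  if (any(drop)) {
    warning(sum(drop), " pair(s) dropped: outside standing biomass is 0",
            call. = FALSE)
    pairs <- pairs[!drop, , drop = FALSE]
  }
  if (!nrow(pairs)) stop("no valid exclosure pairs", call. = FALSE)
  ratio <- pairs$inside_total_kg / pairs$outside_standing_kg
  if (pooling == "global") {
    out <- data.frame(community_id = "all", ratio = mean(ratio),
                      n_pairs = length(ratio), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(ratio, by = list(community_id = pairs$community_id),
                            FUN = mean)
    n <- stats::aggregate(ratio, by = list(community_id = pairs$community_id),
                          FUN = length)
    out <- data.frame(community_id = agg$community_id, ratio = agg$x,
                      n_pairs = n$x, stringsAsFactors = FALSE)
  }
  if (any(out$n_pairs == 1)) {
    out$low_confidence <- out$n_pairs == 1
  }
  out
}
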