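# SOM regressors and their evaluation: accuracy metrics, derived reporting
# statistics, seeded k-fold cross-validation, the random-forest model with
# its hyperparameter grid, impurity-based variable importance with category
# aggregation, and per-pixel prediction/uncertainty maps.

#' Regression accuracy metrics
#'
#' MAE = mean |P - Q|, RMSE = sqrt(mean (P - Q)^2) and R^2 = 1 -
#' SS_res/SS_tot with SS_tot taken about the observed mean. R^2 can be
#' negative and is not clamped; it is `NA` when the observed values have
#' zero variance.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2 (g/kg).
#' @return Named vector `c(mae, rmse, r2)`.
#' @examples
#' som_metrics(c(0, 0, 4), c(1, 1, 1))  # MAE 1.667, RMSE 1.915, R2 -0.031
#' @export
som_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  err <- predicted - observed
  ss_tot <- sum((observed - mean(observed))^2)
  c(mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    r2 = if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot)
}

#' Relative change between two values, in percent
#'
#' `100 * (b - a) / a`: the relative enhancement when a metric moves from
#' `a` to `b`.
#'
#' @param a Base value (nonzero).
#' @param b New value.
#' @return Percent change.
#' @examples
#' relative_change(0.47, 0.53)  # 12.8
#' @export
relative_change <- function(a, b) {
  if (a == 0) stop("zero base value")
  100 * (b - a) / a
}

#' Percent reduction from a to b
#'
#' `100 * (a - b) / a`: how much lower `b` is than `a`, in percent of `a`.
#'
#' @param a Base value (nonzero).
#' @param b Compared value.
#' @return Percent reduction.
#' @export
percent_lower <- function(a, b) {
  if (a == 0) stop("zero base value")
  100 * (a - b) / a
}

#' RMSE/MAE error-dispersion ratio
#'
#' @param rmse,mae Error metrics (MAE nonzero).
#' @return The ratio, a measure of error-distribution tail weight (1 when
#'   all absolute errors are equal).
#' @export
rmse_mae_ratio <- function(rmse, mae) {
  if (mae == 0) stop("zero MAE")
  rmse / mae
}

#' Relative RMSE in percent of the observed mean
#'
#' @param rmse Root mean square error (g/kg).
#' @param mean_observed Mean observed value (nonzero, g/kg).
#' @return Percent.
#' @export
relative_rmse <- function(rmse, mean_observed) {
  if (mean_observed == 0) stop("zero mean")
  100 * rmse / mean_observed
}

#' Coefficient of variation in percent
#'
#' @param sd,mean Standard deviation and mean (nonzero) of a sample.
#' @return Percent.
#' @export
cv_percent <- function(sd, mean) {
  if (mean == 0) stop("zero mean")
  100 * sd / mean
}

#' Derived reporting statistics for a pair of evaluations
#'
#' Builds the reporting table comparing a base and an enhanced evaluation:
#' relative change of R^2, percent reductions of MAE and RMSE, the RMSE/MAE
#' ratios, and (when the observed mean is given) the relative RMSE of the
#' enhanced model. Values are rounded to one decimal, ratios to two.
#'
#' @param base,enhanced Named metric vectors `c(mae, rmse, r2)` (as returned
#'   by [som_metrics()] or an EvalReport's `pooled` element).
#' @param mean_observed Optional mean observed SOM (g/kg).
#' @return A one-row data frame of derived statistics.
#' @export
derived_stats <- function(base, enhanced, mean_observed = NULL) {
  out <- data.frame(
    r2_relative_change = round(relative_change(base["r2"], enhanced["r2"]), 1),
    mae_percent_lower = round(percent_lower(base["mae"], enhanced["mae"]), 1),
    rmse_percent_lower = round(percent_lower(base["rmse"], enhanced["rmse"]), 1),
    ratio_base = round(rmse_mae_ratio(base["rmse"], base["mae"]), 2),
    ratio_enhanced = round(rmse_mae_ratio(enhanced["rmse"], enhanced["mae"]), 2),
    row.names = NULL)
  if (!is.null(mean_observed))
    out$relative_rmse_percent <-
      round(relative_rmse(enhanced["rmse"], mean_observed), 1)
  out
}

#' Random-forest model specification
#'
#' The hyperparameter grids searched are 100-350 trees (step 50) and tree
#' depths 3-8; the chosen defaults are 250 trees of depth 6.
#'
#' @param n_estimators Number of trees (default 250).
#' @param max_depth Maximum tree depth (default 6).
#' @param grid_n_estimators,grid_max_depth Search grids for
#'   `grid_search = TRUE` fits.
#' @return An object of class `rf_spec`.
#' @export
rf_spec <- function(n_estimators = 250L, max_depth = 6L,
                    grid_n_estimators = c(100L, 150L, 200L, 250L, 300L, 350L),
                    grid_max_depth = 3:8) {
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 grid_n_estimators = as.integer(grid_n_estimators),
                 grid_max_depth = as.integer(grid_max_depth)),
            class = "rf_spec")
}

#' Train the random-forest SOM regressor
#'
#' With `grid_search = TRUE` an inner cross-validation selects
#' `(n_estimators, max_depth)` from the specification grids by pooled RMSE;
#' otherwise the chosen defaults are used. The fit is seeded and
#' deterministic.
#'
#' @param spec An [rf_spec()].
#' @param x Feature matrix or data frame.
#' @param y Numeric target (g/kg).
#' @param grid_search Run the inner grid search (default `FALSE`).
#' @param seed Integer seed.
#' @param inner_folds Folds of the inner search (default 5).
#' @return A fitted model of class `som_rf` (wraps the ranger forest and the
#'   chosen hyperparameters).
#' @export
train_rf <- function(spec = rf_spec(), x, y, grid_search = FALSE, seed = 1L,
                     inner_folds = 5L) {
  x <- as.data.frame(x)
  chosen <- c(spec$n_estimators, spec$max_depth)
  if (grid_search) {
    if (length(spec$grid_n_estimators) == 0 || length(spec$grid_max_depth) == 0)
      stop("empty hyperparameter grid")
    folds <- make_folds(length(y), inner_folds, seed = seed + 7L)
    best <- Inf
    for (nt in spec$grid_n_estimators) for (md in spec$grid_max_depth) {
      pred <- rep(NA_real_, length(y))
      for (f in seq_len(inner_folds)) {
        tr <- folds != f
        fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                              num.trees = nt, max.depth = md,
                              seed = seed + f, num.threads = 1)
        pred[!tr] <- stats::predict(fit, x[!tr, , drop = FALSE],
                                    num.threads = 1)$predictions
      }
      rmse <- sqrt(mean((pred - y)^2))
      if (rmse < best) {
        best <- rmse
        chosen <- c(nt, md)
      }
    }
  }
  fit <- ranger::ranger(x = x, y = y, num.trees = chosen[1],
                        max.depth = chosen[2], importance = "impurity",
                        seed = seed, num.threads = 1)
  structure(list(forest = fit, n_estimators = chosen[1],
                 max_depth = chosen[2], features = names(x), seed = seed),
            class = "som_rf")
}

#' @export
predict.som_rf <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[object$features]
  stats::predict(object$forest, newdata, num.threads = 1)$predictions
}

#' Seeded fold assignment
#'
#' @param n Number of samples (>= `folds`).
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in 1..folds, balanced to within one
#'   sample.
#' @export
make_folds <- function(n, folds = 10L, seed = 1L) {
  if (folds > n) stop("more folds than samples")
  rng <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    sample(rep(seq_len(folds), length.out = n))
  })
  rng
}

#' Cross-validate a SOM regressor
#'
#' Seeded 10-fold (by default) cross-validation: feature standardization is
#' fitted on each training fold only, the model is trained per fold, and
#' metrics are computed both per fold and pooled over the concatenated
#' out-of-fold predictions. For an [rf_spec()] the data is a FeatureTable;
#' for a [cnn_spec()] supply the patch tensor via `patches`.
#'
#' @param spec An [rf_spec()] or [cnn_spec()].
#' @param table FeatureTable (needs an `som` column); for CNN models it
#'   still supplies the target.
#' @param patches `PatchTensor` aligned with `table` rows (CNN only).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling folds and model fits.
#' @param grid_search Forwarded to [train_rf()].
#' @param ... Extra arguments forwarded to the model trainer (e.g. CNN
#'   `epochs`).
#' @return An `EvalReport`: list with `pooled` metrics, `fold_metrics`,
#'   `oof` out-of-fold predictions, `fold_assignment`, `models` (per-fold
#'   fits), `standardizers` and `seed`.
#' @export
cross_validate <- function(spec, table, patches = NULL, folds = 10L,
                           seed = 1L, grid_search = FALSE, ...) {
  y <- table$som
  n <- length(y)
  assign_f <- make_folds(n, folds, seed)
  oof <- rep(NA_real_, n)
  models <- vector("list", folds)
  standardizers <- vector("list", folds)
  fold_rows <- vector("list", folds)
  is_cnn <- inherits(spec, "cnn_spec")
  if (is_cnn && is.null(patches)) stop("CNN cross-validation needs patches")
  feats <- if (!is_cnn) feature_columns(table)

  for (f in seq_len(folds)) {
    tr <- assign_f != f
    if (is_cnn) {
      tr_x <- patches[tr, , , , drop = FALSE]
      te_x <- patches[!tr, , , , drop = FALSE]
      class(tr_x) <- class(te_x) <- class(patches)
      st <- standardize_fit(tr_x)
      tr_x <- standardize_apply(tr_x, st)
      te_x <- standardize_apply(te_x, st)
      fit <- train_cnn(spec, tr_x, y[tr], seed = seed + f, ...)
      oof[!tr] <- predict(fit, te_x)
    } else {
      st <- standardize_fit(table[tr, , drop = FALSE], columns = feats)
      tr_x <- standardize_apply(table[tr, , drop = FALSE], st,
                                columns = feats)[feats]
      te_x <- standardize_apply(table[!tr, , drop = FALSE], st,
                                columns = feats)[feats]
      fit <- train_rf(spec, tr_x, y[tr], grid_search = grid_search,
                      seed = seed + f)
      oof[!tr] <- predict(fit, te_x)
    }
    models[[f]] <- fit
    standardizers[[f]] <- st
    fold_rows[[f]] <- data.frame(fold = f, t(som_metrics(y[!tr], oof[!tr])))
  }
  structure(list(pooled = som_metrics(y, oof),
                 fold_metrics = do.call(rbind, fold_rows),
                 oof = oof, fold_assignment = assign_f,
                 models = models, standardizers = standardizers,
                 seed = seed),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("EvalReport: pooled MAE %.3f, RMSE %.3f, R2 %.3f (%d folds, seed %d)\n",
              p["mae"], p["rmse"], p["r2"], nrow(x$fold_metrics), x$seed))
  invisible(x)
}

#' Variable importance with category aggregation
#'
#' Normalizes the fitted forest's impurity importances to percentages
#' (summing to 100) and aggregates them into category shares using the
#' feature-kind map.
#'
#' @param fit A `som_rf` from [train_rf()].
#' @param feature_kinds Named character vector mapping feature name to
#'   category; features missing from the map fall into `"other"`.
#' @return A list of class `ImportanceReport` with data frames
#'   `per_feature` (feature, importance_percent) and `per_category`
#'   (category, importance_percent), each summing to 100.
#' @export
variable_importance <- function(fit, feature_kinds = NULL) {
  if (!inherits(fit, "som_rf")) stop("fit must be a trained som_rf model")
  imp <- fit$forest$variable.importance
  if (is.null(imp)) stop("model was trained without importance")
  imp <- pmax(imp, 0)
  pct <- 100 * imp / sum(imp)
  per_feature <- data.frame(feature = names(pct),
                            importance_percent = as.numeric(pct),
                            row.names = NULL)
  per_feature <- per_feature[order(-per_feature$importance_percent), ,
                             drop = FALSE]
  rownames(per_feature) <- NULL
  kind <- function(nm) {
    if (!is.null(feature_kinds) && nm %in% names(feature_kinds))
      feature_kinds[[nm]] else "other"
  }
  cats <- vapply(per_feature$feature, kind, character(1))
  agg <- tapply(per_feature$importance_percent, cats, sum)
  per_category <- data.frame(category = names(agg),
                             importance_percent = as.numeric(agg),
                             row.names = NULL)
  per_category <- per_category[order(-per_category$importance_percent), ,
                               drop = FALSE]
  rownames(per_category) <- NULL
  structure(list(per_feature = per_feature, per_category = per_category),
            class = "ImportanceReport")
}

#' Per-pixel prediction and uncertainty maps
#'
#' Applies the per-fold models of an [cross_validate()] report to feature
#' rasters. The prediction is the mean across fold models and the
#' uncertainty the standard deviation across them (0 when all fold models
#' agree). A pixel masked in any input channel is masked in both outputs.
#'
#' @param report An `EvalReport` (its `models` and `standardizers` are
#'   used).
#' @param stack Named list of co-registered feature `RasterGrid`s; names
#'   must cover the model features (RF) or patch channels (CNN).
#' @param window Patch edge length for CNN models (default 7).
#' @return List with `prediction` and `uncertainty` `RasterGrid`s.
#' @export
predict_map <- function(report, stack, window = 7L) {
  assert_coregistered(stack)
  ref <- stack[[1]]
  geom <- grid_geometry(ref)
  n_models <- length(report$models)
  is_cnn <- inherits(report$models[[1]], "som_cnn")
  npix <- length(ref$values)
  bad <- Reduce(`|`, lapply(stack, function(g) g$mask))
  preds <- matrix(NA_real_, npix, n_models)
  if (is_cnn) {
    centers <- expand.grid(row = seq_len(geom$nrow), col = seq_len(geom$ncol))
    xy <- data.frame(
      x = geom$transform[1] + (centers$col - 0.5) * geom$transform[3],
      y = geom$transform[2] - (centers$row - 0.5) * geom$transform[4])
    channels <- report$models[[1]]$channels
    if (is.null(channels)) channels <- names(stack)
    patches <- extract_patches(stack[channels], xy, window = window)
    for (m in seq_len(n_models)) {
      p <- standardize_apply(patches, report$standardizers[[m]])
      preds[, m] <- predict(report$models[[m]], p)
    }
    # expand.grid enumerates rows fastest, matching column-major matrices
  } else {
    feats <- report$models[[1]]$features
    X <- vapply(stack[feats], function(g) as.vector(g$values), numeric(npix))
    colnames(X) <- feats
    ok <- which(!as.vector(bad))
    for (m in seq_len(n_models)) {
      Xs <- standardize_apply(X[ok, , drop = FALSE],
                              report$standardizers[[m]])
      preds[ok, m] <- predict(report$models[[m]], Xs)
    }
  }
  mu <- rowMeans(preds)
  sdv <- apply(preds, 1, stats::sd)
  mu[bad] <- NA_real_; sdv[bad] <- NA_real_
  list(prediction = raster_grid(matrix(mu, geom$nrow), ref$transform, ref$crs),
       uncertainty = raster_grid(matrix(sdv, geom$nrow), ref$transform,
                                 ref$crs))
}
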