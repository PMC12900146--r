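# End-to-end experiment orchestration: synthesize (or load) a scene, fuse
# the multi-temporal bands, derive NDVI phenology features, assemble and
# select covariates, train and evaluate the regressors, and emit a
# machine-readable report. All randomness flows from the config seed.

#' Fuse a multi-date scene into per-band feature rasters
#'
#' Applies the configured fusion per spectral band across acquisition
#' dates: `"lew_dwt"` (energy-weighted approximation + local-energy detail
#' selection), `"dwt_mean"` (mean-rule wavelet fusion) or `"splice"` (no
#' fusion; every date-band is its own feature).
#'
#' @param scene List date -> list band -> `RasterGrid` (as produced by
#'   [make_scene()]).
#' @param method `"lew_dwt"`, `"dwt_mean"` or `"splice"`.
#' @param cfg A [fusion_config()]; its `baseline_index` is derived from
#'   `baseline_date`.
#' @param baseline_date Baseline acquisition label (must name a scene
#'   element).
#' @return Named list of `RasterGrid` features: `MMI<k>_<band>` for fused
#'   methods, `B<date>_<band>` for splicing.
#' @export
fuse_scene <- function(scene, method = c("lew_dwt", "dwt_mean", "splice"),
                       cfg = fusion_config(), baseline_date = NULL) {
  method <- match.arg(method)
  dates <- names(scene)
  if (is.null(baseline_date)) baseline_date <- dates[length(dates)]
  if (!baseline_date %in% dates) stop("baseline date not in scene")
  cfg$baseline_index <- match(baseline_date, dates)
  band_names <- names(scene[[1]])
  k <- length(dates)
  if (method == "splice") {
    out <- list()
    for (d in dates) for (b in band_names)
      out[[paste0("B", d, "_", b)]] <-
        raster_grid(normalize_band(scene[[d]][[b]]),
                    scene[[d]][[b]]$transform, scene[[d]][[b]]$crs)
    return(out)
  }
  out <- lapply(band_names, function(b) {
    images <- lapply(dates, function(d) scene[[d]][[b]])
    if (method == "lew_dwt") lew_dwt_fuse(images, cfg)
    else fuse_baseline(images, "traditional_dwt", cfg)
  })
  stats::setNames(out, paste0("MMI", k, "_", band_names))
}

pipeline_config_defaults <- function() {
  list(
    recipe = list(),
    fusion = list(levels = 2L, window = 3L, method = "lew_dwt"),
    sg = list(window = 7L, order = 3L),
    variable_sets = c("Ev", "Ev-Tn-Mm"),
    models = c("RF"),
    folds = 10L,
    rfe = list(enabled = TRUE, n_keep = 24L, repeats = 10L),
    cnn = list(epochs = 150L, batch = 16L, lr = 1e-3, patience = 20L),
    maps = FALSE,
    seed = 1L)
}

merge_config <- function(defaults, config) {
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], config[[nm]])
    else defaults[[nm]] <- config[[nm]]
  }
  defaults
}

#' Validate and resolve a pipeline configuration
#'
#' Merges a partial configuration (list or YAML file path) over the
#' defaults and validates the constrained fields before any computation.
#'
#' @param config Partial configuration list or path to a YAML file.
#' @return The resolved configuration list.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_config_defaults(), config)
  bad <- setdiff(cfg$variable_sets, c("Ev", "Ev-Tn-Mm"))
  if (length(bad))
    stop("unknown variable set(s): ", paste(bad, collapse = ", "))
  bad_m <- setdiff(cfg$models, c("RF", "CNN"))
  if (length(bad_m))
    stop("unknown model(s): ", paste(bad_m, collapse = ", "))
  if (!cfg$fusion$method %in% c("lew_dwt", "dwt_mean", "splice"))
    stop("unknown fusion method: ", cfg$fusion$method)
  if ("Ev-Tn-Mm" %in% cfg$variable_sets &&
      !is.null(cfg$recipe$years) && cfg$recipe$years < 1)
    stop("variable set Ev-Tn-Mm requires an NDVI stack (recipe years >= 1)")
  cfg
}

# Build the scene, sample points and every feature raster group once.
prepare_experiment <- function(cfg) {
  recipe <- do.call(scene_recipe, c(cfg$recipe, list(seed = cfg$seed)))
  som <- make_som_field(recipe)
  parts <- make_scene(recipe, som)
  samples <- draw_samples(recipe, som)

  fus_cfg <- fusion_config(levels = cfg$fusion$levels,
                           window = cfg$fusion$window)
  mm <- fuse_scene(parts$scene, cfg$fusion$method, fus_cfg,
                   baseline_date = recipe$baseline_date)

  tn_maps <- per_pixel_features(parts$ndvi_stack, window = cfg$sg$window,
                                order = cfg$sg$order,
                                samples_per_year = recipe$samples_per_year)
  tn_kinds <- c(n_min = "time-series NDVI", n_max = "time-series NDVI",
                n_std = "time-series NDVI", n_gsl = "time-series NDVI",
                n_amplitude = "time-series NDVI", n_phase = "time-series NDVI",
                mndvi = "vegetation", sdndvi = "vegetation")

  list(recipe = recipe, som = som, scene = parts$scene,
       samples = samples, covariates = parts$covariates,
       covariate_kinds = parts$covariate_kinds,
       categorical = parts$categorical,
       mm = mm, mm_kinds = stats::setNames(
         rep("multitemporal multispectral", length(mm)), names(mm)),
       tn = tn_maps, tn_kinds = tn_kinds,
       ndvi_stack = parts$ndvi_stack)
}

# Assemble the feature table and raster stack for one variable set,
# optionally running recursive feature elimination on the Ev block first.
build_variable_set <- function(prep, set, cfg) {
  ev_rasters <- prep$covariates
  ev_kinds <- prep$covariate_kinds
  tab_ev <- assemble_feature_table(prep$samples, ev_rasters,
                                   kinds = ev_kinds,
                                   categorical = prep$categorical)
  kinds_ev <- attr(tab_ev, "feature_kinds")
  ev_feats <- feature_columns(tab_ev)
  selection <- NULL
  if (isTRUE(cfg$rfe$enabled) && length(ev_feats) > cfg$rfe$n_keep) {
    selection <- rfe_select(tab_ev, n_keep = cfg$rfe$n_keep,
                            repeats = cfg$rfe$repeats, seed = cfg$seed)
    ev_feats <- attr(selection, "selected")
  }
  # one-hot columns map back to their source raster for the raster stack
  ev_stack <- list()
  for (f in ev_feats) {
    if (f %in% names(ev_rasters)) ev_stack[[f]] <- ev_rasters[[f]]
    else {
      src <- sub("_[^_]+$", "", f)
      lev <- as.numeric(sub(".*_", "", f))
      g <- ev_rasters[[src]]
      ev_stack[[f]] <- raster_grid((g$values == lev) * 1, g$transform, g$crs)
    }
  }
  if (set == "Ev") {
    stack <- ev_stack
    kinds <- kinds_ev[names(stack)]
  } else {
    stack <- c(ev_stack, prep$tn, prep$mm)
    kinds <- c(kinds_ev[names(ev_stack)], prep$tn_kinds, prep$mm_kinds)
  }
  tab <- assemble_feature_table(prep$samples, stack, kinds = kinds)
  list(table = tab, stack = stack, kinds = attr(tab, "feature_kinds"),
       selection = selection)
}

#' Run the end-to-end SOM mapping experiment
#'
#' Executes synthesize -> fuse -> NDVI features -> assemble/select ->
#' cross-validate -> (optionally) map, for every configured variable set
#' and model, and returns a machine-readable report bundle. Reports are
#' deterministic for a fixed config (the full resolved config and all
#' seeds are embedded).
#'
#' @param config Partial configuration list or YAML path; see
#'   [resolve_config()].
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` and maps as GeoTIFFs.
#' @return A list with `config`, `evaluations` (per model x variable set:
#'   `EvalReport`), `derived`, `quality`, `importance`, `selection`,
#'   `n_samples` and optionally `maps`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- resolve_config(config)
  prep <- prepare_experiment(cfg)

  baseline_stack <- prep$scene[[prep$recipe$baseline_date]]
  quality <- fusion_quality(prep$mm,
                            lapply(baseline_stack, function(g)
                              raster_grid(normalize_band(g), g$transform,
                                          g$crs)))

  evaluations <- list()
  sets <- list()
  for (set in cfg$variable_sets) {
    built <- build_variable_set(prep, set, cfg)
    sets[[set]] <- built
    for (model in cfg$models) {
      key <- paste(model, set, sep = "_")
      if (model == "RF") {
        evaluations[[key]] <- cross_validate(rf_spec(), built$table,
                                             folds = cfg$folds,
                                             seed = cfg$seed)
      } else {
        patches <- extract_patches(built$stack, built$table, window = 7L)
        evaluations[[key]] <- cross_validate(
          cnn_spec(), built$table, patches = patches, folds = cfg$folds,
          seed = cfg$seed, epochs = cfg$cnn$epochs, batch = cfg$cnn$batch,
          lr = cfg$cnn$lr, patience = cfg$cnn$patience)
      }
    }
  }

  derived <- NULL
  if (all(c("Ev", "Ev-Tn-Mm") %in% cfg$variable_sets)) {
    derived <- lapply(stats::setNames(cfg$models, cfg$models), function(m) {
      derived_stats(evaluations[[paste0(m, "_Ev")]]$pooled,
                    evaluations[[paste0(m, "_Ev-Tn-Mm")]]$pooled,
                    mean_observed = mean(sets[[1]]$table$som))
    })
  }

  imp <- NULL
  full_set <- if ("Ev-Tn-Mm" %in% names(sets)) "Ev-Tn-Mm" else
    names(sets)[1]
  built <- sets[[full_set]]
  rf_full <- train_rf(rf_spec(), built$table[feature_columns(built$table)],
                      built$table$som, seed = cfg$seed)
  imp <- variable_importance(rf_full, built$kinds)

  maps <- NULL
  if (isTRUE(cfg$maps) && "RF" %in% cfg$models) {
    maps <- predict_map(evaluations[[paste0("RF_", full_set)]], built$stack)
  }

  report <- list(config = cfg,
                 n_samples = nrow(sets[[1]]$table),
                 quality = quality,
                 evaluations = evaluations,
                 derived = derived,
                 selection = sets[[full_set]]$selection,
                 importance = imp,
                 maps = maps)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

report_to_json <- function(report) {
  strip <- function(ev) list(pooled = as.list(ev$pooled),
                             fold_metrics = ev$fold_metrics,
                             fold_assignment = ev$fold_assignment,
                             seed = ev$seed)
  jsonlite::toJSON(list(
    config = report$config,
    n_samples = report$n_samples,
    quality = unclass(report$quality),
    evaluations = lapply(report$evaluations, strip),
    derived = report$derived,
    selection = report$selection,
    importance = if (!is.null(report$importance))
      unclass(report$importance)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_to_json(report), file.path(out_dir, "report.json"))
  if (!is.null(report$maps)) {
    write_raster(report$maps$prediction,
                 file.path(out_dir, "som_prediction.tif"))
    write_raster(report$maps$uncertainty,
                 file.path(out_dir, "som_uncertainty.tif"))
  }
  invisible(out_dir)
}

#' Compare fusion strategies under identical folds and seeds
#'
#' Trains the configured model on the multi-temporal features of each
#' fusion method (identical samples, folds and seeds) and reports
#' RMSE/MAE/R^2 per method plus the pairwise percent RMSE reductions.
#'
#' @param config Partial configuration list or YAML path.
#' @param methods At least two of `"lew_dwt"`, `"dwt_mean"`, `"splice"`.
#' @param include_covariates Also include the (selected) environmental and
#'   NDVI features alongside the multi-temporal block (default `TRUE`,
#'   mirroring the full-variable comparison).
#' @return A list with `metrics` (data frame per method) and
#'   `rmse_reduction_percent` (methods x methods matrix, zero diagonal:
#'   entry \[i, j\] is the reduction achieved by method i relative to
#'   method j).
#' @export
compare_fusions <- function(config = list(),
                            methods = c("splice", "dwt_mean", "lew_dwt"),
                            include_covariates = TRUE) {
  if (length(methods) < 2) stop("need at least two methods")
  cfg <- resolve_config(config)
  prep <- prepare_experiment(cfg)

  base <- NULL
  if (include_covariates) {
    built <- build_variable_set(prep, "Ev", cfg)
    base <- built$stack
  }
  fus_cfg <- fusion_config(levels = cfg$fusion$levels,
                           window = cfg$fusion$window)
  evals <- lapply(stats::setNames(methods, methods), function(m) {
    mm <- fuse_scene(prep$scene, m, fus_cfg,
                     baseline_date = prep$recipe$baseline_date)
    stack <- c(base, prep$tn, mm)
    tab <- assemble_feature_table(prep$samples, stack)
    cross_validate(rf_spec(), tab, folds = cfg$folds, seed = cfg$seed)
  })
  metrics <- do.call(rbind, lapply(names(evals), function(m)
    data.frame(method = m, t(evals[[m]]$pooled))))
  n <- length(methods)
  red <- matrix(0, n, n, dimnames = list(methods, methods))
  for (i in seq_len(n)) for (j in seq_len(n))
    red[i, j] <- percent_lower(metrics$rmse[j], metrics$rmse[i])
  list(metrics = metrics, rmse_reduction_percent = red, evaluations = evals)
}

#' Standard synthetic benchmark of the full pipeline
#'
#' Runs the toolkit end to end on the default synthetic study area
#' (200 x 200 pixels, 500 samples, 10-fold cross-validation): random-forest
#' evaluation of the environmental-only (Ev) and composite (Ev-Tn-Mm)
#' variable sets, the shallow-CNN evaluation of the composite set, a
#' random-forest comparison of the three fusion strategies under identical
#' folds, and the fusion quality metrics of the fused product against the
#' baseline-date scene.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param folds Cross-validation folds (default 10).
#' @param cnn_epochs,cnn_patience CNN training caps (defaults 80 / 15).
#' @param rfe Run recursive feature elimination on the Ev block (default
#'   `TRUE`).
#' @param recipe Overrides for [scene_recipe()] fields.
#' @return A list with `samples` statistics, `evaluations` (named
#'   `EvalReport`s), `fusion_comparison` (per-method pooled metrics),
#'   `quality` and `derived` statistics.
#' @export
som_benchmark <- function(seed = 1L, folds = 10L, cnn_epochs = 80L,
                          cnn_patience = 15L, rfe = TRUE, recipe = list()) {
  cfg <- resolve_config(list(seed = as.integer(seed), folds = folds,
                             recipe = recipe,
                             rfe = list(enabled = rfe)))
  prep <- prepare_experiment(cfg)

  baseline_stack <- prep$scene[[prep$recipe$baseline_date]]
  quality <- fusion_quality(prep$mm,
                            lapply(baseline_stack, function(g)
                              raster_grid(normalize_band(g), g$transform,
                                          g$crs)))

  ev <- build_variable_set(prep, "Ev", cfg)
  full <- build_variable_set(prep, "Ev-Tn-Mm", cfg)

  evaluations <- list(
    RF_Ev = cross_validate(rf_spec(), ev$table, folds = folds,
                           seed = cfg$seed),
    RF_EvTnMm = cross_validate(rf_spec(), full$table, folds = folds,
                               seed = cfg$seed))
  patches <- extract_patches(full$stack, full$table, window = 7L)
  evaluations$CNN_EvTnMm <- cross_validate(
    cnn_spec(), full$table, patches = patches, folds = folds,
    seed = cfg$seed, epochs = cnn_epochs, patience = cnn_patience)

  # fusion-strategy comparison on identical folds: Ev + Tn + per-method Mm
  fus_cfg <- fusion_config(levels = cfg$fusion$levels,
                           window = cfg$fusion$window)
  fusion_eval <- lapply(
    stats::setNames(c("splice", "dwt_mean", "lew_dwt"),
                    c("splice", "dwt_mean", "lew_dwt")),
    function(m) {
      mm <- if (m == "lew_dwt") prep$mm else
        fuse_scene(prep$scene, m, fus_cfg,
                   baseline_date = prep$recipe$baseline_date)
      stack <- c(ev$stack, prep$tn, mm)
      tab <- assemble_feature_table(prep$samples, stack)
      cross_validate(rf_spec(), tab, folds = folds, seed = cfg$seed)$pooled
    })

  list(samples = c(n = nrow(ev$table), mean = mean(ev$table$som),
                   sd = stats::sd(ev$table$som)),
       evaluations = evaluations,
       fusion_comparison = fusion_eval,
       quality = quality,
       derived = derived_stats(evaluations$RF_Ev$pooled,
                               evaluations$RF_EvTnMm$pooled,
                               mean_observed = mean(ev$table$som)),
       seed = cfg$seed)
}
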