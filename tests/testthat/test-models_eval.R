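test_that("accuracy metrics match hand arithmetic and edge cases", {
  expect_equal(som_metrics(c(1, 2, 3), c(1, 2, 3)),
               c(mae = 0, rmse = 0, r2 = 1))
  obs <- c(18, 20, 22)
  expect_equal(unname(som_metrics(obs, rep(mean(obs), 3))["r2"]), 0)
  m <- som_metrics(c(0, 0, 4), c(1, 1, 1))
  expect_equal(unname(m["mae"]), 5 / 3, tolerance = 1e-12)
  expect_equal(unname(m["rmse"]), sqrt(11 / 3), tolerance = 1e-4)
  expect_equal(unname(m["r2"]), -0.03125, tolerance = 1e-12)
  expect_true(is.na(som_metrics(c(2, 2, 2), c(1, 2, 3))["r2"]))
})

test_that("RMSE is at least MAE, with equality iff errors are equal", {
  set.seed(51)
  for (i in 1:20) {
    obs <- rnorm(30); pred <- obs + rnorm(30)
    m <- som_metrics(obs, pred)
    expect_gte(m[["rmse"]], m[["mae"]] - 1e-12)
  }
  m_eq <- som_metrics(c(1, 2, 3), c(2, 3, 4))   # all errors equal
  expect_equal(m_eq[["rmse"]], m_eq[["mae"]])
})

test_that("derived statistics compute changes, ratios and dispersion", {
  expect_equal(relative_change(2, 2), 0)
  expect_equal(relative_change(0.5, 0.6), 20)
  expect_equal(percent_lower(2, 1.5), 25)
  expect_equal(rmse_mae_ratio(1.5, 1.5), 1)
  expect_equal(relative_rmse(2, 20), 10)
  expect_equal(cv_percent(2.42, 20.12), 100 * 2.42 / 20.12)
  expect_error(relative_change(0, 1), "zero")
  d <- derived_stats(c(mae = 1.0, rmse = 1.5, r2 = 0.5),
                     c(mae = 0.8, rmse = 1.2, r2 = 0.6),
                     mean_observed = 20)
  expect_equal(d$r2_relative_change, 20)
  expect_equal(d$mae_percent_lower, 20)
  expect_equal(d$ratio_enhanced, 1.5)
  expect_equal(d$relative_rmse_percent, 6)
})

test_that("fold assignment is seeded, balanced and reproducible", {
  f1 <- make_folds(100, 10, seed = 3)
  f2 <- make_folds(100, 10, seed = 3)
  expect_identical(f1, f2)
  expect_equal(as.vector(table(f1)), rep(10L, 10))
  expect_false(identical(f1, make_folds(100, 10, seed = 4)))
  expect_error(make_folds(5, 10), "folds")
})

make_linear_table <- function(n, p = 4, noise = 0.1, seed = 52) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  y <- 20 + 2 * X[, 1] + rnorm(n, sd = noise)
  cbind(data.frame(sample_id = 1:n, x = 0, y = 0, som = y),
        as.data.frame(X))
}

test_that("random forest recovers a noiseless linear signal out of fold", {
  tab <- make_linear_table(500, noise = 0)
  ev <- cross_validate(rf_spec(), tab, folds = 10, seed = 1)
  expect_gt(ev$pooled[["r2"]], 0.9)
})

test_that("random forest does not hallucinate signal from pure noise", {
  tab <- make_linear_table(300)
  set.seed(53)
  tab$som <- rnorm(300)                        # decouple the target
  ev <- cross_validate(rf_spec(), tab, folds = 10, seed = 1)
  expect_lte(ev$pooled[["r2"]], 0.1)
})

test_that("cross-validation is deterministic under its seed", {
  tab <- make_linear_table(120)
  e1 <- cross_validate(rf_spec(), tab, folds = 5, seed = 2)
  e2 <- cross_validate(rf_spec(), tab, folds = 5, seed = 2)
  expect_identical(e1$fold_assignment, e2$fold_assignment)
  expect_identical(e1$oof, e2$oof)
  expect_identical(e1$pooled, e2$pooled)
  # RMSE >= MAE also holds pooled
  expect_gte(e1$pooled[["rmse"]], e1$pooled[["mae"]])
})

test_that("grid search picks hyperparameters from the stated grids", {
  tab <- make_linear_table(80)
  spec <- rf_spec(grid_n_estimators = c(50L, 100L), grid_max_depth = c(2L, 4L))
  fit <- train_rf(spec, tab[paste0("f", 1:4)], tab$som, grid_search = TRUE,
                  seed = 4, inner_folds = 3)
  expect_true(fit$n_estimators %in% c(50L, 100L))
  expect_true(fit$max_depth %in% c(2L, 4L))
  expect_error(train_rf(rf_spec(grid_n_estimators = integer(0)),
                        tab[paste0("f", 1:4)], tab$som, grid_search = TRUE),
               "empty")
})

test_that("CNN forward contract: one finite value per patch, reproducible", {
  set.seed(54)
  P <- array(rnorm(6 * 7 * 7 * 3), c(6, 7, 7, 3))
  class(P) <- c("PatchTensor", class(P))
  spec <- cnn_spec()
  W <- somfuse:::cnn_init_weights(spec, 3, seed = 1)
  out <- somfuse:::cnn_forward(W, P, spec, training = FALSE)$yhat
  expect_length(out, 6)
  expect_true(all(is.finite(out)))
  fit <- train_cnn(spec, P, rnorm(6, 20), seed = 1, epochs = 3, batch = 2,
                   patience = 5)
  expect_identical(predict(fit, P), predict(fit, P))  # no inference dropout
})

test_that("CNN converges to a constant target", {
  set.seed(55)
  P <- array(rnorm(40 * 7 * 7 * 2), c(40, 7, 7, 2))
  class(P) <- c("PatchTensor", class(P))
  fit <- train_cnn(cnn_spec(), P, rep(20.5, 40), seed = 2, epochs = 60,
                   patience = 60)
  expect_true(all(abs(predict(fit, P) - 20.5) < 0.1))
})

test_that("CNN learns a centre-pixel signal", {
  set.seed(56)
  n <- 200
  P <- array(rnorm(n * 7 * 7 * 2), c(n, 7, 7, 2))
  class(P) <- c("PatchTensor", class(P))
  y <- 20 + 2 * P[, 4, 4, 1] + rnorm(n, sd = 0.1)
  fit <- train_cnn(cnn_spec(), P, y, seed = 3, epochs = 250, patience = 250)
  r2 <- som_metrics(y, predict(fit, P))[["r2"]]
  expect_gt(r2, 0.8)
})

test_that("importance percentages conserve mass at both levels", {
  tab <- make_linear_table(200, p = 5)
  fit <- train_rf(rf_spec(), tab[paste0("f", 1:5)], tab$som, seed = 6)
  kinds <- c(f1 = "soil", f2 = "climate", f3 = "climate", f4 = "topographic",
             f5 = "topographic")
  imp <- variable_importance(fit, kinds)
  expect_equal(sum(imp$per_feature$importance_percent), 100, tolerance = 1e-9)
  expect_equal(sum(imp$per_category$importance_percent), 100, tolerance = 1e-9)
  expect_true(all(imp$per_feature$importance_percent >= 0))
  # the single driver ranks first, and its category dominates
  expect_equal(imp$per_feature$feature[1], "f1")
  expect_equal(imp$per_category$category[1], "soil")

  fit1 <- train_rf(rf_spec(), tab["f1"], tab$som, seed = 6)
  imp1 <- variable_importance(fit1)
  expect_equal(imp1$per_feature$importance_percent, 100)
})

test_that("prediction maps agree with table predictions and quantify spread", {
  set.seed(57)
  g1 <- test_grid(matrix(rnorm(144), 12))
  g2 <- test_grid(matrix(rnorm(144), 12))
  stack <- list(f1 = g1, f2 = g2)
  samples <- draw_samples(small_recipe(), test_grid(matrix(20, 12, 12)),
                          n = 50, noise_sd = 0)
  tab <- assemble_feature_table(samples, stack)
  tab$som <- 20 + 2 * tab$f1 - tab$f2 + rnorm(nrow(tab), sd = 0.05)
  ev <- cross_validate(rf_spec(), tab, folds = 5, seed = 3)
  maps <- predict_map(ev, stack)
  expect_s3_class(maps$prediction, "RasterGrid")
  expect_true(all(maps$uncertainty$values >= 0))

  # identical fold models -> zero uncertainty everywhere
  ev0 <- ev
  ev0$models <- rep(ev$models[1], 5)
  ev0$standardizers <- rep(ev$standardizers[1], 5)
  maps0 <- predict_map(ev0, stack)
  expect_equal(max(maps0$uncertainty$values), 0)

  # prediction at a sample pixel equals the fold-model mean of the
  # standardized table prediction for that sample
  px <- points_to_pixels(grid_geometry(g1), tab$x[1], tab$y[1])
  per_model <- vapply(seq_along(ev$models), function(m) {
    Z <- standardize_apply(tab[1, , drop = FALSE], ev$standardizers[[m]],
                           columns = c("f1", "f2"))
    predict(ev$models[[m]], Z[c("f1", "f2")])
  }, numeric(1))
  expect_equal(maps$prediction$values[px], mean(per_model), tolerance = 1e-10)

  # constant inputs give a constant map
  const_stack <- list(f1 = test_grid(matrix(0.3, 12, 12)),
                      f2 = test_grid(matrix(-0.2, 12, 12)))
  maps_c <- predict_map(ev, const_stack)
  expect_equal(max(maps_c$prediction$values) - min(maps_c$prediction$values),
               0)
})
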