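test_that("combination counts match the closed form", {
  expect_equal(count_combinations(6, 1), 6)
  expect_equal(count_combinations(6, 3), 20)
  expect_equal(count_combinations(9, 0), 1)
  expect_error(count_combinations(4, 5), "k <= n")
})

test_that("multi-temporal subsets always contain the baseline", {
  dates <- c("2014", "2015", "2017", "2018", "2019", "2020", "2023")
  expect_equal(enumerate_mmi(dates, "2020", 1), list("2020"))
  all7 <- enumerate_mmi(dates, "2020", 7)
  expect_length(all7, 1)
  expect_setequal(all7[[1]], dates)
  m3 <- enumerate_mmi(dates, "2020", 3)
  expect_length(m3, 15)
  expect_true(all(vapply(m3, function(s) "2020" %in% s, logical(1))))
  expect_true(all(lengths(m3) == 3))
  # deterministic lexicographic order
  expect_identical(m3, enumerate_mmi(dates, "2020", 3))
  expect_identical(m3[[1]], c("2014", "2015", "2020"))
  # union over m covers every baseline-containing subset: 2^6 = 64
  expect_equal(sum(vapply(1:7, function(m)
    length(enumerate_mmi(dates, "2020", m)), numeric(1))), 64)
  expect_error(enumerate_mmi(dates, "2021", 2), "baseline")
  expect_error(enumerate_mmi(dates, "2020", 8), "range")
})

test_that("points map to the pixel whose half-open extent contains them", {
  geom <- grid_geometry(nrow = 4, ncol = 4, transform = TEST_TRANSFORM,
                        crs = TEST_CRS)
  px <- points_to_pixels(geom, 500000 + c(15, 30, 59.9), 4070000 - c(15, 45, 100))
  expect_equal(px[, "col"], c(1L, 2L, 2L))
  expect_equal(px[, "row"], c(1L, 2L, 4L))
  out <- points_to_pixels(geom, 499999, 4070000 - 15)
  expect_true(is.na(out[1, "col"]))
})

test_that("feature-table assembly drops masked samples and one-hot encodes", {
  vals <- matrix(as.numeric(1:16), 4)
  cont <- test_grid(vals)
  cat_r <- test_grid(matrix(rep(c(1, 2), each = 8), 4))
  masked <- test_grid({
    v <- vals; v[1, 1] <- NA; v
  })
  samples <- data.frame(x = 500000 + c(15, 45, 75),
                        y = 4070000 - c(15, 15, 45),
                        som = c(20, 21, 22))
  expect_message(
    tab <- assemble_feature_table(samples, list(a = cont, b = masked,
                                                cl = cat_r),
                                  kinds = c(a = "soil", cl = "parent material"),
                                  categorical = "cl"),
    "dropped")
  expect_equal(nrow(tab), 2)                 # sample on masked cell dropped
  expect_setequal(somfuse:::feature_columns(tab),
                  c("a", "b", "cl_1", "cl_2"))
  expect_equal(attr(tab, "feature_kinds")[["cl_1"]], "parent material")
  expect_true(all(tab$cl_1 + tab$cl_2 == 1))
})

test_that("patch extraction preserves the centre and reflects at edges", {
  set.seed(41)
  g <- test_grid(matrix(rnorm(100), 10))
  # centre sample: patch equals the direct neighbourhood
  s_mid <- data.frame(x = 500000 + 5.5 * 30, y = 4070000 - 5.5 * 30)
  p <- extract_patches(list(f = g), s_mid, window = 7)
  expect_equal(dim(p), c(1, 7, 7, 1))
  expect_equal(p[1, , , 1], g$values[3:9, 3:9])
  expect_equal(unname(p[1, 4, 4, 1]), g$values[6, 6])  # centre = point value

  # corner sample: manual reflection construction
  s_corner <- data.frame(x = 500000 + 15, y = 4070000 - 15)
  pc <- extract_patches(list(f = g), s_corner, window = 7)
  ridx <- c(4, 3, 2, 1, 2, 3, 4)
  expect_equal(pc[1, , , 1], g$values[ridx, ridx])

  # constant raster -> constant patch
  pk <- extract_patches(list(f = test_grid(matrix(2, 10, 10))), s_mid)
  expect_true(all(pk == 2))
  expect_error(extract_patches(list(f = g), data.frame(x = 0, y = 0)),
               "outside")
})

test_that("standardization round-trips and flags zero-variance features", {
  set.seed(42)
  X <- matrix(rnorm(60, mean = 5, sd = 2), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  st <- standardize_fit(X)
  Z <- standardize_apply(X, st)
  expect_equal(colMeans(Z), c(a = 0, b = 0, c = 0), tolerance = 1e-12)
  expect_equal(apply(Z, 2, sd), c(a = 1, b = 1, c = 1), tolerance = 1e-12)
  expect_equal(standardize_apply(Z, st, invert = TRUE), X, tolerance = 1e-10)

  Xz <- cbind(X, d = rep(3, 20))
  expect_warning(stz <- standardize_fit(Xz), "zero-variance")
  Zz <- standardize_apply(Xz, stz)
  expect_true(all(Zz[, "d"] == 0))

  # patch tensors standardize per channel
  P <- array(rnorm(5 * 7 * 7 * 2, mean = 3), c(5, 7, 7, 2))
  class(P) <- c("PatchTensor", class(P))
  stp <- standardize_fit(P)
  Zp <- standardize_apply(P, stp)
  expect_equal(mean(Zp[, , , 1]), 0, tolerance = 1e-12)
  expect_equal(standardize_apply(Zp, stp, invert = TRUE), P,
               tolerance = 1e-10)
})

test_that("recursive elimination keeps the informative feature every repeat", {
  set.seed(43)
  n <- 120
  X <- data.frame(matrix(rnorm(n * 6), n))
  names(X) <- paste0("f", 1:6)
  tab <- cbind(data.frame(sample_id = 1:n, x = 0, y = 0,
                          som = 3 * X$f3 + rnorm(n, sd = 0.05)), X)
  res <- rfe_select(tab, n_keep = 2, repeats = 4, seed = 9,
                    num.trees = 100)
  expect_equal(res$feature[1], "f3")
  expect_equal(res$frequency[res$feature == "f3"], 1)
  expect_setequal(attr(res, "selected"),
                  res$feature[1:2])
  # determinism under the seed
  res2 <- rfe_select(tab, n_keep = 2, repeats = 4, seed = 9,
                     num.trees = 100)
  expect_identical(res, res2)
  # n_keep = all features returns the identity set
  res_all <- rfe_select(tab, n_keep = 6, repeats = 2, seed = 1,
                        num.trees = 50)
  expect_setequal(attr(res_all, "selected"), names(X))
})

test_that("elimination stays well-defined in the presence of duplicates", {
  # exact duplicates share their information; the elimination must still
  # return a full-sized, deterministic selection that keeps the target's
  # true driver (ensemble impurity importance does not split credit
  # between copies, so pair members can legitimately co-survive)
  set.seed(44)
  n <- 150
  base <- matrix(rnorm(n * 8), n)
  colnames(base) <- paste0("u", 1:8)
  y <- 4 * base[, 2] + rnorm(n, sd = 0.1)
  dup <- base[, c(2, 5)]
  colnames(dup) <- c("copy2", "copy5")
  tab <- cbind(data.frame(sample_id = 1:n, x = 0, y = 0, som = as.vector(y)),
               as.data.frame(base), as.data.frame(dup))
  res <- rfe_select(tab, n_keep = 4, repeats = 3, seed = 5, num.trees = 150)
  sel <- attr(res, "selected")
  expect_length(sel, 4)
  expect_true(any(c("u2", "copy2") %in% sel))   # driver information kept
  expect_identical(res, rfe_select(tab, n_keep = 4, repeats = 3, seed = 5,
                                   num.trees = 150))
})
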