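test_that("band normalization min-max scales over unmasked cells", {
  expect_equal(normalize_band(matrix(c(0, 10, 5, 10), 2)),
               matrix(c(0, 1, 0.5, 1), 2))
  expect_equal(normalize_band(matrix(4, 3, 3)), matrix(0, 3, 3))
  m <- matrix(c(NA, 2, 4, 6), 2)
  out <- normalize_band(m)
  expect_equal(out[2, 1], 0)          # min/max computed without masked cell
  expect_equal(out[2, 2], 1)
  expect_true(is.na(out[1, 1]))
  expect_error(normalize_band(matrix(NA_real_, 2, 2)), "fully masked")
})

test_that("image energy is the sum of squares and is homogeneous", {
  expect_equal(image_energy(matrix(1:4, 2)), 30)
  expect_equal(image_energy(matrix(0, 5, 5)), 0)
  set.seed(2)
  x <- matrix(rnorm(16), 4)
  expect_equal(image_energy(3 * x), 9 * image_energy(x))
})

test_that("energy weights normalize, preserve order and permute with input", {
  expect_equal(energy_weights(c(30, 10)), c(0.75, 0.25))
  expect_equal(energy_weights(5), 1)
  expect_equal(energy_weights(rep(2, 4)), rep(0.25, 4))
  expect_error(energy_weights(c(0, 0)), "zero")
  e <- c(4, 1, 3)
  expect_equal(energy_weights(e[c(3, 1, 2)]), energy_weights(e)[c(3, 1, 2)])
  expect_equal(sum(energy_weights(runif(7))), 1, tolerance = 1e-12)
})

test_that("Haar transform of a constant block concentrates into LL", {
  p <- dwt_decompose(matrix(4, 2, 2), fusion_config(levels = 1))
  expect_equal(p$levels[[1]]$LL, matrix(8, 1, 1))
  expect_equal(p$levels[[1]]$HH, matrix(0, 1, 1))
  expect_equal(p$levels[[1]]$HL, matrix(0, 1, 1))
  expect_equal(p$levels[[1]]$LH, matrix(0, 1, 1))
})

test_that("one Haar level agrees with the directly coded butterfly oracle", {
  set.seed(5)
  x <- matrix(rnorm(36), 6)
  p <- dwt_decompose(x, fusion_config(levels = 1))
  o <- oracle_haar_level(x)
  expect_equal(p$levels[[1]]$LL, o$LL)
  expect_equal(p$levels[[1]]$HL, o$HL)
  expect_equal(p$levels[[1]]$LH, o$LH)
  expect_equal(p$levels[[1]]$HH, o$HH)
})

test_that("decompose/reconstruct round-trips odd sizes via recorded padding", {
  set.seed(6)
  for (sz in list(c(5, 5), c(7, 9), c(8, 8), c(11, 6))) {
    x <- matrix(rnorm(prod(sz)), sz[1], sz[2])
    p <- dwt_decompose(x, fusion_config(levels = 2))
    back <- dwt_reconstruct(p)
    expect_identical(dim(back), dim(x))
    expect_lt(max(abs(back - x)) / max(abs(x)), 1e-8)
  }
  expect_error(dwt_decompose(matrix(1, 2, 2), fusion_config(levels = 2)),
               "too small")
})

test_that("local energy matches the brute-force oracle and edge cases", {
  expect_equal(local_energy(matrix(1, 3, 3), 3)[2, 2], 9)
  expect_equal(local_energy(matrix(0, 4, 4), 3), matrix(0, 4, 4))
  set.seed(8)
  for (n in c(4, 8)) {
    x <- matrix(rnorm(n * n), n)
    expect_equal(local_energy(x, 3), oracle_local_energy(x, 3),
                 tolerance = 1e-12)
  }
  x <- matrix(rnorm(64), 8)
  expect_equal(local_energy(x, 5), oracle_local_energy(x, 5),
               tolerance = 1e-12)
  expect_error(local_energy(matrix(1, 4, 4), 2), "odd")
})

test_that("coefficient fusion follows the weighted-mean and argmax rules", {
  mk <- function(v) dwt_decompose(matrix(v, 4, 4), fusion_config(levels = 1))
  # LL weighted mean: constants 2 and 6 with weights 0.75/0.25 -> LL of 3
  pa <- mk(2); pb <- mk(6)
  fused <- fuse_coefficients(list(pa, pb), fusion_config(levels = 1),
                             weights = c(0.75, 0.25))
  expect_equal(fused$levels[[1]]$LL, 0.75 * pa$levels[[1]]$LL +
                 0.25 * pb$levels[[1]]$LL)

  # idempotence: identical pyramids fuse to themselves under any rule
  set.seed(9)
  x <- matrix(rnorm(64), 8)
  p <- dwt_decompose(x, fusion_config(levels = 2))
  for (rl in c("energy_weighted", "local_energy_max"))
    for (rh in c("local_energy_max", "energy_weighted", "mean")) {
      cfg <- fusion_config(levels = 2, rule_low = rl, rule_high = rh)
      f <- fuse_coefficients(list(p, p, p), cfg)
      expect_equal(dwt_reconstruct(f), x, tolerance = 1e-10)
    }

  # argmax selection: uniformly larger detail magnitude wins everywhere
  set.seed(10)
  base <- matrix(rnorm(64), 8)
  pa <- dwt_decompose(base, fusion_config(levels = 1))
  pb <- pa
  pb$levels[[1]]$HH <- pa$levels[[1]]$HH * 3 + sign(pa$levels[[1]]$HH)
  f <- fuse_coefficients(list(pa, pb), fusion_config(levels = 1))
  expect_equal(f$levels[[1]]$HH, pb$levels[[1]]$HH)

  expect_error(fuse_coefficients(list(), fusion_config()), "empty")
  p2 <- dwt_decompose(matrix(1, 6, 6), fusion_config(levels = 1))
  expect_error(fuse_coefficients(list(pa, p2), fusion_config(levels = 1)),
               "structure")
})

test_that("self-fusion is the identity on the normalized image", {
  img <- random_grid(16, 16, seed = 12)
  f <- lew_dwt_fuse(list(img, img), fusion_config())
  expect_equal(f$values, normalize_band(img), tolerance = 1e-8)
  f3 <- lew_dwt_fuse(list(img, img, img), fusion_config(baseline_index = 2))
  expect_equal(f3$values, normalize_band(img), tolerance = 1e-8)
})

test_that("fusing constant images yields a constant; masks are rejected", {
  a <- test_grid(matrix(3, 8, 8)); b <- test_grid(matrix(5, 8, 8))
  expect_error(lew_dwt_fuse(list(a, b)), "zero")   # both normalize to zero
  ab <- test_grid(matrix(c(3, 5), 8, 8))
  f <- lew_dwt_fuse(list(ab, ab))
  expect_equal(sort(unique(as.vector(round(f$values, 12)))), c(0, 1))
  full_mask <- test_grid(matrix(NA_real_, 8, 8))
  expect_error(lew_dwt_fuse(list(ab, full_mask)), "masked")
})

test_that("single-image fusion returns the normalized input", {
  img <- random_grid(10, 10, seed = 13)
  f <- lew_dwt_fuse(list(img))
  expect_equal(f$values, normalize_band(img), tolerance = 1e-8)
})

test_that("fusing a sharp with a blurred copy does not lose gradient", {
  set.seed(14)
  sharp <- matrix(rnorm(32 * 32), 32)
  blur <- sharp
  for (i in 2:31) for (j in 2:31)
    blur[i, j] <- mean(sharp[(i - 1):(i + 1), (j - 1):(j + 1)])
  g_sharp <- test_grid(sharp); g_blur <- test_grid(blur)
  f <- lew_dwt_fuse(list(g_blur, g_sharp), fusion_config(baseline_index = 1))
  expect_gte(average_gradient(f$values),
             average_gradient(normalize_band(g_blur)))
})

test_that("baseline fusion methods behave as documented", {
  img <- random_grid(12, 12, seed = 15)
  f <- fuse_baseline(list(img, img), "traditional_dwt")
  expect_equal(f$values, normalize_band(img), tolerance = 1e-8)

  two <- test_grid(matrix(c(1, 9), 8, 8))
  f2 <- fuse_baseline(list(two, two), "traditional_dwt")
  expect_equal(f2$values, normalize_band(two), tolerance = 1e-8)

  dates <- lapply(1:2, function(i) random_grid(8, 8, seed = i))
  sp <- fuse_baseline(dates, "simple_splicing")
  expect_length(sp, 2)
  expect_equal(sp[[1]]$values, normalize_band(dates[[1]]))
  expect_error(fuse_baseline(dates, "splice_means"), "arg")
})
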