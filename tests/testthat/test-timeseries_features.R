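test_that("NDVI formula, clipping and zero-denominator masking", {
  expect_equal(ndvi(0.5, 0.1), 2 / 3, tolerance = 1e-12)
  expect_equal(ndvi(0.4, 0.4), 0)
  expect_equal(ndvi(0.3, 0), 1)
  expect_true(is.na(ndvi(0.2, -0.2)))
  expect_equal(ndvi(c(0.5, 0.4), c(0.1, 0.4)), c(2 / 3, 0))
})

test_that("S-G filtering is the identity on low-degree polynomials", {
  t <- 0:22
  for (coefs in list(c(0.4, 0, 0, 0), c(0.1, 0.02, 0, 0),
                     c(0.2, 0.01, -0.002, 0), c(0.3, 0.05, -0.004, 1e-4))) {
    y <- coefs[1] + coefs[2] * t + coefs[3] * t^2 + coefs[4] * t^3
    expect_equal(sg_filter(y, window = 7, order = 3), y, tolerance = 1e-10)
  }
  expect_equal(sg_filter(c(1, 2, 3, 4, 5), window = 5, order = 2),
               c(1, 2, 3, 4, 5), tolerance = 1e-10)
  expect_error(sg_filter(1:10, window = 4, order = 2), "odd")
  expect_error(sg_filter(1:10, window = 5, order = 6), "order")
})

test_that("S-G filtering damps noise around a smooth annual cycle", {
  set.seed(31)
  t <- 0:45
  clean <- 0.5 + 0.3 * cos(2 * pi * t / 23)
  noisy <- clean + rnorm(46, sd = 0.05)
  sm <- sg_filter(noisy, window = 7, order = 3)
  expect_lt(mean((sm - clean)^2), mean((noisy - clean)^2))
})

test_that("distribution features use the population standard deviation", {
  f <- stat_features(c(0.2, 0.8, 0.5))
  expect_equal(unname(f["n_min"]), 0.2)
  expect_equal(unname(f["n_max"]), 0.8)
  expect_equal(unname(f["n_std"]), sqrt(0.06), tolerance = 1e-12)
  expect_equal(unname(stat_features(rep(0.4, 5))), c(0.4, 0.4, 0))
  withmask <- stat_features(c(0.2, NA, 0.6))
  expect_equal(unname(withmask["n_max"]), 0.6)
  expect_error(stat_features(c(NA, NA, 0.1)), "2 unmasked")
})

test_that("growing season length counts threshold exceedances per year", {
  pulse <- rep(0, 23); pulse[6:15] <- 1          # 10 composites above
  expect_equal(growing_season_length(pulse, threshold = 0.5), 10)
  expect_equal(growing_season_length(rep(0.1, 23), threshold = 0.5), 0)
  # dynamic-threshold count agrees with a direct brute-force count
  t <- 0:45
  x <- 0.5 + 0.3 * cos(2 * pi * t / 23)
  got <- growing_season_length(x)
  thr <- min(x) + 0.2 * (max(x) - min(x))
  expect_equal(got, sum(x >= thr) / 2)
  # constant series: full year by definition
  expect_equal(growing_season_length(rep(0.4, 23)), 23)
  expect_error(growing_season_length(1:10), "full year")
})

test_that("first harmonic recovers amplitude and phase of annual cosines", {
  t <- 0:22
  for (A in c(0.05, 0.3, 0.9)) for (phi in c(-2, -0.5, 0, 1, 3)) {
    s <- A * cos(2 * pi * t / 23 - phi)
    h <- first_harmonic(s)
    expect_equal(unname(h["n_amplitude"]), A, tolerance = 1e-6)
    expected_phi <- atan2(sin(phi), cos(phi))   # wrapped into (-pi, pi]
    expect_equal(unname(h["n_phase"]), expected_phi, tolerance = 1e-6)
  }
  # multi-year series and DC offsets leave the harmonic unchanged
  t2 <- 0:(3 * 23 - 1)
  s2 <- 0.6 + 0.25 * cos(2 * pi * t2 / 23 - 1.2)
  h2 <- first_harmonic(s2)
  expect_equal(unname(h2["n_amplitude"]), 0.25, tolerance = 1e-6)
  expect_equal(unname(h2["n_phase"]), 1.2, tolerance = 1e-6)
  expect_equal(unname(first_harmonic(rep(0.5, 23))["n_amplitude"]), 0)
  expect_error(first_harmonic(1:10), "full year")
})

test_that("per-pixel feature maps recover pixelwise phenology", {
  # two-pixel stack with known distinct sinusoids
  t <- 0:45
  s1 <- 0.5 + 0.30 * cos(2 * pi * t / 23 - 0.8)
  s2 <- 0.4 + 0.15 * cos(2 * pi * t / 23 - 2.1)
  stack <- lapply(seq_along(t), function(k)
    test_grid(matrix(c(s1[k], s2[k]), 1, 2)))
  f <- per_pixel_features(stack, window = 7, order = 3)
  # smoothing slightly attenuates a pure harmonic; allow a 2% band
  expect_equal(f$n_amplitude$values[1, ], c(0.30, 0.15), tolerance = 0.02)
  expect_equal(f$n_phase$values[1, ], c(0.8, 2.1), tolerance = 0.02)
  expect_equal(f$mndvi$values[1, 1], mean(s1), tolerance = 1e-12)
  expect_equal(f$sdndvi$values[1, 2], sqrt(mean((s2 - mean(s2))^2)),
               tolerance = 1e-12)

  # uniform stack -> constant maps; masked pixel -> masked everywhere
  stack2 <- lapply(seq_along(t), function(k) {
    m <- matrix(s1[k], 3, 3)
    if (k == 5) m[2, 2] <- NA
    test_grid(m)
  })
  f2 <- per_pixel_features(stack2)
  expect_true(is.na(f2$n_max$values[2, 2]))
  off_diag <- f2$n_max$values[-5]
  expect_equal(max(off_diag) - min(off_diag), 0, tolerance = 1e-12)
})
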