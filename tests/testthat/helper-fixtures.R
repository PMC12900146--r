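# Shared fixtures: all built in code at test time.

TEST_TRANSFORM <- c(500000, 4070000, 30, 30)
TEST_CRS <- "EPSG:32650"

test_grid <- function(values, transform = TEST_TRANSFORM, crs = TEST_CRS) {
  raster_grid(values, transform, crs)
}

random_grid <- function(nr, nc, seed = 1) {
  set.seed(seed)
  test_grid(matrix(rnorm(nr * nc), nr, nc))
}

# Independently coded single-level 2x2 orthonormal Haar butterfly, used as
# the oracle for the packaged transform on even-sized images.
oracle_haar_level <- function(x) {
  nr <- nrow(x) %/% 2L
  nc <- ncol(x) %/% 2L
  LL <- HL <- LH <- HH <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
    a <- blk[1, 1]; b <- blk[1, 2]; cc <- blk[2, 1]; d <- blk[2, 2]
    LL[i, j] <- (a + b + cc + d) / 2
    HL[i, j] <- (a - b + cc - d) / 2
    LH[i, j] <- (a + b - cc - d) / 2
    HH[i, j] <- (a - b - cc + d) / 2
  }
  list(LL = LL, HL = HL, LH = LH, HH = HH)
}

# Brute-force local energy with reflective padding (double loop oracle).
oracle_local_energy <- function(coeff, window) {
  h <- (window - 1) %/% 2
  nr <- nrow(coeff); nc <- ncol(coeff)
  refl <- function(k, n) {
    if (k < 1) k <- 2 - k
    if (k > n) k <- 2 * n - k
    k
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -h:h) for (dj in -h:h) {
      acc <- acc + coeff[refl(i + di, nr), refl(j + dj, nc)]^2
    }
    out[i, j] <- acc
  }
  out
}

# A small scene recipe keeping unit tests fast.
small_recipe <- function(seed = 7, ...) {
  scene_recipe(nrow = 24L, ncol = 24L, correlation_length = 4,
               covariate_correlation_length = 5,
               dates = c("2018", "2020", "2023"), baseline_date = "2020",
               years = 2L, n_samples = 60L, seed = seed, ...)
}
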