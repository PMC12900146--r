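# Covariate assembly, multi-temporal combination enumeration, recursive
# feature elimination and patch extraction for the patch-based regressor.
#
# A FeatureTable is a data.frame with columns sample_id, x, y, som followed
# by one column per named covariate, and a "feature_kinds" attribute mapping
# feature name -> category (climate, soil, vegetation, time-series NDVI,
# multitemporal multispectral, ...). Samples falling on masked cells are
# dropped during assembly with a reported count.

#' Binomial coefficient
#'
#' Number of ways to choose `k` of `n` elements; used to enumerate
#' multi-temporal image combinations, where `n` counts the non-baseline
#' dates and `k = m - 1` the dates joining the baseline.
#'
#' @param n,k Nonnegative integers with `k <= n`.
#' @return The binomial coefficient as a numeric scalar.
#' @examples
#' count_combinations(6, 1)  # 6
#' count_combinations(6, 3)  # 20
#' @export
count_combinations <- function(n, k) {
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n")
  choose(n, k)
}

#' Enumerate baseline-anchored date subsets
#'
#' All subsets of `m` acquisition dates that contain the baseline date, in
#' deterministic lexicographic order of the non-baseline members. The count
#' equals `count_combinations(length(dates) - 1, m - 1)`.
#'
#' @param dates Vector of acquisition-date labels.
#' @param baseline The baseline date (must be an element of `dates`).
#' @param m Subset size, `1 <= m <= length(dates)`.
#' @return List of date vectors, each containing the baseline.
#' @export
enumerate_mmi <- function(dates, baseline, m) {
  if (!baseline %in% dates) stop("baseline not among dates")
  if (m < 1 || m > length(dates)) stop("m out of range")
  others <- sort(dates[dates != baseline])
  if (m == 1) return(list(dates[dates == baseline][1]))
  combos <- utils::combn(others, m - 1, simplify = FALSE)
  lapply(combos, function(cc) sort(c(baseline, cc)))
}

feature_columns <- function(table) {
  setdiff(names(table), c("sample_id", "x", "y", "som"))
}

#' Map sample points to grid pixels
#'
#' A point falls in the pixel whose half-open extent contains it
#' (pixel-is-area convention).
#'
#' @param geom Grid geometry from [grid_geometry()].
#' @param x,y Point coordinates in map units.
#' @return Integer matrix with columns `row`, `col`; `NA` outside the
#'   extent.
#' @export
points_to_pixels <- function(geom, x, y) {
  j <- floor((x - geom$transform[1]) / geom$transform[3]) + 1
  i <- floor((geom$transform[2] - y) / geom$transform[4]) + 1
  i[i < 1 | i > geom$nrow] <- NA_integer_
  j[j < 1 | j > geom$ncol] <- NA_integer_
  cbind(row = as.integer(i), col = as.integer(j))
}

#' Assemble a feature table from covariate rasters and sample points
#'
#' Extracts every covariate at the pixel containing each sample point and
#' binds it to the SOM target. Samples falling outside the grid or on a
#' masked cell of any covariate are dropped (the count is reported via
#' `message`). Categorical covariates are one-hot encoded.
#'
#' @param samples Data frame with columns `sample_id` (optional), `x`, `y`,
#'   `som`.
#' @param rasters Named list of co-registered `RasterGrid` covariates.
#' @param kinds Named character vector mapping covariate name to category;
#'   missing names default to `"other"`.
#' @param categorical Character vector of covariate names to one-hot encode.
#' @return A FeatureTable data frame with attribute `feature_kinds`.
#' @export
assemble_feature_table <- function(samples, rasters, kinds = NULL,
                                   categorical = character()) {
  assert_coregistered(rasters)
  stopifnot(all(c("x", "y", "som") %in% names(samples)))
  if (is.null(samples$sample_id)) samples$sample_id <- seq_len(nrow(samples))
  if (is.null(names(rasters)) || any(names(rasters) == ""))
    stop("covariate rasters must be named")
  if (anyDuplicated(names(rasters))) stop("feature names must be unique")
  geom <- grid_geometry(rasters[[1]])
  px <- points_to_pixels(geom, samples$x, samples$y)
  keep <- !is.na(px[, 1]) & !is.na(px[, 2])
  vals <- lapply(rasters, function(g) {
    v <- rep(NA_real_, nrow(samples))
    v[keep] <- g$values[px[keep, , drop = FALSE]]
    v
  })
  tab <- data.frame(sample_id = samples$sample_id, x = samples$x,
                    y = samples$y, som = samples$som, vals,
                    check.names = FALSE)
  ok <- stats::complete.cases(tab)
  if (any(!ok))
    message(sum(!ok), " sample(s) dropped (outside extent or on masked cells)")
  tab <- tab[ok, , drop = FALSE]
  rownames(tab) <- NULL

  kind_of <- function(nm) {
    if (!is.null(kinds) && nm %in% names(kinds)) kinds[[nm]] else "other"
  }
  out_kinds <- character(0)
  for (nm in names(rasters)) {
    if (nm %in% categorical) {
      lev <- sort(unique(tab[[nm]]))
      for (lv in lev) {
        col <- paste0(nm, "_", lv)
        tab[[col]] <- as.numeric(tab[[nm]] == lv)
        out_kinds[col] <- kind_of(nm)
      }
      tab[[nm]] <- NULL
    } else {
      out_kinds[nm] <- kind_of(nm)
    }
  }
  attr(tab, "feature_kinds") <- out_kinds
  tab
}

rf_ranker_importance <- function(x, y, num.trees, max.depth, seed) {
  fit <- ranger::ranger(x = x, y = y, num.trees = num.trees,
                        max.depth = max.depth, importance = "impurity",
                        seed = seed, num.threads = 1)
  fit$variable.importance
}

#' Recursive feature elimination with a random-forest ranker
#'
#' Each repeat eliminates the least-important feature (by random-forest
#' impurity importance) one at a time until `n_keep` remain. Features are
#' then ranked by their selection frequency across repeats, with ties broken
#' by mean elimination order (later elimination = stronger feature). The
#' procedure is deterministic given `seed`.
#'
#' @param table A FeatureTable from [assemble_feature_table()], or any data
#'   frame with an `som` column plus feature columns.
#' @param n_keep Number of features to retain (default 24).
#' @param repeats Number of elimination repeats (default 10).
#' @param seed Integer seed.
#' @param num.trees,max.depth Ranker forest size (defaults 250 trees, depth
#'   6).
#' @return A data frame with `feature`, `frequency`, `mean_elimination_order`
#'   and `rank`, ordered by rank; the top `n_keep` form the selected set
#'   (attribute `selected`).
#' @export
rfe_select <- function(table, n_keep = 24L, repeats = 10L, seed = 1L,
                       num.trees = 250L, max.depth = 6L) {
  feats <- feature_columns(table)
  p <- length(feats)
  if (p < n_keep) stop("fewer features than n_keep")
  if (nrow(table) < 20) stop("too few samples for recursive elimination")
  y <- table$som
  n_steps <- p - n_keep
  sel_count <- stats::setNames(rep(0, p), feats)
  elim_order <- stats::setNames(rep(0, p), feats)
  for (r in seq_len(repeats)) {
    current <- feats
    step <- 0L
    while (length(current) > n_keep) {
      step <- step + 1L
      sub_seed <- (as.numeric(seed) * 1009 + r * 101 + step) %% 2147483629
      imp <- rf_ranker_importance(table[current], y, num.trees, max.depth,
                                  seed = as.integer(sub_seed))
      worst <- current[which.min(imp[current])]
      elim_order[worst] <- elim_order[worst] + step
      current <- setdiff(current, worst)
    }
    sel_count[current] <- sel_count[current] + 1
    elim_order[current] <- elim_order[current] + n_steps + 1L
  }
  res <- data.frame(feature = feats,
                    frequency = sel_count[feats] / repeats,
                    mean_elimination_order = elim_order[feats] / repeats,
                    row.names = NULL)
  res <- res[order(-res$frequency, -res$mean_elimination_order,
                   res$feature), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "selected") <- res$feature[seq_len(n_keep)]
  res
}

reflect_index <- function(idx, n) {
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  ifelse(idx > n, 2L * n - idx, idx)
}

#' Extract neighbourhood patches at sample points
#'
#' Cuts a `window` x `window` patch of every feature raster, centred on the
#' pixel containing each sample; windows crossing the grid edge are filled
#' by reflection. The patch centre always equals the point-extracted value.
#'
#' @param stack Named list of co-registered feature `RasterGrid`s (the
#'   channels).
#' @param samples Data frame with `x`, `y` columns (map units).
#' @param window Odd patch edge length (default 7).
#' @return An array `n_samples x window x window x channels` with
#'   `dimnames` carrying the channel names (class `PatchTensor`).
#' @export
extract_patches <- function(stack, samples, window = 7L) {
  assert_coregistered(stack)
  window <- as.integer(window)
  stopifnot(window %% 2L == 1L)
  h <- (window - 1L) %/% 2L
  geom <- grid_geometry(stack[[1]])
  px <- points_to_pixels(geom, samples$x, samples$y)
  if (anyNA(px)) stop("sample(s) outside the raster extent")
  n <- nrow(px); C <- length(stack)
  out <- array(NA_real_, c(n, window, window, C),
               dimnames = list(NULL, NULL, NULL, names(stack)))
  for (s in seq_len(n)) {
    ri <- reflect_index(px[s, 1] + (-h:h), geom$nrow)
    ci <- reflect_index(px[s, 2] + (-h:h), geom$ncol)
    for (k in seq_len(C))
      out[s, , , k] <- stack[[k]]$values[ri, ci]
  }
  class(out) <- c("PatchTensor", class(out))
  out
}

#' Fit standardization statistics on training data
#'
#' @param x A FeatureTable/data frame of features, a numeric matrix, or a
#'   `PatchTensor` (statistics per channel).
#' @param columns Feature columns to use when `x` is a FeatureTable
#'   (defaults to all feature columns).
#' @return A list with `mean`, `sd` and `zero_variance` flags.
#' @export
standardize_fit <- function(x, columns = NULL) {
  if (inherits(x, "PatchTensor")) {
    m <- apply(x, 4, mean)
    s <- apply(x, 4, stats::sd)
  } else {
    if (is.data.frame(x)) {
      if (is.null(columns)) columns <- feature_columns(x)
      x <- as.matrix(x[columns])
    }
    m <- colMeans(x)
    s <- apply(x, 2, stats::sd)
  }
  zv <- s == 0 | !is.finite(s)
  if (any(zv)) warning("zero-variance feature(s): ",
                       paste(names(m)[zv], collapse = ", "))
  s[zv] <- 1
  list(mean = m, sd = s, zero_variance = zv)
}

#' Apply (or invert) a standardization
#'
#' Z-scores features or patch channels with training-fold statistics;
#' `invert = TRUE` undoes the transform (round trip is the identity).
#'
#' @param x Same types as [standardize_fit()].
#' @param stats Statistics from [standardize_fit()].
#' @param invert Undo instead of apply.
#' @param columns Feature columns when `x` is a FeatureTable.
#' @return `x` with standardized values, same type.
#' @export
standardize_apply <- function(x, stats, invert = FALSE, columns = NULL) {
  if (inherits(x, "PatchTensor")) {
    for (k in seq_len(dim(x)[4])) {
      x[, , , k] <- if (invert) x[, , , k] * stats$sd[k] + stats$mean[k]
      else (x[, , , k] - stats$mean[k]) / stats$sd[k]
    }
    return(x)
  }
  is_df <- is.data.frame(x)
  if (is_df) {
    if (is.null(columns)) columns <- feature_columns(x)
    m <- as.matrix(x[columns])
  } else m <- x
  m <- if (invert) sweep(sweep(m, 2, stats$sd, "*"), 2, stats$mean, "+")
  else sweep(sweep(m, 2, stats$mean, "-"), 2, stats$sd, "/")
  if (is_df) {
    x[columns] <- m
    x
  } else m
}
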