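# Shallow convolutional regressor for 7x7 covariate patches.
#
# Architecture: conv 3x3 x32 (ReLU, valid) -> maxpool 2x2 -> conv 2x2 x48
# (ReLU) -> dropout 0.2 -> conv 2x2 x24 (ReLU) -> conv 2x2 x12 (ReLU) ->
# dropout 0.2 -> flatten -> dense 80 (ReLU) -> dropout 0.1 -> dense 15
# (ReLU) -> dense 1 (linear). The 2x2 convolutions keep the 2x2 spatial
# extent via bottom/right zero padding so the layer sequence is well-formed
# on a 7x7 input. Training minimizes mean squared error with Adam; dropout
# is active only during training; the target is z-scored internally and
# predictions are mapped back to g/kg.
#
# Implemented directly with matrix operations (im2col convolutions and
# hand-written backpropagation); every stochastic step (weight
# initialization, batching, dropout, validation split) is seeded.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' CNN model specification
#'
#' Fixed shallow architecture for 7x7 neighbourhood patches (see the package
#' vignette); the number of input channels adapts to the supplied patches.
#'
#' @param window Patch edge length the network accepts (default 7).
#' @param conv_filters Filters of the four convolution layers.
#' @param dense_units Units of the two hidden dense layers.
#' @param dropout Dropout rates after conv2, conv4 and dense1.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(window = 7L, conv_filters = c(32L, 48L, 24L, 12L),
                     dense_units = c(80L, 15L), dropout = c(0.2, 0.2, 0.1)) {
  structure(list(window = as.integer(window),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 dropout = as.numeric(dropout)),
            class = "cnn_spec")
}

# --- low-level layers ------------------------------------------------------

conv_im2col <- function(X, k, pad_same) {
  d <- dim(X); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (pad_same) {
    Xp <- array(0, c(N, H + k - 1L, W + k - 1L, C))
    Xp[, seq_len(H), seq_len(W), ] <- X
    X <- Xp; H_out <- H; W_out <- W
  } else {
    H_out <- H - k + 1L; W_out <- W - k + 1L
  }
  cols <- matrix(0, N * H_out * W_out, k * k * C)
  blk <- 0L
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    sl <- X[, di + seq_len(H_out), dj + seq_len(W_out), , drop = FALSE]
    cols[, blk + seq_len(C)] <- matrix(sl, N * H_out * W_out, C)
    blk <- blk + C
  }
  list(cols = cols, H_out = H_out, W_out = W_out, N = N, C = C,
       H_in = if (pad_same) dim(X)[2] else H,
       W_in = if (pad_same) dim(X)[3] else W, pad_same = pad_same, k = k)
}

conv_forward <- function(X, W, b, pad_same = FALSE) {
  k <- dim(W)[1]; K <- dim(W)[4]
  ic <- conv_im2col(X, k, pad_same)
  Wmat <- matrix(W, k * k * dim(W)[3], K)
  out_mat <- ic$cols %*% Wmat
  out_mat <- sweep(out_mat, 2, b, "+")
  out <- array(out_mat, c(ic$N, ic$H_out, ic$W_out, K))
  list(out = out, cache = list(ic = ic, W = W, X_dim = dim(X)))
}

conv_backward <- function(dOut, cache) {
  ic <- cache$ic; W <- cache$W
  k <- dim(W)[1]; C <- dim(W)[3]; K <- dim(W)[4]
  dOut_mat <- matrix(dOut, ic$N * ic$H_out * ic$W_out, K)
  Wmat <- matrix(W, k * k * C, K)
  dW <- array(crossprod(ic$cols, dOut_mat), dim(W))
  db <- colSums(dOut_mat)
  dcols <- dOut_mat %*% t(Wmat)
  dXp <- array(0, c(ic$N, ic$H_in, ic$W_in, C))
  blk <- 0L
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    dXp[, di + seq_len(ic$H_out), dj + seq_len(ic$W_out), ] <-
      dXp[, di + seq_len(ic$H_out), dj + seq_len(ic$W_out), , drop = FALSE] +
      array(dcols[, blk + seq_len(C)], c(ic$N, ic$H_out, ic$W_out, C))
    blk <- blk + C
  }
  if (ic$pad_same) {
    dX <- dXp[, seq_len(cache$X_dim[2]), seq_len(cache$X_dim[3]), ,
              drop = FALSE]
  } else dX <- dXp
  list(dX = dX, dW = dW, db = db)
}

maxpool_forward <- function(X) {
  d <- dim(X); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ri <- seq_len(2L * Ho); ci <- seq_len(2L * Wo)
  cand <- list(X[, ri[ri %% 2L == 1L], ci[ci %% 2L == 1L], , drop = FALSE],
               X[, ri[ri %% 2L == 1L], ci[ci %% 2L == 0L], , drop = FALSE],
               X[, ri[ri %% 2L == 0L], ci[ci %% 2L == 1L], , drop = FALSE],
               X[, ri[ri %% 2L == 0L], ci[ci %% 2L == 0L], , drop = FALSE])
  out <- cand[[1]]; which_max <- array(1L, dim(out))
  for (q in 2:4) {
    better <- cand[[q]] > out
    out[better] <- cand[[q]][better]
    which_max[better] <- q
  }
  list(out = out, cache = list(which_max = which_max, in_dim = d,
                               Ho = Ho, Wo = Wo))
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$in_dim
  dX <- array(0, d)
  Ho <- cache$Ho; Wo <- cache$Wo
  off <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  for (q in 1:4) {
    sel <- cache$which_max == q
    grad <- dOut * sel
    rows <- 2L * seq_len(Ho) - 2L + off[[q]][1]
    cols <- 2L * seq_len(Wo) - 2L + off[[q]][2]
    dX[, rows, cols, ] <- dX[, rows, cols, , drop = FALSE] + grad
  }
  dX
}

dropout_mask <- function(dim, rate) {
  array(stats::rbinom(prod(dim), 1L, 1 - rate) / (1 - rate), dim)
}

cnn_init_weights <- function(spec, C, seed) {
  he <- function(fan_in, dims) array(stats::rnorm(prod(dims),
                                                  sd = sqrt(2 / fan_in)), dims)
  f <- spec$conv_filters
  with_seed(seed, {
    list(conv1_W = he(9 * C, c(3, 3, C, f[1])), conv1_b = rep(0, f[1]),
         conv2_W = he(4 * f[1], c(2, 2, f[1], f[2])), conv2_b = rep(0, f[2]),
         conv3_W = he(4 * f[2], c(2, 2, f[2], f[3])), conv3_b = rep(0, f[3]),
         conv4_W = he(4 * f[3], c(2, 2, f[3], f[4])), conv4_b = rep(0, f[4]),
         dense1_W = he(4 * f[4], c(4 * f[4], spec$dense_units[1])),
         dense1_b = rep(0, spec$dense_units[1]),
         dense2_W = he(spec$dense_units[1],
                       c(spec$dense_units[1], spec$dense_units[2])),
         dense2_b = rep(0, spec$dense_units[2]),
         out_W = he(spec$dense_units[2], c(spec$dense_units[2], 1)),
         out_b = 0)
  })
}

cnn_forward <- function(W, X, spec, training = FALSE) {
  cache <- list()
  c1 <- conv_forward(X, W$conv1_W, W$conv1_b, pad_same = FALSE)
  a1 <- pmax(c1$out, 0); cache$c1 <- c1$cache; cache$a1 <- a1
  p1 <- maxpool_forward(a1); cache$p1 <- p1$cache
  c2 <- conv_forward(p1$out, W$conv2_W, W$conv2_b, pad_same = TRUE)
  a2 <- pmax(c2$out, 0); cache$c2 <- c2$cache; cache$a2 <- a2
  if (training) {
    m2 <- dropout_mask(dim(a2), spec$dropout[1]); a2 <- a2 * m2
    cache$m2 <- m2
  }
  c3 <- conv_forward(a2, W$conv3_W, W$conv3_b, pad_same = TRUE)
  a3 <- pmax(c3$out, 0); cache$c3 <- c3$cache; cache$a3 <- a3
  c4 <- conv_forward(a3, W$conv4_W, W$conv4_b, pad_same = TRUE)
  a4 <- pmax(c4$out, 0); cache$c4 <- c4$cache; cache$a4 <- a4
  if (training) {
    m4 <- dropout_mask(dim(a4), spec$dropout[2]); a4 <- a4 * m4
    cache$m4 <- m4
  }
  N <- dim(a4)[1]
  flat <- matrix(aperm(a4, c(1, 4, 3, 2)), N)      # deterministic unravel
  cache$flat_dim <- dim(a4)
  z1 <- flat %*% W$dense1_W
  z1 <- sweep(z1, 2, W$dense1_b, "+")
  h1 <- pmax(z1, 0); cache$flat <- flat; cache$h1 <- h1
  if (training) {
    md <- matrix(stats::rbinom(length(h1), 1L, 1 - spec$dropout[3]) /
                   (1 - spec$dropout[3]), nrow(h1))
    h1 <- h1 * md; cache$md <- md
  }
  z2 <- h1 %*% W$dense2_W
  z2 <- sweep(z2, 2, W$dense2_b, "+")
  h2 <- pmax(z2, 0); cache$h1d <- h1; cache$h2 <- h2
  yhat <- as.vector(h2 %*% W$out_W + W$out_b)
  cache$h2v <- h2
  list(yhat = yhat, cache = cache)
}

cnn_backward <- function(W, X, yhat, y, cache, spec) {
  N <- length(y)
  g <- list()
  dy <- matrix(2 * (yhat - y) / N, ncol = 1)
  g$out_W <- crossprod(cache$h2v, dy)
  g$out_b <- sum(dy)
  dh2 <- dy %*% t(W$out_W)
  dz2 <- dh2 * (cache$h2 > 0)
  g$dense2_W <- crossprod(cache$h1d, dz2)
  g$dense2_b <- colSums(dz2)
  dh1 <- dz2 %*% t(W$dense2_W)
  if (!is.null(cache$md)) dh1 <- dh1 * cache$md
  dz1 <- dh1 * (cache$h1 > 0)
  g$dense1_W <- crossprod(cache$flat, dz1)
  g$dense1_b <- colSums(dz1)
  dflat <- dz1 %*% t(W$dense1_W)
  da4 <- aperm(array(dflat, cache$flat_dim[c(1, 4, 3, 2)]), c(1, 4, 3, 2))
  if (!is.null(cache$m4)) da4 <- da4 * cache$m4
  dc4 <- da4 * (cache$a4 > 0)
  b4 <- conv_backward(dc4, cache$c4)
  g$conv4_W <- b4$dW; g$conv4_b <- b4$db
  dc3 <- b4$dX * (cache$a3 > 0)
  b3 <- conv_backward(dc3, cache$c3)
  g$conv3_W <- b3$dW; g$conv3_b <- b3$db
  da2 <- b3$dX
  if (!is.null(cache$m2)) da2 <- da2 * cache$m2
  dc2 <- da2 * (cache$a2 > 0)
  b2 <- conv_backward(dc2, cache$c2)
  g$conv2_W <- b2$dW; g$conv2_b <- b2$db
  dp1 <- maxpool_backward(b2$dX, cache$p1)
  dc1 <- dp1 * (cache$a1 > 0)
  b1 <- conv_backward(dc1, cache$c1)
  g$conv1_W <- b1$dW; g$conv1_b <- b1$db
  g
}

adam_step <- function(W, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(g)) {
    wn <- nm
    state$m[[wn]] <- beta1 * state$m[[wn]] + (1 - beta1) * g[[nm]]
    state$v[[wn]] <- beta2 * state$v[[wn]] + (1 - beta2) * g[[nm]]^2
    W[[wn]] <- W[[wn]] - lr * (state$m[[wn]] / corr1) /
      (sqrt(state$v[[wn]] / corr2) + eps)
  }
  list(W = W, state = state)
}

#' Train the shallow CNN SOM regressor
#'
#' Minimizes mean squared error with Adam on z-scored targets; dropout is
#' active only during training, and early stopping monitors a held-out
#' split of the training data, restoring the best weights. Fully seeded and
#' deterministic.
#'
#' @param spec A [cnn_spec()].
#' @param patches `PatchTensor` (n x window x window x channels), already
#'   standardized per channel.
#' @param y Numeric target (g/kg).
#' @param seed Integer seed.
#' @param epochs Maximum epochs (default 300).
#' @param batch Minibatch size (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience Early-stopping patience in epochs (default 30).
#' @param val_fraction Fraction of the training set held out for early
#'   stopping (default 0.1).
#' @return A fitted model of class `som_cnn`.
#' @export
train_cnn <- function(spec = cnn_spec(), patches, y, seed = 1L,
                      epochs = 300L, batch = 16L, lr = 1e-3,
                      patience = 30L, val_fraction = 0.1) {
  d <- dim(patches)
  if (length(d) != 4 || d[2] != spec$window || d[3] != spec$window)
    stop(sprintf("patches must be n x %d x %d x C", spec$window, spec$window))
  if (d[4] < 1) stop("at least one channel required")
  N <- d[1]
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd
  channels <- dimnames(patches)[[4]]

  W <- cnn_init_weights(spec, d[4], seed)
  state <- list(t = 0L,
                m = lapply(W, function(w) w * 0),
                v = lapply(W, function(w) w * 0))

  n_val <- max(1L, round(val_fraction * N))
  idx <- with_seed(seed + 1L, sample.int(N))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- if (N - n_val >= batch || N <= batch) idx[-seq_len(n_val)] else idx
  if (length(tr_idx) == 0) tr_idx <- idx
  Xtr <- patches[tr_idx, , , , drop = FALSE]
  Xval <- patches[val_idx, , , , drop = FALSE]
  ytr <- ys[tr_idx]; yval <- ys[val_idx]
  n_tr <- length(tr_idx)

  best_val <- Inf; best_W <- W; wait <- 0L
  with_seed(seed + 2L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      for (start in seq(1L, n_tr, by = batch)) {
        sel <- ord[start:min(start + batch - 1L, n_tr)]
        Xb <- Xtr[sel, , , , drop = FALSE]
        fw <- cnn_forward(W, Xb, spec, training = TRUE)
        g <- cnn_backward(W, Xb, fw$yhat, ytr[sel], fw$cache, spec)
        upd <- adam_step(W, g, state, lr)
        W <- upd$W; state <- upd$state
      }
      val_pred <- cnn_forward(W, Xval, spec, training = FALSE)$yhat
      val_mse <- mean((val_pred - yval)^2)
      if (val_mse < best_val - 1e-7) {
        best_val <- val_mse; best_W <- W; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  structure(list(W = best_W, spec = spec, channels = channels,
                 y_mean = y_mean, y_sd = y_sd, seed = seed,
                 val_mse = best_val),
            class = "som_cnn")
}

#' @export
predict.som_cnn <- function(object, newdata, ...) {
  if (length(dim(newdata)) != 4)
    stop("newdata must be an n x window x window x C patch array")
  yhat <- cnn_forward(object$W, newdata, object$spec, training = FALSE)$yhat
  yhat * object$y_sd + object$y_mean
}
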