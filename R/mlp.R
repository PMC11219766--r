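# Minimal dense feed-forward network for binary classification: ReLU hidden
# layers, sigmoid output, binary cross-entropy loss, ADAM optimiser.
# Deliberately desk-scale: plain matrix algebra, full reproducibility from a
# single seed.

#' Initialise a multilayer perceptron
#'
#' He-scaled Gaussian weight initialisation, zero biases; deterministic for a
#' fixed seed.
#' @param sizes integer vector of layer widths, input first, 1 output last
#'   (e.g. `c(377, 32, 16, 1)`).
#' @param seed RNG seed for the initial weights.
#' @return object of class `fb_mlp`.
#' @export
mlp_new <- function(sizes, seed = 1L) {
  stopifnot(length(sizes) >= 2, sizes[length(sizes)] == 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(sizes = sizes, W = W, b = b, seed = seed, trained = FALSE),
            class = "fb_mlp")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  A
}

#' Predict with a multilayer perceptron
#' @param net an `fb_mlp`.
#' @param X numeric matrix (rows = samples) or a single feature vector.
#' @return numeric vector of sigmoid outputs in (0, 1).
#' @export
mlp_predict <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  as.numeric(.mlp_forward(net, X)[[length(net$W) + 1L]])
}

#' Train a multilayer perceptron
#'
#' Mini-batch backpropagation with binary cross-entropy loss and ADAM
#' updates. Shuffling and updates are deterministic for a fixed seed.
#' @param net an [mlp_new] result.
#' @param X training matrix (rows = samples).
#' @param y 0/1 labels.
#' @param epochs number of passes over the data.
#' @param batch mini-batch size.
#' @param lr ADAM step size.
#' @param beta1,beta2,eps ADAM moment parameters.
#' @param seed RNG seed for the epoch shuffles.
#' @return trained `fb_mlp`; `$loss` holds the per-epoch mean BCE curve.
#' @export
mlp_train <- function(net, X, y, epochs = 500L, batch = 50L, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1L) {
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  n <- nrow(X); t <- 0L
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      A <- .mlp_forward(net, Xb)
      p <- pmin(pmax(A[[L + 1]], 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss - mean(yb * log(p) + (1 - yb) * log(1 - p))
      nb <- nb + 1L
      # output delta for sigmoid + BCE is (p - y)
      delta <- (A[[L + 1]] - yb) / length(idx)
      t <- t + 1L
      for (l in L:1) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(net$W[[l]])) * (A[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        net$W[[l]] <- net$W[[l]] - lr * (mW[[l]] / (1 - beta1^t)) /
          (sqrt(vW[[l]] / (1 - beta2^t)) + eps)
        net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / (1 - beta1^t)) /
          (sqrt(vb[[l]] / (1 - beta2^t)) + eps)
      }
    }
    loss[ep] <- ep_loss / nb
  }
  net$loss <- loss
  net$trained <- TRUE
  net
}

#' Serialise a network to portable JSON
#'
#' Plain-text format: layer sizes, seeds and weight matrices as nested JSON
#' arrays, readable anywhere.
#' @param net an `fb_mlp`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
mlp_save <- function(net, path) {
  obj <- list(sizes = net$sizes, seed = net$seed, trained = net$trained,
              W = lapply(net$W, function(w) unclass(w)),
              b = net$b)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Load a network saved by [mlp_save]
#' @param path JSON file.
#' @return an `fb_mlp`.
#' @export
mlp_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sizes = as.integer(obj$sizes), seed = obj$seed,
                 trained = isTRUE(obj$trained[1]),
                 W = lapply(obj$W, function(w) matrix(as.numeric(w), nrow = nrow(w))),
                 b = lapply(obj$b, as.numeric)),
            class = "fb_mlp")
}
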