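# Multi-layer perceptron for binary classification: ReLU hidden layers,
# sigmoid output, cross-entropy loss with L2 penalty. Trained either with
# L-BFGS (full-batch, via optim) or minibatch Adam with early stopping on a
# held-out validation fraction. Written in plain R + BLAS because the image
# ships no multi-hidden-layer MLP; dense matrix products dominate the cost.

mlp_layer_dims <- function(d, hidden) {
  sizes <- c(d, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L),
         function(i) c(inp = sizes[i], out = sizes[i + 1L]))
}

mlp_init <- function(d, hidden, seed) {
  rng <- local_rng(seed)
  dims <- mlp_layer_dims(d, hidden)
  lapply(dims, function(dm) {
    limit <- sqrt(6 / (dm[["inp"]] + dm[["out"]]))
    W <- matrix(rng$draw(function()
      stats::runif(dm[["inp"]] * dm[["out"]], -limit, limit)),
      dm[["inp"]], dm[["out"]])
    list(W = W, b = numeric(dm[["out"]]))
  })
}

mlp_pack <- function(layers) {
  unlist(lapply(layers, function(l) c(as.vector(l$W), l$b)))
}

mlp_unpack <- function(par, dims) {
  pos <- 0L
  lapply(dims, function(dm) {
    nw <- dm[["inp"]] * dm[["out"]]
    W <- matrix(par[pos + seq_len(nw)], dm[["inp"]], dm[["out"]])
    b <- par[pos + nw + seq_len(dm[["out"]])]
    pos <<- pos + nw + dm[["out"]]
    list(W = W, b = b)
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers))
  A <- X
  for (i in seq_along(layers)) {
    Z <- sweep(A %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    A <- if (i < length(layers)) pmax(Z, 0) else 1 / (1 + exp(-Z))
    acts[[i]] <- A
  }
  acts
}

# Loss and gradient in one pass; gradient returned packed.
mlp_loss_grad <- function(par, dims, X, y, alpha) {
  layers <- mlp_unpack(par, dims)
  n <- nrow(X)
  acts <- mlp_forward(layers, X)
  p <- pmin(pmax(acts[[length(acts)]][, 1], 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p)) +
    alpha / (2 * n) * sum(vapply(layers, function(l) sum(l$W^2), 0))
  grads <- vector("list", length(layers))
  delta <- matrix((p - y) / n, ncol = 1)
  for (i in rev(seq_along(layers))) {
    A_prev <- if (i == 1) X else acts[[i - 1]]
    grads[[i]] <- list(W = crossprod(A_prev, delta) + alpha / n * layers[[i]]$W,
                       b = colSums(delta))
    if (i > 1) {
      delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i - 1]] > 0)
    }
  }
  list(loss = loss, grad = mlp_pack(grads))
}

#' Fit a multi-layer perceptron classifier
#'
#' @param X numeric feature matrix (standardized)
#' @param y 0/1 labels
#' @param hidden integer vector of hidden-layer sizes
#' @param solver "lbfgs" (full batch) or "adam" (minibatch, optional early
#'   stopping on a validation fraction)
#' @param alpha L2 penalty (default 1e-4)
#' @param maxit iteration cap: L-BFGS iterations or Adam epochs
#' @param seed RNG seed for initialisation, shuffling and validation split
#' @param early_stopping stop when validation loss stops improving (adam only)
#' @param validation_fraction fraction held out for early stopping
#' @param patience epochs without improvement tolerated before stopping
#' @param batch_size Adam minibatch size
#' @param learning_rate Adam step size
#' @return an \code{lrr_mlp} model
#' @keywords internal
mlp_fit <- function(X, y, hidden, solver = c("lbfgs", "adam"), alpha = 1e-4,
                    maxit = 100L, seed = 1L, early_stopping = FALSE,
                    validation_fraction = 0.2, patience = 10L,
                    batch_size = 200L, learning_rate = 1e-3) {
  solver <- match.arg(solver)
  X <- as.matrix(X); y <- as.numeric(y)
  dims <- mlp_layer_dims(ncol(X), hidden)
  layers0 <- mlp_init(ncol(X), hidden, seed)
  par <- mlp_pack(layers0)
  if (solver == "lbfgs") {
    env <- new.env()
    fn <- function(p) {
      env$last <- mlp_loss_grad(p, dims, X, y, alpha)
      env$last_par <- p
      env$last$loss
    }
    gr <- function(p) {
      if (!identical(p, env$last_par)) fn(p)
      env$last$grad
    }
    fit <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e7))
    par <- fit$par
  } else {
    rng <- local_rng(seed + 1L)
    n <- nrow(X)
    if (early_stopping) {
      val_idx <- rng$draw(function()
        sample.int(n, max(2L, round(validation_fraction * n))))
      Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]
      Xt <- X[-val_idx, , drop = FALSE]; yt <- y[-val_idx]
    } else {
      Xt <- X; yt <- y
    }
    m <- numeric(length(par)); v <- numeric(length(par))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
    best_val <- Inf; best_par <- par; stale <- 0L
    for (epoch in seq_len(maxit)) {
      ord <- rng$draw(function() sample.int(nrow(Xt)))
      for (start in seq(1, nrow(Xt), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, nrow(Xt))]
        lg <- mlp_loss_grad(par, dims, Xt[idx, , drop = FALSE], yt[idx], alpha)
        t <- t + 1
        m <- b1 * m + (1 - b1) * lg$grad
        v <- b2 * v + (1 - b2) * lg$grad^2
        par <- par - learning_rate * (m / (1 - b1^t)) /
          (sqrt(v / (1 - b2^t)) + eps)
      }
      if (early_stopping) {
        vl <- mlp_loss_grad(par, dims, Xv, yv, alpha)$loss
        if (vl < best_val - 1e-4) {
          best_val <- vl; best_par <- par; stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= patience) break
        }
      }
    }
    if (early_stopping) par <- best_par
  }
  structure(list(dims = dims, par = par, hidden = hidden, solver = solver),
            class = "lrr_mlp")
}

#' @keywords internal
mlp_predict_prob <- function(model, X) {
  X <- as.matrix(X)
  layers <- mlp_unpack(model$par, model$dims)
  mlp_forward(layers, X)[[length(layers)]][, 1]
}
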