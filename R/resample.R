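# SMOTE + Tomek-link resampling for heavy class imbalance, written here
# because the image has no R equivalent of combined over/under-samplers.
# SMOTE interpolates synthetic minority samples between a minority point and
# one of its k nearest minority neighbours until the classes balance; the
# Tomek pass then removes both members of every cross-class mutual
# nearest-neighbour pair to clean the boundary.

# Chunked nearest-neighbour index (squared Euclidean) to keep memory flat.
nn1_index <- function(X, chunk = 512L) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  out <- integer(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * X[idx, , drop = FALSE] %*% t(X)
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' SMOTE + Tomek-link resampling
#'
#' @param X standardized feature matrix
#' @param y 0/1 labels (1 = minority assumed; checked)
#' @param k neighbours used for SMOTE interpolation (default 5)
#' @param seed RNG seed
#' @return list(X, y) with synthetic minority samples appended and
#'   Tomek-linked pairs removed
#' @keywords internal
smote_tomek <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  minority <- if (n1 <= n0) 1L else 0L
  mi <- which(y == minority)
  n_new <- abs(n0 - n1)
  rng <- local_rng(seed)
  if (n_new > 0 && length(mi) >= 2) {
    Xm <- X[mi, , drop = FALSE]
    k_eff <- min(k, length(mi) - 1L)
    d2 <- as.matrix(stats::dist(Xm))^2
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k_eff)]))
    base <- rng$draw(function() sample.int(length(mi), n_new, replace = TRUE))
    pick <- rng$draw(function() sample.int(k_eff, n_new, replace = TRUE))
    u <- rng$runif(n_new)
    neigh <- nn[cbind(base, pick)]
    X_new <- Xm[base, , drop = FALSE] +
      u * (Xm[neigh, , drop = FALSE] - Xm[base, , drop = FALSE])
    X <- rbind(X, X_new)
    y <- c(y, rep(minority, n_new))
  }
  nn1 <- nn1_index(X)
  tomek <- which(nn1[nn1] == seq_along(nn1) & y != y[nn1])
  if (length(tomek)) {
    drop <- unique(c(tomek, nn1[tomek]))
    X <- X[-drop, , drop = FALSE]
    y <- y[-drop]
  }
  list(X = X, y = y)
}
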