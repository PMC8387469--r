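#' 2-D stochastic-neighbor (t-SNE) embedding of a distance matrix
#'
#' Exact t-distributed stochastic neighbor embedding for the small point sets
#' this package embeds (tens of brain regions).  Input similarities are
#' Gaussian kernels on the supplied distances with per-point bandwidths
#' calibrated to the target perplexity by bisection; the low-dimensional
#' kernel is the Student-t with one degree of freedom; the Kullback-Leibler
#' divergence is minimized by gradient descent with momentum and early
#' exaggeration.  Deterministic under a fixed seed.
#'
#' @param d a `dist` object or a symmetric distance matrix.
#' @param perplexity effective neighbor count (default `(n-1)/3`, capped to
#'   a valid value).
#' @param n_iter gradient-descent iterations (default 500).
#' @param learning_rate step size (default 50).
#' @param seed integer seed for the random initialization (default 1).
#' @return an n x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(d, perplexity = NULL, n_iter = 500,
                       learning_rate = 50, seed = 1) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 points to embed", call. = FALSE)
  perplexity <- perplexity %||% ((n - 1) / 3)
  perplexity <- max(1.01, min(perplexity, n - 1.01))
  target_h <- log(perplexity)

  D2 <- D^2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (it in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { hi <- beta; beta <- (lo + beta) / 2; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target_h) < 1e-7) break
      if (h > target_h) { lo <- beta; beta <- if (hi < 1e19) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + beta) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    momentum <- 0.5
    for (iter in seq_len(n_iter)) {
      ex <- if (iter <= 100) 4 else 1
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      G <- 4 * ((ex * P - Q) * num)
      grad <- (diag(rowSums(G)) - G) %*% Y
      if (iter == 20) momentum <- 0.8
      inc <- momentum * inc - learning_rate * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    colnames(Y) <- c("dim1", "dim2")
    Y
  })
}
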