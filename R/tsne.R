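#' t-SNE embedding of gaze-metric vectors
#'
#' Exact (non-approximated) t-distributed stochastic neighbor embedding for
#' the qualitative cluster plots of per-scene metric vectors. The exact
#' gradient is quadratic in the number of points, which is ample for the
#' per-subject use case (~138 scenes). Deterministic given the RNG state;
#' call `set.seed()` before embedding.
#'
#' @param x numeric matrix (points x features).
#' @param perplexity target perplexity; clamped to `(n - 1) / 3`.
#' @param n_iter gradient-descent iterations.
#' @param eta learning rate.
#' @return n x 2 matrix of embedding coordinates.
#' @export
embed_metrics <- function(x, perplexity = 30, n_iter = 500, eta = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5) stop("embedding needs at least 5 points", call. = FALSE)
  perplexity <- min(perplexity, (n - 1) / 3)

  P <- tsne_affinities(x, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  for (iter in seq_len(n_iter)) {
    exag <- if (iter <= 100) 4 else 1
    D2 <- as.matrix(stats::dist(Y))^2
    Wq <- 1 / (1 + D2); diag(Wq) <- 0
    Q <- pmax(Wq / sum(Wq), 1e-12)
    L <- (exag * P - Q) * Wq
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 250) momentum <- 0.8
  }
  Y
}

# binary-search per-point bandwidths to hit the target perplexity
tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  D2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}
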