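# Small exact t-SNE on a precomputed distance matrix.  Only meant for the
# handful of points this package embeds (a dozen model distributions), so no
# Barnes-Hut machinery: O(n^2) per iteration is plenty.

tsne_perplexity_p <- function(D, perplexity) {
  n <- nrow(D)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    d2 <- D[i, -i]^2
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:60) {
      w <- exp(-d2 * beta)
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 2; next }
      p <- w / sw
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-6) break
      if (H > logU) { lo <- beta; beta <- if (hi < 1e19) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of a distance matrix
#'
#' Exact (non-approximate) t-SNE with momentum gradient descent and early
#' exaggeration, seeded for reproducibility.
#'
#' @param D symmetric distance matrix
#' @param perplexity neighborhood size parameter
#' @param seed RNG seed for the initial layout
#' @param n_iter gradient iterations
#' @return n x 2 coordinate matrix
#' @export
tsne_embed <- function(D, perplexity = 5, seed = 1, n_iter = 500) {
  n <- nrow(D)
  if (perplexity >= n) perplexity <- max(2, n - 1)
  P <- tsne_perplexity_p(D, perplexity)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  V <- matrix(0, n, 2)
  eta <- 100; momentum <- 0.5
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100) 4 else 1
    sq <- as.matrix(stats::dist(Y))^2
    W <- 1 / (1 + sq); diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    G <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      coef <- 4 * (ex * P[i, ] - Q[i, ]) * W[i, ]
      G[i, ] <- colSums(coef * sweep(-Y, 2, -Y[i, ]))  # sum_j coef_ij (y_i - y_j)
    }
    if (iter == 250) momentum <- 0.8
    V <- momentum * V - eta * G
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
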