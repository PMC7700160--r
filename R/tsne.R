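## Exact (O(n^2)) t-SNE, sufficient for desk-scale cohorts (n up to ~1000).
## Follows the widely recommended settings for transcriptome maps:
## PCA initialization, early exaggeration, learning rate ~ n/12,
## perplexity bounded by the sample count.

tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_exact <- function(X, perplexity, n_iter = 400, seed = 1,
                       early_exaggeration = 12, exaggeration_iter = 100,
                       learning_rate = NULL) {
  n <- nrow(X)
  set.seed(seed)
  learning_rate <- learning_rate %||% max(n / 12, 50)
  ## input affinities on PCA-reduced data
  Xc <- scale(X, center = TRUE, scale = FALSE)
  npc <- min(50, n - 1, ncol(X))
  pc <- prcomp(Xc, rank. = npc)
  Z <- pc$x
  D2 <- as.matrix(dist(Z))^2
  P <- tsne_affinities(D2, perplexity)

  ## PCA initialization scaled to SD 1e-4 (plus a hair of jitter for exact ties)
  Y <- pc$x[, 1:2, drop = FALSE]
  Y <- Y / max(sd(Y[, 1]), 1e-12) * 1e-4 +
    matrix(rnorm(n * 2, sd = 1e-6), n, 2)

  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exaggeration_iter) P * early_exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8),
                  0.01)
    inc <- momentum * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 250) momentum <- 0.8
  }
  Y
}
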