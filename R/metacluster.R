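## Meta-clustering of tumor samples on matrisome expression: a 2-D embedding
## (t-SNE, or PCA for speed), Gaussian-mixture clustering with BIC model
## selection, and majority-vote promotion of sample labels to subtype labels.

#' Embed samples in two dimensions from matrisome expression
#'
#' Samples (columns of the expression matrix) are embedded with exact t-SNE
#' (PCA initialization, early exaggeration, learning rate `n/12`, perplexity
#' defaulting to `n/100` bounded to `[30, 500]` and always below the t-SNE
#' limit `(n - 1) / 3`) or, for `method = "pca"`, the first two principal
#' components. Deterministic under a fixed seed.
#'
#' @param expression gene x sample matrix (restricted to matrisome genes).
#' @param method `"tsne"` or `"pca"`.
#' @param perplexity t-SNE perplexity; default as above.
#' @param n_iter t-SNE iterations.
#' @param seed integer seed.
#' @return sample x 2 coordinate matrix.
#' @export
embed_samples <- function(expression, method = c("tsne", "pca"),
                          perplexity = NULL, n_iter = 400, seed = 1) {
  method <- match.arg(method)
  n <- ncol(expression)
  if (n < 3) stop_ctx("need at least 3 samples to embed (got %d)", n)
  X <- t(expression)
  if (method == "pca") {
    pc <- prcomp(X, rank. = 2)
    Y <- pc$x[, 1:2, drop = FALSE]
  } else {
    perplexity <- perplexity %||% min(max(n / 100, 30), 500)
    if (perplexity >= (n - 1) / 3)
      perplexity <- max((n - 1) / 3 - 1e-6, 2)
    if (n < 10)
      stop_ctx(paste0("t-SNE needs >= 10 samples for a usable perplexity ",
                      "(got %d); use method = 'pca' or add samples"), n)
    Y <- tsne_exact(X, perplexity = perplexity, n_iter = n_iter, seed = seed)
  }
  dimnames(Y) <- list(colnames(expression), c("dim1", "dim2"))
  Y
}

#' Cluster samples by Gaussian mixture or density
#'
#' `"gmm"` fits Gaussian mixture models with `mclust`, choosing the number of
#' components by BIC over `G` (default 1..10). `"density"` runs DBSCAN on the
#' embedding (noise points are attached to the nearest cluster).
#'
#' @param x sample x d matrix (an embedding, or e.g. principal components).
#' @param method `"gmm"` or `"density"`.
#' @param G candidate component counts for the GMM.
#' @param eps,min_pts DBSCAN parameters; `eps` defaults to the 90th
#'   percentile of each point's nearest-neighbour distance.
#' @param seed integer seed.
#' @return integer vector of cluster labels, named by sample.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_samples <- function(x, method = c("gmm", "density"), G = 1:10,
                            eps = NULL, min_pts = 5, seed = 1) {
  method <- match.arg(method)
  x <- as.matrix(x)
  set.seed(seed)
  if (method == "gmm") {
    fit <- Mclust(x, G = G, verbose = FALSE)
    if (is.null(fit)) stop_ctx("GMM fit failed on the embedding")
    labels <- as.integer(fit$classification)
  } else {
    labels <- dbscan_simple(x, eps = eps, min_pts = min_pts)
  }
  names(labels) <- rownames(x)
  labels
}

## minimal DBSCAN on a dense distance matrix; noise points (label 0) are
## reattached to the nearest labelled point so every sample gets a cluster
dbscan_simple <- function(x, eps = NULL, min_pts = 5) {
  D <- as.matrix(dist(x))
  n <- nrow(D)
  if (is.null(eps)) {
    nn <- apply(D + diag(Inf, n), 1, min)
    eps <- 3 * quantile(nn, 0.9, names = FALSE)
  }
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    nbr <- which(D[i, ] <= eps)
    if (length(nbr) < min_pts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbr, i)
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        nbj <- which(D[j, ] <= eps)
        if (length(nbj) >= min_pts) queue <- union(queue, nbj[labels[nbj] == 0L])
      }
    }
  }
  if (any(labels == 0L) && cl > 0) {
    for (i in which(labels == 0L)) {
      lab <- which(labels > 0L)
      labels[i] <- labels[lab[which.min(D[i, lab])]]
    }
  }
  if (cl == 0L) labels[] <- 1L
  labels
}

#' Promote sample cluster labels to subtype meta-cluster assignments
#'
#' Each subtype is assigned the majority cluster of its samples; ties break
#' to the lowest cluster index. The agreement score is the majority fraction.
#'
#' @param labels integer cluster labels named by sample (or aligned with
#'   `annotation$sample`).
#' @param annotation sample annotation with `sample` and `subtype`.
#' @param method provenance string stored on the result.
#' @return data frame of class `metacluster_assignment` with columns
#'   `subtype`, `cluster`, `agreement`.
#' @export
assign_subtype_clusters <- function(labels, annotation,
                                    method = "gmm") {
  if (!is.null(names(labels)))
    labels <- labels[annotation$sample]
  if (length(labels) != nrow(annotation) || anyNA(labels))
    stop_ctx("every sample in the annotation must carry a cluster label")
  subs <- sort(unique(annotation$subtype))
  res <- lapply(subs, function(s) {
    tab <- table(labels[annotation$subtype == s])
    best <- max(tab)
    winners <- as.integer(names(tab)[tab == best])
    data.frame(subtype = s, cluster = min(winners),
               agreement = best / sum(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "method") <- method
  class(out) <- c("metacluster_assignment", "data.frame")
  out
}

#' Agreement between two sample partitions (adjusted Rand index)
#'
#' @param a,b two label vectors over the same samples.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

## default meta-clustering route used by the pipeline: GMM with BIC on the
## top principal components of matrisome expression
metacluster_cohort <- function(expression, annotation, n_pcs = 5, G = 1:10,
                               seed = 1) {
  pc <- prcomp(t(expression), rank. = min(n_pcs, ncol(expression) - 1,
                                          nrow(expression)))
  labels <- cluster_samples(pc$x, method = "gmm", G = G, seed = seed)
  assign_subtype_clusters(labels, annotation, method = "gmm_pca")
}
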