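## Two-track landmark selection.
##
## Cluster track: per-subtype Mann-Whitney screen against the rest of the
## cohort (excluding same-meta-cluster subtypes, except for the designated
## no-exclusion cluster), intersected with subtype-associated coexpression
## modules and pruned by cross-validated adaptive LASSO.
##
## Subtype track: per-gene bimodal EM fit (diagnostic) and the
## mean-plus-2SD over-expression rule.
##
## Landmarks are the genes passing both tracks.

#' Benjamini-Hochberg step-up q-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; kept as a
#' named operation because every screen in the package reports q-values.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values, monotone in the p-values and bounded by 1.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_ctx("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Mann-Whitney over-expression screen for one subtype
#'
#' Every gene is tested (two-sided Mann-Whitney U; exact for small untied
#' samples, normal approximation with tie correction otherwise) between the
#' focal subtype and the rest of the cohort, after removing samples of other
#' subtypes sharing the focal subtype's meta-cluster. The removal is skipped
#' when the focal subtype sits in the designated no-exclusion cluster
#' (by default the largest cluster, whose members are heterogeneous).
#' P-values are BH-corrected across genes; the significant set requires
#' `q < alpha` and subtype median above the background median.
#'
#' @param expression gene x sample matrix.
#' @param annotation sample annotation (`sample`, `subtype`).
#' @param clusters a [assign_subtype_clusters()] result, or a named vector
#'   subtype -> cluster.
#' @param subtype focal subtype.
#' @param alpha FDR threshold (default 0.05).
#' @param no_exclusion cluster label(s) for which same-cluster removal is
#'   skipped; `NULL` picks the cluster with most subtypes.
#' @return data frame of class `screen_result`: `gene`, `U`, `p`, `q`,
#'   `direction`, `significant`; attributes record the excluded subtypes.
#' @export
mwu_screen <- function(expression, annotation, clusters, subtype,
                       alpha = 0.05, no_exclusion = NULL) {
  cl <- cluster_map(clusters)
  if (!subtype %in% names(cl)) stop_ctx("subtype '%s' not in cluster map",
                                        subtype)
  if (is.null(no_exclusion)) no_exclusion <- largest_cluster(cl)
  focal_cluster <- cl[[subtype]]
  excluded <- character(0)
  if (!focal_cluster %in% no_exclusion)
    excluded <- setdiff(names(cl)[cl == focal_cluster], subtype)
  in_sub <- annotation$subtype == subtype
  in_bg <- !in_sub & !(annotation$subtype %in% excluded)
  if (sum(in_sub) < 2) stop_ctx("subtype '%s' has fewer than 2 samples",
                                subtype)
  if (!any(in_bg))
    stop_ctx("background empty after excluding cluster '%s' subtypes",
             focal_cluster)
  sub_cols <- annotation$sample[in_sub]
  bg_cols <- annotation$sample[in_bg]
  res <- t(apply(expression, 1, function(v) {
    x <- v[sub_cols]; y <- v[bg_cols]
    wt <- suppressWarnings(wilcox.test(x, y))
    c(U = unname(wt$statistic), p = wt$p.value,
      direction = sign(median(x) - median(y)))
  }))
  out <- data.frame(gene = rownames(expression), U = res[, "U"],
                    p = res[, "p"], stringsAsFactors = FALSE)
  out$q <- benjamini_hochberg(out$p)
  out$direction <- res[, "direction"]
  out$significant <- out$q < alpha & out$direction > 0
  rownames(out) <- NULL
  attr(out, "subtype") <- subtype
  attr(out, "excluded_subtypes") <- excluded
  attr(out, "n_background") <- length(bg_cols)
  class(out) <- c("screen_result", "data.frame")
  out
}

cluster_map <- function(clusters) {
  if (is.data.frame(clusters)) setNames(clusters$cluster, clusters$subtype)
  else clusters
}

largest_cluster <- function(cl) {
  tab <- table(cl)
  names(tab)[which.max(tab)]
}

#' Weighted gene coexpression modules
#'
#' Signed weighted network analysis scoped to the supplied expression:
#' adjacency `((1 + cor) / 2)^power` with the soft threshold chosen as the
#' smallest power in 1..20 whose degree distribution reaches a scale-free
#' fit R^2 of 0.8 (falling back to 6), topological-overlap dissimilarity,
#' average-linkage clustering with the module count picked by mean
#' silhouette width, and minimum module size 5 (smaller modules are pooled
#' into module 0). Each module is summarized by its eigengene (first
#' principal component of the standardized module expression, oriented to
#' correlate positively with its genes on average).
#'
#' @param expression gene x sample matrix (matrisome genes, cluster-scoped
#'   samples).
#' @param power soft-threshold power; `NULL` selects it as above.
#' @param min_module_size smallest module kept.
#' @param max_modules upper bound for the silhouette search.
#' @return list of class `coexpression_modules`: `modules` (named integer
#'   vector; 0 = unassigned), `eigengenes` (sample x module matrix),
#'   `power`, `scale_free_r2`.
#' @export
coexpression_modules <- function(expression, power = NULL,
                                 min_module_size = 5, max_modules = 10) {
  if (nrow(expression) < 10) stop_ctx("need >= 10 genes for modules")
  if (ncol(expression) < 20) stop_ctx("need >= 20 samples for modules")
  sds <- apply(expression, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene(s) from the network",
                    sum(sds == 0)))
    expression <- expression[sds > 0, , drop = FALSE]
  }
  cc <- cor(t(expression))
  r2 <- NA_real_
  if (is.null(power)) {
    sel <- select_soft_power(cc)
    power <- sel$power
    r2 <- sel$r2
  }
  adj <- ((1 + cc) / 2)^power
  dissim <- 1 - tom_similarity(adj)
  hc <- hclust(as.dist(dissim), method = "average")
  g <- nrow(expression)
  ks <- 2:min(max_modules, g - 1)
  sil <- vapply(ks, function(k) {
    mean(cluster::silhouette(cutree(hc, k), dmatrix = dissim)[, 3])
  }, numeric(1))
  k <- ks[which.max(sil)]
  modules <- cutree(hc, k)
  tab <- table(modules)
  small <- as.integer(names(tab)[tab < min_module_size])
  modules[modules %in% small] <- 0L
  modules <- as.integer(factor(modules, levels = c(0, setdiff(sort(unique(modules)), 0)))) - 1L
  names(modules) <- rownames(expression)
  mods <- setdiff(sort(unique(modules)), 0L)
  eig <- sapply(mods, function(m) module_eigengene(
    expression[names(modules)[modules == m], , drop = FALSE]))
  if (length(mods) > 0) {
    eig <- matrix(eig, ncol = length(mods),
                  dimnames = list(colnames(expression), paste0("ME", mods)))
  } else eig <- matrix(0, ncol(expression), 0,
                       dimnames = list(colnames(expression), NULL))
  structure(list(modules = modules, eigengenes = eig, power = power,
                 scale_free_r2 = r2),
            class = "coexpression_modules")
}

## topological overlap matrix from an adjacency with unit diagonal
tom_similarity <- function(adj) {
  diag(adj) <- 0
  L <- adj %*% adj
  k <- rowSums(adj)
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (L + adj) / denom
  diag(tom) <- 1
  tom
}

select_soft_power <- function(cc, target_r2 = 0.8, powers = 1:20) {
  for (p in powers) {
    adj <- ((1 + cc) / 2)^p
    diag(adj) <- 0
    k <- rowSums(adj)
    r2 <- scale_free_r2(k)
    if (!is.na(r2) && r2 >= target_r2) return(list(power = p, r2 = r2))
  }
  list(power = 6, r2 = NA_real_)
}

scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  dk <- tapply(k, bins, mean)
  pk <- as.numeric(table(bins)) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  summary(fit)$r.squared
}

module_eigengene <- function(mat) {
  z <- t(scale(t(mat)))
  pc <- prcomp(t(z), rank. = 1)
  e <- pc$x[, 1]
  if (mean(cor(e, t(mat))) < 0) e <- -e
  e
}

#' Module-subtype association of eigengenes
#'
#' Point-biserial correlation of each module eigengene with the subtype
#' indicator, BH-corrected across modules.
#'
#' @param modules a [coexpression_modules()] object.
#' @param indicator logical/0-1 vector over the module samples (focal
#'   subtype membership).
#' @return data frame: `module`, `cor`, `p`, `q`.
#' @export
eigengene_association <- function(modules, indicator) {
  eig <- modules$eigengenes
  if (ncol(eig) == 0)
    return(data.frame(module = integer(0), cor = numeric(0),
                      p = numeric(0), q = numeric(0)))
  indicator <- as.numeric(indicator)
  if (length(unique(indicator)) < 2)
    stop_ctx("subtype indicator is constant over the module samples")
  res <- apply(eig, 2, function(e) {
    ct <- cor.test(e, indicator)
    c(cor = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(module = as.integer(sub("^ME", "", colnames(eig))),
                    cor = res["cor", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$q <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  out
}

#' Genes passing the cluster-level comparison
#'
#' Intersection of the Mann-Whitney-significant genes with genes belonging
#' to a coexpression module whose eigengene-subtype association passes
#' `q < alpha` (either sign: the orientation of an eigengene is arbitrary
#' for heterogeneous modules, and the over-expression direction is already
#' enforced by the screen).
#'
#' @param screen a [mwu_screen()] result.
#' @param modules a [coexpression_modules()] object over the same scope.
#' @param indicator subtype indicator over the module samples.
#' @param alpha association FDR threshold.
#' @return character vector of genes.
#' @export
cluster_level_genes <- function(screen, modules, indicator, alpha = 0.05) {
  sig <- screen$gene[screen$significant]
  if (length(sig) == 0) return(character(0))
  assoc <- eigengene_association(modules, indicator)
  keep_mods <- assoc$module[assoc$q < alpha]
  mod_genes <- names(modules$modules)[modules$modules %in% keep_mods]
  intersect(sig, mod_genes)
}

#' Adaptive LASSO pruning of candidate genes
#'
#' Two-stage logistic fit of subtype-vs-rest on the candidate genes: a ridge
#' pilot provides coefficients whose inverse absolute values become L1
#' penalty weights; the weighted LASSO path is cross-validated (deviance)
#' and genes with non-zero coefficients at `lambda.min` are returned.
#' A single candidate passes through untested.
#'
#' @param x sample x gene matrix of candidate genes (all cohort samples).
#' @param y binary outcome (focal-subtype membership).
#' @param folds CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return character vector of retained genes.
#' @export
adaptive_lasso_prune <- function(x, y, folds = 10, seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (ncol(x) == 0) return(character(0))
  if (ncol(x) == 1) return(colnames(x))
  if (min(table(y)) < folds)
    stop_ctx("both classes need at least %d members for %d-fold CV",
             folds, folds)
  keep <- apply(x, 2, sd) > 0
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) return(character(0))
  if (ncol(x) == 1) return(colnames(x))
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = length(y)))
  ridge <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                             foldid = foldid)
  beta <- as.numeric(coef(ridge, s = "lambda.min"))[-1]
  w <- 1 / pmax(abs(beta), 1e-8)
  w <- pmin(w, 1e8)
  alasso <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                              penalty.factor = w, foldid = foldid)
  b <- as.numeric(coef(alasso, s = "lambda.min"))[-1]
  colnames(x)[b != 0]
}

#' Two-component Gaussian mixture fit of one gene's expression
#'
#' Expectation-maximization from a deterministic quantile-based
#' initialization; components are ordered `mu1 <= mu2`, convergence is
#' declared when the log-likelihood gain drops below `tol` (default 1e-8)
#' or after `max_iter` iterations. The log-likelihood trace is retained so
#' monotonicity can be verified.
#'
#' @param x numeric vector (>= 10 non-missing values with variance > 0).
#' @param max_iter,tol EM controls.
#' @return object of class `bimodal_fit`: `mu1`, `mu2`, `sigma1`, `sigma2`,
#'   `lambda` (weight of the lower component), `loglik` (trace),
#'   `iterations`, `converged`, `cohort_mean`, `cohort_sd`,
#'   `separated` (`mu2 - mu1 >= 2` pooled SDs, a bimodality diagnostic).
#' @export
fit_bimodal <- function(x, max_iter = 1000, tol = 1e-8) {
  x <- x[!is.na(x)]
  if (length(x) < 10) stop_ctx("need >= 10 non-missing values (got %d)",
                               length(x))
  if (sd(x) == 0) stop_ctx("degenerate input: zero variance")
  mu <- unname(quantile(x, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * sd(x) / 2
  sg <- rep(max(sd(x) / 2, 1e-6), 2)
  lam <- 0.5
  floor_sg <- max(sd(x) * 1e-3, 1e-9)
  ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- lam * dnorm(x, mu[1], sg[1])
    d2 <- (1 - lam) * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll[it] <- sum(log(tot))
    g <- d1 / tot
    lam <- mean(g)
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    sg[1] <- max(sqrt(sum(g * (x - mu[1])^2) / sum(g)), floor_sg)
    sg[2] <- max(sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g)), floor_sg)
    if (it > 1 && ll[it] - ll[it - 1] < tol) { converged <- TRUE; break }
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); lam <- 1 - lam
  }
  pooled <- sqrt((sg[1]^2 + sg[2]^2) / 2)
  structure(list(mu1 = mu[1], mu2 = mu[2], sigma1 = sg[1], sigma2 = sg[2],
                 lambda = lam, loglik = ll, iterations = length(ll),
                 converged = converged, cohort_mean = mean(x),
                 cohort_sd = sd(x), separated = (mu[2] - mu[1]) >= 2 * pooled),
            class = "bimodal_fit")
}

#' Mean-plus-2SD subtype over-expression rule
#'
#' A gene is allocated to a subtype when the subtype's mean expression is
#' equal to or greater than the total-cohort mean plus two total-cohort SDs
#' of that gene. For a constant gene (cohort SD 0) the rule degenerates to a
#' strict comparison with the cohort mean and the decision is flagged.
#'
#' @param gene gene symbol.
#' @param subtype focal subtype.
#' @param expression gene x sample matrix.
#' @param annotation sample annotation.
#' @return logical; attributes `margin` (subtype mean minus threshold) and
#'   `degenerate`.
#' @export
two_sd_select <- function(gene, subtype, expression, annotation) {
  if (!gene %in% rownames(expression)) stop_ctx("gene '%s' not in matrix",
                                                gene)
  v <- expression[gene, ]
  m <- mean(v)
  s <- sd(v)
  sub_mean <- mean(v[annotation$sample[annotation$subtype == subtype]])
  if (s == 0) {
    out <- sub_mean > m
    attr(out, "margin") <- sub_mean - m
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- sub_mean >= m + 2 * s
  attr(out, "margin") <- sub_mean - (m + 2 * s)
  attr(out, "degenerate") <- FALSE
  out
}

#' Subtype-level gene selection
#'
#' Applies [two_sd_select()] to every gene for one subtype; each gene's
#' cohort-wide bimodal EM fit is attached as a diagnostic (the rule itself
#' uses the cohort mean and SD).
#'
#' @param expression gene x sample matrix.
#' @param annotation sample annotation.
#' @param subtype focal subtype.
#' @param min_samples minimum subtype size (default 10).
#' @param fits optional pre-computed list of [fit_bimodal()] objects by gene.
#' @return character vector of selected genes; attribute `fits` carries the
#'   diagnostics.
#' @export
subtype_level_genes <- function(expression, annotation, subtype,
                                min_samples = 10, fits = NULL) {
  n_sub <- sum(annotation$subtype == subtype)
  if (n_sub < min_samples) return(character(0))
  sel <- vapply(rownames(expression), function(g)
    as.logical(two_sd_select(g, subtype, expression, annotation)),
    logical(1))
  out <- rownames(expression)[sel]
  attr(out, "fits") <- fits
  out
}

#' Intersect the cluster- and subtype-level selections into landmarks
#'
#' @param cluster_sets named list subtype -> genes passing the cluster track.
#' @param subtype_sets named list subtype -> genes passing the subtype track.
#' @return data frame of class `landmark_set`: `subtype`, `gene`,
#'   `cluster_pass`, `subtype_pass`, `landmark` (both flags).
#' @export
intersect_landmarks <- function(cluster_sets, subtype_sets) {
  subs <- union(names(cluster_sets), names(subtype_sets))
  rows <- lapply(subs, function(s) {
    cg <- cluster_sets[[s]] %||% character(0)
    sg <- subtype_sets[[s]] %||% character(0)
    genes <- union(cg, sg)
    if (length(genes) == 0) return(NULL)
    data.frame(subtype = s, gene = genes,
               cluster_pass = genes %in% cg,
               subtype_pass = genes %in% sg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subtype = character(0), gene = character(0),
                      cluster_pass = logical(0), subtype_pass = logical(0))
  out$landmark <- out$cluster_pass & out$subtype_pass
  rownames(out) <- NULL
  class(out) <- c("landmark_set", "data.frame")
  out
}

#' Run the full two-track landmark selection over a cohort
#'
#' For each subtype: Mann-Whitney screen (meta-cluster exclusion rule),
#' coexpression modules on the subtype's cluster scope, intersection,
#' adaptive-LASSO pruning (subtype vs whole cohort, no exclusions), the
#' subtype-level 2SD rule, and the final intersection of the two tracks.
#'
#' @param expression gene x sample matrix (matrisome genes).
#' @param annotation sample annotation.
#' @param clusters subtype meta-cluster assignment.
#' @param alpha FDR threshold for the screen and module association.
#' @param min_samples subtype-size floor for the subtype track.
#' @param seed integer seed (CV folds).
#' @return a `landmark_set` (see [intersect_landmarks()]).
#' @export
select_landmarks <- function(expression, annotation, clusters, alpha = 0.05,
                             min_samples = 10, seed = 1) {
  cl <- cluster_map(clusters)
  no_excl <- largest_cluster(cl)
  subs <- names(cl)
  module_cache <- list()
  cluster_sets <- list()
  subtype_sets <- list()
  for (sub in subs) {
    screen <- mwu_screen(expression, annotation, cl, sub, alpha = alpha,
                         no_exclusion = no_excl)
    ## module scope: samples of the focal subtype's meta-cluster; if the
    ## cluster holds a single subtype the indicator would be constant, so
    ## the scope widens to the whole cohort
    members <- names(cl)[cl == cl[[sub]]]
    scope <- if (length(members) > 1)
      annotation$sample[annotation$subtype %in% members]
    else annotation$sample
    key <- paste(sort(unique(annotation$subtype[annotation$sample %in% scope])),
                 collapse = "|")
    if (is.null(module_cache[[key]]))
      module_cache[[key]] <- coexpression_modules(
        expression[, scope, drop = FALSE])
    mods <- module_cache[[key]]
    indicator <- annotation$subtype[match(scope, annotation$sample)] == sub
    cand <- cluster_level_genes(screen, mods, indicator, alpha = alpha)
    if (length(cand) > 1) {
      y <- as.numeric(annotation$subtype == sub)
      x <- t(expression[cand, annotation$sample, drop = FALSE])
      cand <- adaptive_lasso_prune(x, y, seed = seed)
    }
    cluster_sets[[sub]] <- cand
    subtype_sets[[sub]] <- subtype_level_genes(expression, annotation, sub,
                                               min_samples = min_samples)
  }
  intersect_landmarks(cluster_sets, subtype_sets)
}
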