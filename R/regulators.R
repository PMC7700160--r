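## Regulator modelling: each eligible (subtype, landmark gene) task regresses
## the gene's expression within the subtype on the stacked regulator layers,
## independently by sparse-component regression (linear) and random-forest
## regression (non-linear), and candidate triplets are the union of the two
## selections.

#' Assemble the regressor design matrix for one subtype
#'
#' Stacks all regulator layers column-wise for the subtype's samples.
#' When TF-target or miRNA-target maps are supplied and a focal gene is
#' given, TF and miRNA regressors are restricted to the annotated regulators
#' of that gene. Constant columns are dropped; continuous columns are
#' standardized (binary mutation columns are left as 0/1).
#'
#' @param layers named list of regulator x sample matrices.
#' @param annotation sample annotation.
#' @param subtype focal subtype.
#' @param gene focal gene (only used to apply the target maps).
#' @param tf_targets,mirna_targets optional two-column data frames
#'   (`regulator`, `target`).
#' @return sample x regressor matrix; column names `layer:regulator`,
#'   attribute `layer` maps columns to layers.
#' @export
assemble_design <- function(layers, annotation, subtype, gene = NULL,
                            tf_targets = NULL, mirna_targets = NULL) {
  cols <- annotation$sample[annotation$subtype == subtype]
  if (length(cols) == 0) stop_ctx("subtype '%s' has no samples", subtype)
  blocks <- list()
  layer_of <- character(0)
  for (lname in names(layers)) {
    mat <- layers[[lname]][, cols, drop = FALSE]
    if (!is.null(gene)) {
      map <- if (lname == "tf") tf_targets
             else if (lname == "mirna") mirna_targets else NULL
      if (!is.null(map)) {
        regs <- map$regulator[map$target == gene]
        mat <- mat[intersect(rownames(mat), regs), , drop = FALSE]
      }
    }
    if (nrow(mat) == 0) next
    X <- t(mat)
    keep <- apply(X, 2, sd) > 0
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0) next
    binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
    X[, !binary] <- scale(X[, !binary, drop = FALSE])
    colnames(X) <- paste0(lname, ":", colnames(X))
    blocks[[lname]] <- X
    layer_of <- c(layer_of, rep(lname, ncol(X)))
  }
  if (length(blocks) == 0)
    stop_ctx("no usable regressors remain for subtype '%s'", subtype)
  design <- do.call(cbind, blocks)
  attr(design, "layer") <- setNames(layer_of, colnames(design))
  design
}

#' Eligible (subtype, gene) modelling tasks
#'
#' Keeps tasks whose subtype has at least `min_patients` samples and whose
#' gene has at least `min_nonzero` non-zero expression values within the
#' subtype.
#'
#' @param annotation sample annotation.
#' @param expression gene x sample matrix.
#' @param landmarks a landmark table (`subtype`, `gene`, optional
#'   `landmark` flag restricting to landmarks).
#' @param min_patients,min_nonzero eligibility floors (default 10 each;
#'   the boundaries are inclusive).
#' @return data frame `subtype`, `gene` of eligible tasks.
#' @export
eligibility_filter <- function(annotation, expression, landmarks,
                               min_patients = 10, min_nonzero = 10) {
  lm <- as.data.frame(landmarks)
  if ("landmark" %in% names(lm)) lm <- lm[lm$landmark, , drop = FALSE]
  if (nrow(lm) == 0)
    return(data.frame(subtype = character(0), gene = character(0)))
  keep <- logical(nrow(lm))
  for (i in seq_len(nrow(lm))) {
    cols <- annotation$sample[annotation$subtype == lm$subtype[i]]
    if (length(cols) < min_patients) next
    if (!lm$gene[i] %in% rownames(expression)) next
    keep[i] <- sum(expression[lm$gene[i], cols] != 0) >= min_nonzero
  }
  out <- lm[keep, c("subtype", "gene"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sparse-component regression selection
#'
#' Sequentially extracts up to `k_max` sparse components: each component's
#' loadings are the soft-thresholded correlations of the (deflated)
#' regressors with the (deflated) response, keeping entries above
#' `threshold` times the largest absolute loading; the response and design
#' are deflated on each component's score. The number of components (0 to
#' `k_max`) is chosen by `folds`-fold cross-validated predictive R^2 of the
#' component regression; when no component count achieves positive CV R^2,
#' nothing is selected. A regressor is selected iff it carries a non-zero
#' loading on a retained component.
#'
#' @param y response (gene expression within the subtype).
#' @param X sample x regressor design from [assemble_design()].
#' @param k_max maximum number of components (CV searches 1..k_max).
#' @param threshold sparsity: fraction of the max absolute loading below
#'   which loadings are zeroed (default 0.5).
#' @param folds CV folds for choosing the component count.
#' @param gain_min minimum cross-validated R^2 a component must add to be
#'   retained (default 0.05); guards against overfit noise components.
#' @param cv_repeats number of repeated CV fold splits averaged when
#'   estimating the per-component R^2 curve (default 3; repetition keeps a
#'   lucky single split from smuggling in a noise component).
#' @param seed integer seed (fold assignment).
#' @return data frame `regressor`, `layer`, `score` (loading x component
#'   coefficient), `component`; attributes `cv_r2`, `k`.
#' @export
spcr_fit <- function(y, X, k_max = 5, threshold = 0.5, folds = 5,
                     gain_min = 0.05, cv_repeats = 3, seed = 1) {
  X <- as.matrix(X)
  if (length(y) < 10) stop_ctx("need >= 10 samples (got %d)", length(y))
  if (ncol(X) == 0) stop_ctx("empty design")
  layer_of <- attr(X, "layer") %||% setNames(rep(NA_character_, ncol(X)),
                                             colnames(X))
  sst <- sum((y - mean(y))^2)
  r2_rep <- matrix(NA_real_, cv_repeats, k_max)
  for (rep_i in seq_len(cv_repeats)) {
    set.seed(seed + (rep_i - 1L) * 7919L)
    foldid <- sample(rep(seq_len(folds), length.out = length(y)))
    preds <- matrix(NA_real_, length(y), k_max)
    for (f in seq_len(folds)) {
      tr <- foldid != f
      fit <- spcr_path(y[tr], X[tr, , drop = FALSE], k_max, threshold)
      for (k in seq_len(k_max))
        preds[!tr, k] <- spcr_predict(fit, X[!tr, , drop = FALSE], k)
    }
    r2_rep[rep_i, ] <- vapply(seq_len(k_max), function(k)
      1 - sum((y - preds[, k])^2) / sst, numeric(1))
  }
  cv_r2 <- colMeans(r2_rep)
  ## components are retained incrementally while each adds >= gain_min of
  ## cross-validated R^2 (and the first already clears it)
  best <- 0L
  for (k in seq_len(k_max)) {
    gain <- if (k == 1) cv_r2[1] else cv_r2[k] - cv_r2[k - 1]
    if (is.finite(gain) && gain >= gain_min) best <- k else break
  }
  empty <- data.frame(regressor = character(0), layer = character(0),
                      score = numeric(0), component = integer(0))
  if (best == 0L || cv_r2[best] <= 0) {
    attr(empty, "cv_r2") <- suppressWarnings(max(cv_r2, na.rm = TRUE))
    attr(empty, "k") <- 0L
    return(empty)
  }
  fit <- spcr_path(y, X, best, threshold)
  rows <- list()
  for (k in seq_along(fit$loadings)) {
    v <- fit$loadings[[k]]
    nz <- which(v != 0)
    if (length(nz) == 0) next
    nm <- colnames(X)[nz]
    rows[[k]] <- data.frame(regressor = sub("^[^:]*:", "", nm),
                            layer = unname(layer_of[nm]),
                            score = v[nz] * fit$coefs[k],
                            component = k, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty
  ## a regressor loading on several retained components is reported once,
  ## at its largest absolute score
  if (nrow(out) > 1) {
    out <- out[order(-abs(out$score)), ]
    out <- out[!duplicated(out$regressor), ]
  }
  rownames(out) <- NULL
  attr(out, "cv_r2") <- cv_r2[best]
  attr(out, "k") <- best
  out
}

spcr_path <- function(y, X, k_max, threshold) {
  mu_y <- mean(y)
  r <- y - mu_y
  center <- colMeans(X)
  Xd <- sweep(X, 2, center)
  p <- ncol(X)
  ## M maps the centered original design onto the current deflated design,
  ## so each component's contribution folds into a plain coefficient vector
  M <- diag(p)
  loadings <- list(); coefs <- numeric(0); betas <- list()
  beta <- numeric(p)
  for (k in seq_len(k_max)) {
    w <- drop(crossprod(Xd, r)) / length(r)
    mw <- max(abs(w))
    if (!is.finite(mw) || mw == 0) break
    w[abs(w) < threshold * mw] <- 0
    w <- sign(w) * pmax(abs(w) - threshold * mw, 0)
    nv <- sqrt(sum(w^2))
    if (nv == 0) break
    v <- w / nv
    z <- drop(Xd %*% v)
    vz <- sum(z^2)
    if (vz < 1e-12) break
    b <- sum(z * r) / vz
    loadings[[k]] <- v
    coefs[k] <- b
    mv <- drop(M %*% v)
    beta <- beta + b * mv
    betas[[k]] <- beta
    proj <- crossprod(z, Xd) / vz
    r <- r - b * z
    Xd <- Xd - z %*% proj
    M <- M - mv %*% proj
  }
  list(loadings = loadings, coefs = coefs, betas = betas, mu_y = mu_y,
       center = center)
}

spcr_predict <- function(fit, Xnew, k) {
  k <- min(k, length(fit$betas))
  pred <- rep(fit$mu_y, nrow(Xnew))
  if (k == 0) return(pred)
  Xc <- sweep(Xnew, 2, fit$center)
  pred + drop(Xc %*% fit$betas[[k]])
}

#' Random-forest regression selection with shadow features
#'
#' Fits a 500-tree random forest of the response on the design augmented
#' with shadow features (`shadow_reps` blocks of independently column-wise
#' permuted copies of the design); a regressor is selected when its
#' permutation importance exceeds the maximum shadow importance of every
#' block. The forest's 10-fold cross-validated R^2 is recorded (using
#' lighter forests, since forest size only smooths the R^2 estimate);
#' tasks with CV R^2 <= 0 yield no selections.
#'
#' @param y response.
#' @param X sample x regressor design.
#' @param folds CV folds (default 10).
#' @param num_trees forest size for the importance fit (default 500).
#' @param shadow_reps number of permuted shadow blocks (default 15: a larger
#'   shadow pool places the selection bar at a higher quantile of the null
#'   importance distribution;
#'   1 reproduces the single-block rule).
#' @param cv_trees forest size per CV fold (default 100).
#' @param seed integer seed.
#' @return data frame `regressor`, `layer`, `score` (permutation
#'   importance); attribute `cv_r2`.
#' @export
rfr_fit <- function(y, X, folds = 10, num_trees = 500, shadow_reps = 15,
                    cv_trees = 100, seed = 1) {
  X <- as.matrix(X)
  if (length(y) < 10) stop_ctx("need >= 10 samples (got %d)", length(y))
  layer_of <- attr(X, "layer") %||% setNames(rep(NA_character_, ncol(X)),
                                             colnames(X))
  p <- ncol(X)
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(p))
  set.seed(seed)
  ## cross-validated R^2 of the plain forest
  foldid <- sample(rep(seq_len(folds), length.out = length(y)))
  pred <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    fit <- ranger::ranger(x = df[tr, , drop = FALSE], y = y[tr],
                          num.trees = cv_trees,
                          num.threads = 1, seed = seed + f)
    pred[!tr] <- predict(fit, df[!tr, , drop = FALSE],
                         num.threads = 1)$predictions
  }
  cv_r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  empty <- data.frame(regressor = character(0), layer = character(0),
                      score = numeric(0))
  if (cv_r2 <= 0) {
    attr(empty, "cv_r2") <- cv_r2
    return(empty)
  }
  set.seed(seed * 131L + 7L)
  shadows <- lapply(seq_len(shadow_reps), function(r) {
    s <- as.data.frame(apply(X, 2, sample))
    names(s) <- paste0("sh", r, "_", seq_len(p))
    s
  })
  aug <- do.call(cbind, c(list(df), shadows))
  fit <- ranger::ranger(x = aug, y = y, num.trees = num_trees,
                        importance = "permutation", num.threads = 1,
                        seed = seed * 977L + 3L)
  imp <- fit$variable.importance
  real <- imp[seq_len(p)]
  block_max <- vapply(seq_len(shadow_reps), function(r)
    max(imp[p * r + seq_len(p)]), numeric(1))
  sel <- which(real > max(block_max))
  nm <- colnames(X)[sel]
  out <- data.frame(regressor = sub("^[^:]*:", "", nm),
                    layer = unname(layer_of[nm]),
                    score = unname(real[sel]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cv_r2") <- cv_r2
  out
}

#' Combine sPCR and RFR selections into candidate triplets
#'
#' @param spcr_results,rfr_results named lists (by `subtype||gene` task) of
#'   the per-task selection tables, or single tables for one task; each must
#'   carry `subtype` and `gene` columns (added by [infer_regulators()]).
#' @return data frame of class `triplet_set`: `subtype`, `gene`,
#'   `regulator`, `layer`, `source` (`spcr`/`rfr`/`both`), `score`, ordered
#'   by (subtype, gene, layer, regulator).
#' @export
extract_triplets <- function(spcr_results, rfr_results) {
  norm <- function(x, src) {
    if (is.data.frame(x)) x <- list(x)
    rows <- Filter(function(d) !is.null(d) && nrow(d) > 0, x)
    if (length(rows) == 0)
      return(data.frame(subtype = character(0), gene = character(0),
                        regulator = character(0), layer = character(0),
                        score = numeric(0), source = character(0)))
    d <- do.call(rbind, rows)
    if ("regressor" %in% names(d) && !"regulator" %in% names(d))
      names(d)[names(d) == "regressor"] <- "regulator"
    d$source <- src
    d[, c("subtype", "gene", "regulator", "layer", "score", "source")]
  }
  a <- norm(spcr_results, "spcr")
  b <- norm(rfr_results, "rfr")
  all <- rbind(a, b)
  if (nrow(all) == 0) {
    all$source <- character(0)
    class(all) <- c("triplet_set", "data.frame")
    return(all)
  }
  key <- paste(all$subtype, all$gene, all$regulator, all$layer, sep = "\r")
  agg <- lapply(split(all, key), function(d) {
    src <- if (length(unique(d$source)) > 1) "both" else d$source[1]
    data.frame(subtype = d$subtype[1], gene = d$gene[1],
               regulator = d$regulator[1], layer = d$layer[1],
               source = src, score = d$score[which.max(abs(d$score))],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$subtype, out$gene, out$layer, out$regulator), ]
  rownames(out) <- NULL
  class(out) <- c("triplet_set", "data.frame")
  out
}

#' Run regulator inference over all eligible tasks of a cohort
#'
#' @param cohort a `matrisome_cohort` (or supply `expression`, `layers`,
#'   `annotation` of the same shapes).
#' @param landmarks landmark table (rows with `landmark == TRUE` are used).
#' @param min_patients,min_nonzero eligibility floors.
#' @param tf_targets,mirna_targets optional regulator-target maps.
#' @param k_max,threshold sPCR controls; `num_trees`, `shadow_reps` RFR
#'   controls; `seed` for CV folds and forests.
#' @return a `triplet_set` (see [extract_triplets()]); attribute `tasks`
#'   holds the eligible task list.
#' @export
infer_regulators <- function(cohort, landmarks, min_patients = 10,
                             min_nonzero = 10, tf_targets = NULL,
                             mirna_targets = NULL, k_max = 5,
                             threshold = 0.5, num_trees = 500,
                             shadow_reps = 3, seed = 1) {
  expr <- cohort$expression
  ann <- cohort$annotation
  layers <- cohort$layers
  tasks <- eligibility_filter(ann, expr, landmarks,
                              min_patients = min_patients,
                              min_nonzero = min_nonzero)
  spcr_res <- list(); rfr_res <- list()
  design_cache <- list()
  for (i in seq_len(nrow(tasks))) {
    sub <- tasks$subtype[i]; gene <- tasks$gene[i]
    cache_key <- if (is.null(tf_targets) && is.null(mirna_targets)) sub
                 else paste(sub, gene)
    if (is.null(design_cache[[cache_key]]))
      design_cache[[cache_key]] <- assemble_design(
        layers, ann, sub, gene = gene, tf_targets = tf_targets,
        mirna_targets = mirna_targets)
    X <- design_cache[[cache_key]]
    y <- expr[gene, rownames(X)]
    key <- paste(sub, gene, sep = "||")
    s <- tryCatch(spcr_fit(y, X, k_max = k_max, threshold = threshold,
                           seed = seed + i),
                  error = function(e) NULL)
    r <- tryCatch(rfr_fit(y, X, num_trees = num_trees,
                          shadow_reps = shadow_reps, seed = seed + i),
                  error = function(e) NULL)
    add_task <- function(d) {
      if (is.null(d) || nrow(d) == 0) return(NULL)
      d$subtype <- sub; d$gene <- gene
      d
    }
    spcr_res[[key]] <- add_task(s)
    rfr_res[[key]] <- add_task(r)
  }
  out <- extract_triplets(spcr_res, rfr_res)
  attr(out, "tasks") <- tasks
  out
}
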