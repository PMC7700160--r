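## Pan-cancer robustness gate: every candidate triplet is trained in a
## logistic model (subtype vs rest of cohort) on the gene, the regulator and
## their product, scored on the same cohort, and kept when the ROC AUC is at
## least the threshold (0.8 by default, inclusive).

#' Area under the ROC curve
#'
#' Rank-based AUC: the Mann-Whitney concordance probability that a random
#' positive outranks a random negative, with ties counted one half.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical or 0/1); both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop_ctx("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Validate one candidate triplet by pan-cancer logistic regression
#'
#' Fits `subtype membership ~ gene + regulator (+ gene:regulator)` over the
#' whole cohort, computes the AUC of the fitted scores on the same cohort
#' (the training cohort is deliberately also the test cohort), and flags the
#' triplet as kept when AUC >= `threshold`.
#'
#' @param triplet one-row data frame (`subtype`, `gene`, `regulator`,
#'   `layer`, and optionally `source`, `score`).
#' @param expression gene x sample matrix.
#' @param layers regulator layers.
#' @param annotation sample annotation.
#' @param threshold AUC gate (default 0.8, inclusive).
#' @param predictors `"interaction"` includes the product term,
#'   `"main"` restricts to the two main effects.
#' @return the triplet row extended with `auc` and `kept`; attribute
#'   `coefficients` carries the logistic fit.
#' @export
triplet_logistic_auc <- function(triplet, expression, layers, annotation,
                                 threshold = 0.8,
                                 predictors = c("interaction", "main")) {
  predictors <- match.arg(predictors)
  gene <- triplet$gene; lay <- triplet$layer; reg <- triplet$regulator
  if (!gene %in% rownames(expression))
    stop_ctx("gene '%s' not observable cohort-wide", gene)
  if (!lay %in% names(layers) || !reg %in% rownames(layers[[lay]]))
    stop_ctx("regulator '%s' (layer %s) not observable cohort-wide",
             reg, lay)
  g <- expression[gene, annotation$sample]
  r <- layers[[lay]][reg, annotation$sample]
  label <- as.numeric(annotation$subtype == triplet$subtype)
  fml <- if (predictors == "interaction") label ~ g * r else label ~ g + r
  fit <- suppressWarnings(glm(fml, family = binomial()))
  a <- auc(fitted(fit), label)
  out <- triplet
  out$auc <- a
  out$kept <- a >= threshold
  attr(out, "coefficients") <- coef(fit)
  out
}

#' Validate a whole triplet set
#'
#' Applies [triplet_logistic_auc()] to every row; triplets whose gene or
#' regulator is not observable cohort-wide are dropped with a message.
#'
#' @inheritParams triplet_logistic_auc
#' @param triplets a `triplet_set`.
#' @return data frame with `auc` and `kept` columns appended.
#' @export
validate_triplets <- function(triplets, expression, layers, annotation,
                              threshold = 0.8,
                              predictors = c("interaction", "main")) {
  predictors <- match.arg(predictors)
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(triplets))) {
    v <- tryCatch(
      triplet_logistic_auc(triplets[i, , drop = FALSE], expression, layers,
                           annotation, threshold, predictors),
      error = function(e) NULL)
    if (is.null(v)) dropped <- dropped + 1L else rows[[length(rows) + 1L]] <- v
  }
  if (dropped > 0)
    message(sprintf("dropped %d triplet(s) not observable cohort-wide",
                    dropped))
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    z <- as.data.frame(triplets)[0, , drop = FALSE]
    z$auc <- numeric(0); z$kept <- logical(0); z
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Keep validated interactions and summarize them
#'
#' @param validated output of [validate_triplets()].
#' @param catalog optional matrisome catalog for the per-category tally.
#' @return list: `kept` (interactions with AUC >= threshold), `summary`
#'   (per-subtype and per-layer counts, per-category counts when a catalog
#'   is given, and mean/min/max AUC of the kept set).
#' @export
filter_and_summarize <- function(validated, catalog = NULL) {
  thr <- attr(validated, "threshold") %||% 0.8
  kept <- validated[validated$kept, , drop = FALSE]
  rownames(kept) <- NULL
  summ <- list(
    n_candidates = nrow(validated),
    n_kept = nrow(kept),
    threshold = thr,
    by_subtype = as.data.frame(table(subtype = kept$subtype),
                               stringsAsFactors = FALSE),
    by_layer = as.data.frame(table(layer = kept$layer),
                             stringsAsFactors = FALSE),
    auc_mean = if (nrow(kept) > 0) mean(kept$auc) else NA_real_,
    auc_min = if (nrow(kept) > 0) min(kept$auc) else NA_real_,
    auc_max = if (nrow(kept) > 0) max(kept$auc) else NA_real_)
  if (!is.null(catalog))
    summ$by_category <- interaction_breakdown(kept, catalog)
  list(kept = kept, summary = summ)
}
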