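## Matrisome gene annotation: division (core / associated) and category,
## plus the bookkeeping breakdowns used in reporting.

CORE_CATEGORIES <- c("collagens", "proteoglycans", "ECM glycoproteins")
ASSOC_CATEGORIES <- c("ECM-affiliated proteins", "ECM regulators",
                      "secreted factors")
ALL_CATEGORIES <- c(CORE_CATEGORIES, ASSOC_CATEGORIES)

#' Load a matrisome catalog
#'
#' Reads a TSV with columns `gene`, `division`, `category` and validates it:
#' categories must be among the six matrisome categories, the division must
#' be consistent with the category (collagens, proteoglycans and ECM
#' glycoproteins are core matrisome; ECM-affiliated proteins, ECM regulators
#' and secreted factors are matrisome-associated), and gene symbols must be
#' unique.
#'
#' With no `path` the packaged catalog is returned: a synthetic stand-in for
#' the published 1027-gene matrisome annotation, with synthetic gene symbols
#' but the published category sizes (44 collagens, 35 proteoglycans, 195 ECM
#' glycoproteins, 171 ECM-affiliated proteins, 238 ECM regulators, 344
#' secreted factors).
#'
#' @param path optional path to a user catalog TSV.
#' @return a data frame of class `matrisome_catalog`.
#' @export
load_matrisome_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "matrisome_catalog_synthetic.tsv",
                        package = "matriscope", mustWork = TRUE)
  if (!file.exists(path)) stop_ctx("catalog file not found: '%s'", path)
  cat_df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(cat_df) == 0) stop_ctx("catalog '%s' is empty", path)
  need <- c("gene", "division", "category")
  if (!all(need %in% names(cat_df)))
    stop_ctx("catalog must have columns: %s", paste(need, collapse = ", "))
  dup <- cat_df$gene[duplicated(cat_df$gene)]
  if (length(dup) > 0)
    stop_ctx("duplicate gene symbols in catalog: %s",
             paste(head(unique(dup), 5), collapse = ", "))
  bad <- setdiff(unique(cat_df$category), ALL_CATEGORIES)
  if (length(bad) > 0)
    stop_ctx("unknown matrisome categories: %s", paste(bad, collapse = ", "))
  expected_div <- ifelse(cat_df$category %in% CORE_CATEGORIES,
                         "core", "associated")
  off <- cat_df$division != expected_div
  if (any(off))
    stop_ctx("division inconsistent with category for: %s",
             paste(head(cat_df$gene[off], 5), collapse = ", "))
  class(cat_df) <- c("matrisome_catalog", "data.frame")
  cat_df
}

catalog_lookup <- function(genes, catalog) {
  idx <- match(genes, catalog$gene)
  missing <- genes[is.na(idx)]
  list(found = catalog[idx[!is.na(idx)], , drop = FALSE], missing = missing)
}

#' Division and category breakdown of a gene set
#'
#' Counts and percentages (of the genes found in the catalog) by matrisome
#' division and category. Percentages are `100 * k / N` rounded half-up to
#' one decimal. Genes absent from the catalog are reported and excluded.
#'
#' @param genes character vector of gene symbols.
#' @param catalog a [load_matrisome_catalog()] catalog.
#' @return a data frame with columns `level` (`division`/`category`),
#'   `name`, `count`, `percent`; attribute `missing` lists unknown genes.
#' @export
matrisome_breakdown <- function(genes, catalog = load_matrisome_catalog()) {
  genes <- unique(genes)
  lk <- catalog_lookup(genes, catalog)
  n <- nrow(lk$found)
  div_counts <- vapply(c("core", "associated"),
                       function(d) sum(lk$found$division == d), integer(1))
  cat_counts <- vapply(ALL_CATEGORIES,
                       function(cc) sum(lk$found$category == cc), integer(1))
  out <- rbind(
    data.frame(level = "division", name = names(div_counts),
               count = as.integer(div_counts), stringsAsFactors = FALSE),
    data.frame(level = "category", name = names(cat_counts),
               count = as.integer(cat_counts), stringsAsFactors = FALSE))
  out$percent <- if (n > 0) round_half_up(100 * out$count / n, 1) else 0
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "missing") <- lk$missing
  out
}

#' Breakdown of regulatory interactions by matrisome annotation
#'
#' Tallies a set of (subtype, gene, regulator) triplets by the matrisome
#' division and category of the target gene, overall and per tumor type
#' (the prefix of the subtype label up to the first `.`).
#'
#' @param triplets data frame with at least columns `subtype` and `gene`.
#' @param catalog a matrisome catalog.
#' @return list with `overall` (as [matrisome_breakdown()], but counting
#'   interactions, not unique genes) and `by_type` (long data frame).
#' @export
interaction_breakdown <- function(triplets,
                                  catalog = load_matrisome_catalog()) {
  if (nrow(triplets) == 0) {
    z <- data.frame(level = c("division", "division", rep("category", 6)),
                    name = c("core", "associated", ALL_CATEGORIES),
                    count = 0L, percent = 0, stringsAsFactors = FALSE)
    return(list(overall = z,
                by_type = data.frame(type = character(0),
                                     category = character(0),
                                     count = integer(0))))
  }
  idx <- match(triplets$gene, catalog$gene)
  if (anyNA(idx))
    stop_ctx("triplet genes missing from catalog: %s",
             paste(head(unique(triplets$gene[is.na(idx)]), 5), collapse = ", "))
  division <- catalog$division[idx]
  category <- catalog$category[idx]
  n <- nrow(triplets)
  div_counts <- vapply(c("core", "associated"),
                       function(d) sum(division == d), integer(1))
  cat_counts <- vapply(ALL_CATEGORIES, function(cc) sum(category == cc),
                       integer(1))
  overall <- rbind(
    data.frame(level = "division", name = names(div_counts),
               count = as.integer(div_counts), stringsAsFactors = FALSE),
    data.frame(level = "category", name = names(cat_counts),
               count = as.integer(cat_counts), stringsAsFactors = FALSE))
  overall$percent <- round_half_up(100 * overall$count / n, 1)
  type <- sub("\\..*$", "", triplets$subtype)
  by_type <- as.data.frame(table(type = type, category = category),
                           stringsAsFactors = FALSE)
  names(by_type)[3] <- "count"
  list(overall = overall, by_type = by_type[by_type$count > 0, , drop = FALSE])
}

#' Are landmark genes enriched in the top quarter of matrisome expression?
#'
#' Within each subtype, matrisome genes are ranked by their median expression
#' across the subtype's samples; the top quarter is the highest 25% of ranks.
#' For every subtype with at least one landmark, the fraction of landmark
#' genes in the top quarter is compared one-sidedly with the fraction of
#' non-selected matrisome genes there.
#'
#' @param landmarks data frame with columns `subtype`, `gene` (landmark calls).
#' @param expression gene x sample matrix.
#' @param annotation sample annotation with `sample` and `subtype`.
#' @return data frame per subtype: `n_landmark`, `landmark_frac`,
#'   `other_frac`, `enriched` (landmark fraction strictly greater).
#' @export
top_quartile_enrichment <- function(landmarks, expression, annotation) {
  out <- list()
  for (sub in unique(landmarks$subtype)) {
    lg <- intersect(landmarks$gene[landmarks$subtype == sub],
                    rownames(expression))
    if (length(lg) == 0) next
    cols <- annotation$sample[annotation$subtype == sub]
    med <- apply(expression[, cols, drop = FALSE], 1, median)
    cutoff <- quantile(med, 0.75, names = FALSE)
    top <- names(med)[med > cutoff]
    other <- setdiff(rownames(expression), lg)
    lf <- mean(lg %in% top)
    of <- mean(other %in% top)
    out[[sub]] <- data.frame(subtype = sub, n_landmark = length(lg),
                             landmark_frac = lf, other_frac = of,
                             enriched = lf > of, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(subtype = character(0), n_landmark = integer(0),
                      landmark_frac = numeric(0), other_frac = numeric(0),
                      enriched = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
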