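# Shared fixtures, generated in code.

# small cohort for fast structural tests
small_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_config(
    n_types = 3L, subtypes_per_type = 2L, n_samples_per_subtype = 20L,
    n_matrisome_genes = 60L,
    n_regulators_per_layer = c(tf = 6L, program = 4L, mirna = 4L,
                               methylation = 5L, cna = 5L, mutation = 4L),
    n_planted_markers_per_subtype = 2L, marker_effect_sd = 2.5,
    n_metaclusters = 3L, seed = seed, ...))
}

# tiny annotation + expression pair with two subtypes, no planted structure
toy_expression <- function(n_per = 20, genes = 10, seed = 1, shift = 0,
                           marked_gene = 1, marked_subtype = "B") {
  set.seed(seed)
  subs <- rep(c("A", "B"), each = n_per)
  samples <- sprintf("s%03d", seq_along(subs))
  expr <- matrix(rnorm(genes * length(subs), 8, 2), genes,
                 dimnames = list(sprintf("g%02d", seq_len(genes)), samples))
  if (shift != 0)
    expr[marked_gene, subs == marked_subtype] <-
      expr[marked_gene, subs == marked_subtype] + shift
  ann <- data.frame(sample = samples, type = "T01", subtype = subs,
                    stringsAsFactors = FALSE)
  list(expression = expr, annotation = ann)
}

# brute-force AUC by pairwise concordance (ties count one half)
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by enumeration of all assignments (no ties)
mwu_exact_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  u_stat <- function(xi, yi) sum(outer(xi, yi, ">"))
  obs <- u_stat(x, y)
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(ix) u_stat(vals[ix], vals[-ix]))
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(obs - mu))
}
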