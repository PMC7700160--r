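## Synthetic multi-omics cohort generator with planted ground truth.
##
## The generator emulates the shape of a pan-cancer cohort: tumor types split
## into subtypes, subtypes grouped into matrisome meta-clusters, matrisome
## genes with subtype-specific bimodal over-expression, stacked regulator
## layers with planted regulator->gene links, and exponential survival with
## gene-dependent hazards. Every planted effect is returned as ground truth
## so downstream recovery can be scored.

LAYER_NAMES <- c("tf", "program", "mirna", "methylation", "cna", "mutation",
                 "stromal")
## layers used for planted regulator->gene links (continuous codomains)
LINK_LAYERS <- c("tf", "program", "cna", "methylation")

#' Configuration for the synthetic cohort generator
#'
#' Defaults define the reference benchmark cohort: 5 meta-clusters of one
#' tumor type each, 2 subtypes per type (10 subtypes), 50 samples per subtype,
#' 120 matrisome genes, 3 planted markers per subtype each with one planted
#' regulator link.
#'
#' @param n_types number of tumor types.
#' @param subtypes_per_type subtypes within each type.
#' @param n_samples_per_subtype samples per subtype (as low as 10 is allowed,
#'   mirroring the smallest real subtypes).
#' @param n_matrisome_genes number of matrisome genes (named from the packaged
#'   catalog).
#' @param n_regulators_per_layer named integer vector giving the number of
#'   candidate regulators per layer (`tf`, `program`, `mirna`, `methylation`,
#'   `cna`, `mutation`; `stromal` always has exactly one row).
#' @param n_planted_markers_per_subtype planted over-expressed marker genes
#'   per subtype (disjoint across subtypes).
#' @param marker_effect_sd marker over-expression effect in cohort-SD units:
#'   the realized subtype shift equals this multiple of the realized
#'   cohort-wide SD of the gene (see the methods vignette for the
#'   calibration).
#' @param regulator_effect standardized slope of planted regulator->gene
#'   links within the marked subtype.
#' @param noise_sd residual SD (in background-SD units) of link-carrying
#'   marker genes within their subtype.
#' @param censoring_rate fraction of samples censored, in `[0, 1)`.
#' @param hazard_log_hr per-unit log hazard ratio for planted prognostic
#'   genes (standardized expression within the subtype).
#' @param seed integer seed; a fixed seed yields identical cohorts.
#' @param n_metaclusters number of meta-clusters (types are assigned
#'   round-robin).
#' @param metacluster_shift shared mean shift (in background-SD units) that
#'   each meta-cluster adds to its own random subset of genes.
#' @param metacluster_gene_frac fraction of non-marker genes shifted per
#'   meta-cluster.
#' @param links_per_marker planted regulator links per marker gene.
#' @param baseline_mean,baseline_sd location and scale of the log-like
#'   background expression model (values are truncated at 0).
#' @param base_hazard baseline exponential hazard (per day).
#'
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_types = 5L,
                          subtypes_per_type = 2L,
                          n_samples_per_subtype = 50L,
                          n_matrisome_genes = 120L,
                          n_regulators_per_layer = c(tf = 15L, program = 8L,
                                                     mirna = 10L,
                                                     methylation = 12L,
                                                     cna = 12L, mutation = 8L),
                          n_planted_markers_per_subtype = 5L,
                          marker_effect_sd = 3.0,
                          regulator_effect = 1.0,
                          noise_sd = 0.5,
                          censoring_rate = 0.3,
                          hazard_log_hr = 1.0,
                          seed = 1L,
                          n_metaclusters = min(5L, n_types),
                          metacluster_shift = 2.0,
                          metacluster_gene_frac = 0.1,
                          links_per_marker = 1L,
                          baseline_mean = 8,
                          baseline_sd = 2,
                          base_hazard = 1 / 1000) {
  cfg <- list(n_types = assert_count(n_types, "n_types"),
              subtypes_per_type = assert_count(subtypes_per_type,
                                               "subtypes_per_type"),
              n_samples_per_subtype = assert_count(n_samples_per_subtype,
                                                   "n_samples_per_subtype"),
              n_matrisome_genes = assert_count(n_matrisome_genes,
                                               "n_matrisome_genes"),
              n_regulators_per_layer = n_regulators_per_layer,
              n_planted_markers_per_subtype =
                assert_count(n_planted_markers_per_subtype,
                             "n_planted_markers_per_subtype", min = 0L),
              marker_effect_sd = marker_effect_sd,
              regulator_effect = regulator_effect,
              noise_sd = noise_sd,
              censoring_rate = censoring_rate,
              hazard_log_hr = hazard_log_hr,
              seed = assert_count(seed, "seed", min = 0L),
              n_metaclusters = assert_count(n_metaclusters, "n_metaclusters"),
              metacluster_shift = metacluster_shift,
              metacluster_gene_frac = metacluster_gene_frac,
              links_per_marker = assert_count(links_per_marker,
                                              "links_per_marker", min = 0L),
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              base_hazard = base_hazard)
  lay <- cfg$n_regulators_per_layer
  if (is.null(names(lay)) || !all(names(lay) %in% setdiff(LAYER_NAMES, "stromal")))
    stop_ctx("n_regulators_per_layer must be named with layers among: %s",
             paste(setdiff(LAYER_NAMES, "stromal"), collapse = ", "))
  if (any(lay < 1)) stop_ctx("all layer sizes must be >= 1")
  if (marker_effect_sd < 0) stop_ctx("marker_effect_sd must be >= 0")
  if (noise_sd < 0) stop_ctx("noise_sd must be >= 0")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop_ctx("censoring_rate must be in [0, 1)")
  n_subtypes <- cfg$n_types * cfg$subtypes_per_type
  if (n_subtypes * cfg$n_planted_markers_per_subtype > cfg$n_matrisome_genes)
    stop_ctx("planted markers (%d subtypes x %d) exceed gene count (%d)",
             n_subtypes, cfg$n_planted_markers_per_subtype,
             cfg$n_matrisome_genes)
  if (cfg$links_per_marker > min(lay[intersect(LINK_LAYERS, names(lay))]))
    stop_ctx("links_per_marker exceeds the size of the smallest link layer")
  ## a shift of e cohort-SDs is attainable only while e^2 f (1-f) < 1,
  ## f being the subtype's share of the cohort (the shift inflates the SD)
  f <- 1 / n_subtypes
  if (cfg$n_planted_markers_per_subtype > 0 &&
      marker_effect_sd^2 * f * (1 - f) >= 1)
    stop_ctx(paste0("marker_effect_sd = %.2f cohort SDs is unattainable when ",
                    "each subtype is 1/%d of the cohort"),
             marker_effect_sd, n_subtypes)
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("synthetic cohort config:",
      x$n_types, "types x", x$subtypes_per_type, "subtypes x",
      x$n_samples_per_subtype, "samples;", x$n_matrisome_genes, "genes;",
      "marker effect", x$marker_effect_sd, "cohort SDs; seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic pan-cancer-like multi-omics cohort
#'
#' Produces a log-scale expression matrix, per-sample annotation (type,
#' subtype, meta-cluster, purity, age, survival), stacked regulator layers and
#' the planted ground truth (markers, regulator links, prognostic genes).
#'
#' Marker genes are drawn from a two-component model: background
#' `N(mu, sigma^2)` everywhere, and a shifted component within the marked
#' subtype whose mean exceeds the background by `marker_effect_sd` realized
#' cohort SDs. Linked marker genes additionally track their planted regulator
#' (standardized within the subtype) with slope `regulator_effect` (in
#' background-SD units) and residual SD `noise_sd`. Survival times are
#' exponential with a hazard depending on the planted prognostic gene of each
#' subtype.
#'
#' @param config a [cohort_config()].
#' @return an object of class `matrisome_cohort`: a list with elements
#'   `expression` (gene x sample matrix), `annotation` (data frame),
#'   `layers` (named list of regulator x sample matrices, class
#'   `regulator_layers`), `truth` (class `planted_truth`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stop_ctx("config must be built with cohort_config()")
  set.seed(config$seed)
  sigma <- config$baseline_sd
  n_sub <- config$n_types * config$subtypes_per_type
  n <- n_sub * config$n_samples_per_subtype
  g <- config$n_matrisome_genes

  catalog <- load_matrisome_catalog()
  genes <- sort(sample(catalog$gene, g))
  samples <- sprintf("S%04d", seq_len(n))
  types <- sprintf("T%02d", seq_len(config$n_types))
  subtypes <- as.vector(t(outer(types, seq_len(config$subtypes_per_type),
                                function(t, i) paste0(t, ".", i))))
  mc_of_type <- setNames(paste0("MC", ((seq_len(config$n_types) - 1L) %%
                                         config$n_metaclusters) + 1L), types)
  ann <- data.frame(
    sample = samples,
    type = rep(rep(types, each = config$subtypes_per_type),
               each = config$n_samples_per_subtype),
    subtype = rep(subtypes, each = config$n_samples_per_subtype),
    stringsAsFactors = FALSE)
  ann$metacluster <- mc_of_type[ann$type]
  ann$purity <- runif(n, 0.25, 0.95)
  ann$age <- pmin(pmax(round(rnorm(n, 63, 10)), 25), 90)

  ## planted markers: disjoint gene sets across subtypes
  k <- config$n_planted_markers_per_subtype
  marker_genes <- if (k > 0) sample(genes, n_sub * k) else character(0)
  markers <- if (k > 0)
    data.frame(subtype = rep(subtypes, each = k), gene = marker_genes,
               stringsAsFactors = FALSE)
  else data.frame(subtype = character(0), gene = character(0))

  ## meta-cluster structure: each meta-cluster shifts its own random subset
  ## of non-marker genes
  mcs <- unique(mc_of_type)
  n_shift <- max(1L, round(config$metacluster_gene_frac * g))
  free_genes <- setdiff(genes, marker_genes)
  mc_genes <- lapply(setNames(mcs, mcs), function(m)
    sample(free_genes, min(n_shift, length(free_genes))))

  ## background expression
  mu_g <- config$baseline_mean + rnorm(g)
  expr <- matrix(rnorm(g * n, mean = mu_g, sd = sigma), nrow = g,
                 dimnames = list(genes, samples))
  for (m in mcs) {
    cols <- ann$metacluster == m
    expr[mc_genes[[m]], cols] <- expr[mc_genes[[m]], cols] +
      config$metacluster_shift * sigma
  }

  ## regulator layers
  lay_sizes <- config$n_regulators_per_layer
  layers <- list()
  for (lname in names(lay_sizes)) {
    p <- as.integer(lay_sizes[[lname]])
    ids <- sprintf("%s_%03d", toupper(lname), seq_len(p))
    vals <- switch(lname,
      tf = matrix(rnorm(p * n, 6, 1.5), p),
      program = matrix(rnorm(p * n), p),
      mirna = matrix(pmax(rnorm(p * n, 4, 1), 0), p),
      methylation = matrix(rbeta(p * n, 2, 2), p),
      cna = matrix(rnorm(p * n, 0, 0.5), p),
      mutation = matrix(rbinom(p * n, 1, 0.15), p))
    dimnames(vals) <- list(ids, samples)
    layers[[lname]] <- vals
  }
  layers$stromal <- matrix(1 - ann$purity, nrow = 1,
                           dimnames = list("STROMAL_001", samples))
  class(layers) <- "regulator_layers"

  ## marker over-expression, calibrated so the realized subtype shift equals
  ## marker_effect_sd cohort SDs (the shift itself inflates the cohort SD)
  e <- config$marker_effect_sd
  f <- 1 / n_sub
  shift <- if (k > 0 && e > 0) e * sigma / sqrt(1 - e^2 * f * (1 - f)) else 0

  ## planted regulator links (cycled over the continuous link layers)
  links <- data.frame(subtype = character(0), gene = character(0),
                      regulator = character(0), layer = character(0),
                      effect = numeric(0), stringsAsFactors = FALSE)
  link_layers <- intersect(LINK_LAYERS, names(layers))
  li <- 0L
  if (nrow(markers) > 0 && config$links_per_marker > 0) {
    for (i in seq_len(nrow(markers))) {
      for (j in seq_len(config$links_per_marker)) {
        li <- li + 1L
        lname <- link_layers[((li - 1L) %% length(link_layers)) + 1L]
        reg <- sample(rownames(layers[[lname]]), 1)
        links <- rbind(links, data.frame(
          subtype = markers$subtype[i], gene = markers$gene[i],
          regulator = reg, layer = lname, effect = config$regulator_effect,
          stringsAsFactors = FALSE))
      }
    }
  }

  for (i in seq_len(nrow(markers))) {
    sub <- markers$subtype[i]; gene <- markers$gene[i]
    cols <- which(ann$subtype == sub)
    glinks <- links[links$subtype == sub & links$gene == gene, , drop = FALSE]
    base <- mu_g[match(gene, genes)] + shift
    if (nrow(glinks) > 0) {
      lin <- 0
      for (r in seq_len(nrow(glinks))) {
        v <- layers[[glinks$layer[r]]][glinks$regulator[r], cols]
        sdv <- sd(v)
        z <- if (sdv > 1e-12) (v - mean(v)) / sdv else rep(0, length(v))
        lin <- lin + glinks$effect[r] * sigma * z
      }
      expr[gene, cols] <- base + lin +
        rnorm(length(cols), 0, config$noise_sd * sigma)
    } else {
      expr[gene, cols] <- base + rnorm(length(cols), 0, sigma)
    }
  }
  expr <- pmax(expr, 0)

  ## prognostic planted genes: one marker per subtype drives the hazard
  prognostic <- data.frame(subtype = character(0), gene = character(0),
                           sign = numeric(0), stringsAsFactors = FALSE)
  rate <- rep(config$base_hazard, n)
  if (k > 0) {
    for (si in seq_along(subtypes)) {
      sub <- subtypes[si]
      gene <- markers$gene[markers$subtype == sub][1]
      sgn <- if (si %% 2 == 0) -1 else 1
      prognostic <- rbind(prognostic, data.frame(
        subtype = sub, gene = gene, sign = sgn, stringsAsFactors = FALSE))
      cols <- which(ann$subtype == sub)
      x <- expr[gene, cols]
      z <- if (sd(x) > 1e-12) (x - mean(x)) / sd(x) else rep(0, length(x))
      rate[cols] <- config$base_hazard * exp(config$hazard_log_hr * sgn * z)
    }
  }
  t_event <- rexp(n, rate = rate)
  censored <- runif(n) < config$censoring_rate
  ann$time <- ifelse(censored, pmax(runif(n) * t_event, 0.5), t_event)
  ann$event <- as.integer(!censored)

  truth <- structure(list(markers = markers, links = links,
                          prognostic = prognostic), class = "planted_truth")
  structure(list(expression = expr, annotation = ann, layers = layers,
                 truth = truth, config = config),
            class = "matrisome_cohort")
}

#' @export
print.matrisome_cohort <- function(x, ...) {
  cat("matrisome cohort:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples;",
      length(unique(x$annotation$subtype)), "subtypes;",
      nrow(x$truth$markers), "planted markers,",
      nrow(x$truth$links), "planted links\n")
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Expression, annotation and each regulator layer go to TSV, the planted
#' truth to JSON, and the configuration to YAML; [read_cohort()] round-trips
#' them losslessly.
#'
#' @param cohort a `matrisome_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "matrisome_cohort")) stop_ctx("not a matrisome_cohort")
  if (ncol(cohort$expression) == 0 || nrow(cohort$annotation) == 0)
    stop_ctx("refusing to write an empty cohort (0 samples)")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  write_tsv_matrix(cohort$expression, files["expression"], id_col = "gene")
  write.table(cohort$annotation, files["annotation"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (lname in names(cohort$layers)) {
    p <- file.path(dir, paste0("layer_", lname, ".tsv"))
    write_tsv_matrix(cohort$layers[[lname]], p, id_col = "regulator")
    files[paste0("layer_", lname)] <- p
  }
  jsonlite::write_json(unclass(cohort$truth), files["truth"],
                       dataframe = "columns", digits = NA)
  cfg <- unclass(cohort$config)
  ## named atomic vectors lose their names in YAML; store the layer sizes
  ## as a map
  cfg$n_regulators_per_layer <- as.list(cfg$n_regulators_per_layer)
  yaml::write_yaml(cfg, files["config"])
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a `matrisome_cohort`.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop_ctx("cohort directory not found: '%s'", dir)
  expr <- read_tsv_matrix(file.path(dir, "expression.tsv"))
  ann <- read.delim(file.path(dir, "annotation.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  lfiles <- list.files(dir, pattern = "^layer_.*\\.tsv$", full.names = TRUE)
  layers <- lapply(lfiles, read_tsv_matrix)
  names(layers) <- sub("^layer_(.*)\\.tsv$", "\\1", basename(lfiles))
  layers <- layers[intersect(LAYER_NAMES, names(layers))]
  class(layers) <- "regulator_layers"
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- structure(lapply(tr, function(d) {
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    if (nrow(d) == 0 && "sign" %in% names(d)) d$sign <- numeric(0)
    d
  }), class = "planted_truth")
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfgl$n_regulators_per_layer <- unlist(cfgl$n_regulators_per_layer)
  config <- do.call(cohort_config, cfgl)
  structure(list(expression = expr, annotation = ann, layers = layers,
                 truth = truth, config = config),
            class = "matrisome_cohort")
}
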