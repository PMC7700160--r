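## End-to-end orchestration: meta-clustering -> landmark selection ->
## regulator inference -> robustness gate -> prognostics -> summaries.

#' Pipeline parameters
#'
#' All stage thresholds in one place. Defaults are the reference constants:
#' FDR alpha 0.05, AUC gate 0.8 (inclusive), eligibility floors of 10
#' patients and 10 non-zero expression values.
#'
#' @param alpha FDR / significance threshold used by the screen, module
#'   association and prognostics.
#' @param auc_threshold robustness AUC gate.
#' @param min_patients,min_nonzero eligibility floors for regulator
#'   modelling (and the subtype-track size floor).
#' @param seed master seed; per-stage seeds are derived deterministically
#'   (see `stage_seed`).
#' @param n_pcs principal components fed to the GMM meta-clustering.
#' @param gmm_g candidate GMM component counts.
#' @param spcr_k_max,spcr_threshold sPCR controls.
#' @param rfr_trees,rfr_shadow_reps RFR controls.
#' @param predictors logistic-validation predictor set
#'   (`"interaction"`/`"main"`).
#' @param run_prognostics,run_summaries stage toggles.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(alpha = 0.05, auc_threshold = 0.8,
                            min_patients = 10, min_nonzero = 10, seed = 1,
                            n_pcs = 5, gmm_g = 1:10, spcr_k_max = 5,
                            spcr_threshold = 0.5, rfr_trees = 500,
                            rfr_shadow_reps = 15,
                            predictors = "interaction",
                            run_prognostics = TRUE, run_summaries = TRUE) {
  structure(list(alpha = alpha, auc_threshold = auc_threshold,
                 min_patients = min_patients, min_nonzero = min_nonzero,
                 seed = as.integer(seed), n_pcs = n_pcs, gmm_g = gmm_g,
                 spcr_k_max = spcr_k_max, spcr_threshold = spcr_threshold,
                 rfr_trees = rfr_trees, rfr_shadow_reps = rfr_shadow_reps,
                 predictors = predictors,
                 run_prognostics = run_prognostics,
                 run_summaries = run_summaries),
            class = "pipeline_params")
}

#' Run the full landmark / regulator / prognostics pipeline
#'
#' Stages run in order: meta-clustering (GMM with BIC on top principal
#' components of matrisome expression, unless a pre-computed assignment is
#' supplied), two-track landmark selection, regulator inference (sPCR and
#' RFR), pan-cancer logistic AUC validation, prognostic scan, and the
#' bookkeeping summaries. The run is idempotent under a fixed seed.
#'
#' @param cohort a `matrisome_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param params a [pipeline_params()].
#' @param clusters optional pre-computed subtype->cluster assignment (data
#'   frame `subtype`, `cluster`), bypassing the clustering stage.
#' @param tf_targets,mirna_targets optional regulator-target maps.
#' @param catalog matrisome catalog for the summaries.
#' @return list of class `pipeline_result`: `clusters`, `landmarks`,
#'   `triplets`, `validated`, `interactions` (kept), `prognostics`,
#'   `summaries`, `manifest`.
#' @export
run_pipeline <- function(cohort, params = pipeline_params(),
                         clusters = NULL, tf_targets = NULL,
                         mirna_targets = NULL,
                         catalog = load_matrisome_catalog()) {
  stopifnot(inherits(cohort, "matrisome_cohort"))
  seed <- params$seed
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop_ctx("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (is.null(clusters)) {
    clusters <- run_stage("metacluster", function()
      metacluster_cohort(cohort$expression, cohort$annotation,
                         n_pcs = params$n_pcs, G = params$gmm_g,
                         seed = stage_seed(seed, "cluster")))
  }
  landmarks <- run_stage("landmark_selection", function()
    select_landmarks(cohort$expression, cohort$annotation, clusters,
                     alpha = params$alpha,
                     min_samples = params$min_patients,
                     seed = stage_seed(seed, "landmarks")))
  triplets <- run_stage("regulator_inference", function()
    infer_regulators(cohort, landmarks,
                     min_patients = params$min_patients,
                     min_nonzero = params$min_nonzero,
                     tf_targets = tf_targets,
                     mirna_targets = mirna_targets,
                     k_max = params$spcr_k_max,
                     threshold = params$spcr_threshold,
                     num_trees = params$rfr_trees,
                     shadow_reps = params$rfr_shadow_reps,
                     seed = stage_seed(seed, "infer")))
  validated <- run_stage("robustness_filter", function()
    validate_triplets(triplets, cohort$expression, cohort$layers,
                      cohort$annotation,
                      threshold = params$auc_threshold,
                      predictors = params$predictors))
  filtered <- filter_and_summarize(validated, catalog = catalog)
  prognostics <- NULL
  if (params$run_prognostics)
    prognostics <- run_stage("prognostics", function()
      prognostic_scan(landmarks, cohort$expression, cohort$annotation,
                      alpha = params$alpha))
  summaries <- NULL
  if (params$run_summaries) {
    lmk <- landmarks[landmarks$landmark, , drop = FALSE]
    summaries <- run_stage("summaries", function() list(
      landmark_breakdown = matrisome_breakdown(unique(lmk$gene), catalog),
      interaction_breakdown = interaction_breakdown(filtered$kept, catalog),
      top_quartile = top_quartile_enrichment(lmk, cohort$expression,
                                             cohort$annotation),
      validation = filtered$summary))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("matriscope")),
    seed = seed,
    params = unclass(params),
    counts = list(
      n_samples = ncol(cohort$expression),
      n_genes = nrow(cohort$expression),
      n_subtypes = length(unique(cohort$annotation$subtype)),
      n_clusters = length(unique(clusters$cluster)),
      n_landmarks = sum(landmarks$landmark),
      n_candidate_triplets = nrow(triplets),
      n_interactions = nrow(filtered$kept),
      n_prognostic = if (is.null(prognostics)) NA_integer_
                     else sum(prognostics$prognostic)))
  structure(list(clusters = clusters, landmarks = landmarks,
                 triplets = triplets, validated = validated,
                 interactions = filtered$kept, prognostics = prognostics,
                 summaries = summaries, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cts <- x$manifest$counts
  cat("pipeline result:", cts$n_landmarks, "landmarks,",
      cts$n_candidate_triplets, "candidate triplets,",
      cts$n_interactions, "kept interactions",
      if (!is.na(cts$n_prognostic))
        paste0("(", cts$n_prognostic, " prognostic genes)"), "\n")
  invisible(x)
}

#' Human-readable report of a pipeline run
#'
#' Deterministic summary: per-subtype landmark and interaction counts,
#' matrisome division/category breakdowns, AUC distribution of the kept
#' interactions, and the prognostic table.
#'
#' @param bundle a `pipeline_result`.
#' @param catalog matrisome catalog.
#' @return list of class `pipeline_report` with a `text` element (markdown
#'   lines) and the underlying tables; printing shows the text.
#' @export
make_report <- function(bundle, catalog = load_matrisome_catalog()) {
  lmk <- bundle$landmarks
  lmk <- if (nrow(lmk) > 0) lmk[lmk$landmark, , drop = FALSE] else lmk
  kept <- bundle$interactions
  lb <- matrisome_breakdown(unique(lmk$gene), catalog)
  ib <- interaction_breakdown(kept, catalog)
  subs <- sort(union(lmk$subtype, kept$subtype))
  by_sub <- data.frame(
    subtype = subs,
    n_landmarks = vapply(subs, function(s) sum(lmk$subtype == s),
                         integer(1)),
    n_interactions = vapply(subs, function(s) sum(kept$subtype == s),
                            integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  fmt_pct <- function(b, nm)
    sprintf("%s: %d (%.1f%%)", nm, b$count[b$name == nm],
            b$percent[b$name == nm])
  txt <- c(
    "# Pipeline report",
    sprintf("Landmark genes: %d unique in %d subtypes",
            length(unique(lmk$gene)), length(unique(lmk$subtype))),
    sprintf("Kept interactions: %d (AUC >= %.2f)", nrow(kept),
            attr(bundle$validated, "threshold") %||% 0.8),
    "",
    "## Landmark breakdown",
    vapply(c("core", "associated"), fmt_pct, character(1), b = lb),
    "",
    "## Interaction breakdown",
    vapply(c("core", "associated", ALL_CATEGORIES), fmt_pct, character(1),
           b = ib$overall),
    "",
    "## AUC of kept interactions",
    if (nrow(kept) > 0)
      sprintf("mean %.3f, min %.3f, max %.3f", mean(kept$auc),
              min(kept$auc), max(kept$auc))
    else "none kept",
    "",
    "## Prognostic genes",
    if (!is.null(bundle$prognostics) && nrow(bundle$prognostics) > 0)
      sprintf("%d prognostic (%d age-independent) of %d tested",
              sum(bundle$prognostics$prognostic),
              sum(bundle$prognostics$age_independent),
              nrow(bundle$prognostics))
    else "none tested")
  structure(list(text = txt, by_subtype = by_sub, landmark_breakdown = lb,
                 interaction_breakdown = ib,
                 prognostics = bundle$prognostics),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Score a pipeline run against the planted truth of a synthetic cohort
#'
#' @param bundle a `pipeline_result`.
#' @param truth the cohort's `planted_truth`.
#' @return list: `landmark_recall`, `landmark_precision`,
#'   `interaction_recall`, `interaction_precision` (NA when a denominator
#'   is empty).
#' @export
score_against_truth <- function(bundle, truth) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  lmk <- bundle$landmarks[bundle$landmarks$landmark, , drop = FALSE]
  found <- paste(lmk$subtype, lmk$gene)
  planted <- paste(truth$markers$subtype, truth$markers$gene)
  kept <- bundle$interactions
  found_l <- paste(kept$subtype, kept$gene, kept$regulator)
  planted_l <- paste(truth$links$subtype, truth$links$gene,
                     truth$links$regulator)
  list(landmark_recall = ratio(sum(planted %in% found), length(planted)),
       landmark_precision = ratio(sum(found %in% planted), length(found)),
       interaction_recall = ratio(sum(planted_l %in% found_l),
                                  length(planted_l)),
       interaction_precision = ratio(sum(found_l %in% planted_l),
                                     length(found_l)))
}
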