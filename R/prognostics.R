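## Prognostic assessment of landmark genes within their subtype: mean-split
## stratification, two-group log-rank test, and a Cox proportional-hazards
## model with age as covariate.

#' Split samples by mean expression
#'
#' `high` is expression at or above the subtype mean; `low` below.
#'
#' @param x expression values of one gene within one subtype.
#' @return factor with levels `low`, `high` (high = x >= mean).
#' @export
stratify_by_mean <- function(x) {
  factor(ifelse(x >= mean(x), "high", "low"), levels = c("low", "high"))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square via [survival::survdiff()].
#'
#' @param groups two-level factor.
#' @param time,event survival times (> 0) and event indicators (0/1).
#' @return list `statistic`, `p`, `n_events`.
#' @export
logrank_test <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop_ctx("log-rank needs exactly two groups")
  ev <- tapply(event, groups, sum)
  if (any(ev < 1)) stop_ctx("both groups need at least one event")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  list(statistic = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       n_events = sum(event))
}

#' Age-adjusted Cox model for a two-group split
#'
#' Partial-likelihood fit (Efron tie handling) of
#' `Surv(time, event) ~ group + age`; returns the hazard ratio and Wald p
#' for the group term and the age coefficient. Rank-deficient designs
#' (e.g. a covariate proportional to the group indicator) raise a warning,
#' not an error.
#'
#' @param groups two-level factor (`low`/`high`).
#' @param time,event survival data.
#' @param age age covariate (non-constant).
#' @return list `hr`, `p`, `coef_age`, `p_age`, `collinear`.
#' @export
cox_age_adjusted <- function(groups, time, event, age) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop_ctx("need exactly two groups")
  if (sum(event) < 2) stop_ctx("need at least 2 events")
  if (sd(age) == 0) stop_ctx("age is constant")
  collinear <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ groups + age,
                    ties = "efron"),
    warning = function(w) {
      collinear <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  grow <- grep("^groups", rownames(co))
  if (anyNA(coef(fit))) collinear <- TRUE
  if (collinear)
    warning("Cox fit is unstable (collinear or degenerate covariates)")
  list(hr = unname(co[grow, "exp(coef)"]),
       p = unname(co[grow, "Pr(>|z|)"]),
       coef_age = unname(co["age", "coef"]),
       p_age = unname(co["age", "Pr(>|z|)"]),
       collinear = collinear)
}

#' Prognostic scan of landmark genes
#'
#' For each (subtype, gene): samples are mean-split on the gene's
#' expression, the two groups are compared by log-rank test, and an
#' age-adjusted Cox model estimates the hazard ratio of the high group.
#' A gene is `prognostic` when the log-rank p is below `alpha`, and
#' additionally `age_independent` when the Cox group term stays below
#' `alpha` with age in the model. Genes whose split leaves a group with
#' fewer than 2 samples, or a group without events, are skipped.
#'
#' @param landmarks landmark table (`subtype`, `gene`; rows with a
#'   `landmark` column restrict to `landmark == TRUE`).
#' @param expression gene x sample matrix.
#' @param annotation sample annotation with `time`, `event`, `age`.
#' @param alpha significance level (default 0.05).
#' @return data frame of class `prognostic_result`: group sizes, log-rank
#'   statistic and p, Cox HR and p, direction
#'   (`high_expression_unfavorable` if HR > 1), `prognostic`,
#'   `age_independent`.
#' @export
prognostic_scan <- function(landmarks, expression, annotation,
                            alpha = 0.05) {
  lm <- as.data.frame(landmarks)
  if ("landmark" %in% names(lm)) lm <- lm[lm$landmark, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(lm))) {
    sub <- lm$subtype[i]; gene <- lm$gene[i]
    ann <- annotation[annotation$subtype == sub, , drop = FALSE]
    ann <- ann[complete.cases(ann[, c("time", "event", "age")]), ,
               drop = FALSE]
    if (nrow(ann) < 4 || sum(ann$event) < 2) next
    if (!gene %in% rownames(expression)) next
    x <- expression[gene, ann$sample]
    if (sd(x) == 0) next
    grp <- stratify_by_mean(x)
    if (min(table(grp)) < 2) next
    if (any(tapply(ann$event, grp, sum) < 1)) next
    lr <- logrank_test(grp, ann$time, ann$event)
    cx <- tryCatch(
      suppressWarnings(cox_age_adjusted(grp, ann$time, ann$event, ann$age)),
      error = function(e) NULL)
    if (is.null(cx)) next
    rows[[length(rows) + 1L]] <- data.frame(
      subtype = sub, gene = gene,
      n_low = sum(grp == "low"), n_high = sum(grp == "high"),
      logrank_stat = lr$statistic, logrank_p = lr$p,
      cox_hr = cx$hr, cox_p = cx$p,
      direction = if (cx$hr > 1) "high_expression_unfavorable"
                  else "high_expression_favorable",
      prognostic = lr$p < alpha,
      age_independent = lr$p < alpha & cx$p < alpha,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(subtype = character(0), gene = character(0),
               n_low = integer(0), n_high = integer(0),
               logrank_stat = numeric(0), logrank_p = numeric(0),
               cox_hr = numeric(0), cox_p = numeric(0),
               direction = character(0), prognostic = logical(0),
               age_independent = logical(0))
  rownames(out) <- NULL
  class(out) <- c("prognostic_result", "data.frame")
  out
}
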