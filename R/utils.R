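#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbeta rbinom rexp sd quantile median cor
#'   cor.test prcomp kmeans dnorm hclust cutree as.dist wilcox.test p.adjust
#'   glm binomial fitted lm coef residuals predict var pnorm setNames
#'   complete.cases dist pchisq
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## round-half-up at `digits` decimals; base round() is round-half-even and
## would turn 22.05 into 22.0 where the field's reports print 22.1
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x))
    stop_ctx("'%s' must be a single integer >= %d (got %s)", name, min,
             paste(format(x), collapse = ","))
  as.integer(x)
}

## gene x sample matrices are written/read as TSV: first column holds the row
## identifier, remaining columns are samples
write_tsv_matrix <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_ctx("failed writing '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop_ctx("file not found: '%s'", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

## deterministic per-stage seeds derived from a master seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(cohort = 11L, cluster = 101L, landmarks = 211L, infer = 307L,
            validate = 401L, prognosis = 503L, report = 601L)
  if (!stage %in% names(offs)) stop_ctx("unknown stage '%s'", stage)
  (as.integer(seed) %% 2000000000L) + offs[[stage]]
}
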