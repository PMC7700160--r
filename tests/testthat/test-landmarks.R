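test_that("Mann-Whitney p-values match exhaustive enumeration on tiny samples", {
  ## x = {1,2}, y = {3,4}: all 6 rank configurations, observed is extreme
  p_enum <- mwu_exact_enum(c(1, 2), c(3, 4))
  expect_equal(p_enum, 1 / 3, tolerance = 1e-12)
  p_wt <- wilcox.test(c(1, 2), c(3, 4))$p.value
  expect_equal(p_wt, p_enum, tolerance = 1e-12)
  ## a larger untied case, n = 3 + 4
  set.seed(7)
  x <- sample(seq(0.1, 10, by = 0.1), 3)
  y <- setdiff(sample(seq(0.1, 10, by = 0.1), 7), x)[1:4]
  expect_equal(wilcox.test(x, y)$p.value, mwu_exact_enum(x, y),
               tolerance = 1e-12)
})

test_that("the screen excludes same-cluster subtypes except in the no-exclusion cluster", {
  co <- small_cohort(seed = 13)
  cl <- setNames(c(1, 1, 2, 2, 3, 3), unique(co$annotation$subtype))
  sub <- names(cl)[1]
  scr <- mwu_screen(co$expression, co$annotation, cl, sub,
                    no_exclusion = "3")
  expect_equal(attr(scr, "excluded_subtypes"), names(cl)[2])
  ## markers of the focal subtype are significant and over-expressed
  planted <- co$truth$markers$gene[co$truth$markers$subtype == sub]
  expect_true(all(planted %in% scr$gene[scr$significant]))
  ## no-exclusion cluster keeps its siblings in the background
  sub3 <- names(cl)[5]
  scr3 <- mwu_screen(co$expression, co$annotation, cl, sub3,
                     no_exclusion = "3")
  expect_length(attr(scr3, "excluded_subtypes"), 0)
  ## a cluster covering everything empties the background
  cl_all <- setNames(rep(1, 6), names(cl))
  expect_error(mwu_screen(co$expression, co$annotation, cl_all, sub,
                          no_exclusion = "none"), "background empty")
})

test_that("screen q-values are monotone, bounded, and rank-invariant", {
  co <- small_cohort(seed = 14)
  cl <- setNames(rep(1:3, each = 2), unique(co$annotation$subtype))
  sub <- names(cl)[3]
  scr <- mwu_screen(co$expression, co$annotation, cl, sub)
  expect_true(all(scr$q >= scr$p - 1e-12))
  expect_true(all(scr$q <= 1))
  ## monotone transform of expression leaves the rank test unchanged
  co2 <- co
  co2$expression <- exp(co$expression / 4)
  scr2 <- mwu_screen(co2$expression, co2$annotation, cl, sub)
  expect_equal(scr$p, scr2$p, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg matches hand computation and edge cases", {
  ## hand application of q_i = min_{j >= i} m p_(j) / j
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.4, 5)), rep(0.4, 5))
  expect_equal(benjamini_hochberg(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("coexpression modules recover planted orthogonal blocks exactly", {
  set.seed(21)
  n <- 60
  latent1 <- rnorm(n); latent2 <- rnorm(n)
  block1 <- t(sapply(1:10, function(i) latent1 + rnorm(n, sd = 0.45)))
  block2 <- t(sapply(1:10, function(i) latent2 + rnorm(n, sd = 0.45)))
  expr <- rbind(block1, block2)
  dimnames(expr) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n))
  mods <- coexpression_modules(expr)
  m <- mods$modules
  expect_equal(length(unique(m)), 2)
  expect_equal(length(unique(m[1:10])), 1)
  expect_equal(length(unique(m[11:20])), 1)
  expect_false(m[1] == m[11])
  ## eigengenes have positive variance and track the latent factors
  expect_true(all(apply(mods$eigengenes, 2, var) > 0))
  expect_gt(max(abs(cor(mods$eigengenes[, 1], latent1)),
                abs(cor(mods$eigengenes[, 2], latent1))), 0.9)
})

test_that("a duplicated gene lands in the same module as its copy", {
  set.seed(22)
  n <- 50
  expr <- matrix(rnorm(12 * n), 12, n,
                 dimnames = list(sprintf("g%02d", 1:12),
                                 sprintf("s%02d", 1:n)))
  latent <- rnorm(n)
  expr[1, ] <- latent + rnorm(n, sd = 0.3)
  expr[2, ] <- expr[1, ] + rnorm(n, sd = 1e-6)
  mods <- coexpression_modules(expr, min_module_size = 2)
  expect_equal(mods$modules[["g01"]], mods$modules[["g02"]])
})

test_that("constant genes are dropped from the network with a warning", {
  tx <- toy_expression(n_per = 30, genes = 12, seed = 3)
  tx$expression[5, ] <- 7
  expect_warning(mods <- coexpression_modules(tx$expression), "constant")
  expect_false("g05" %in% names(mods$modules))
})

test_that("independent noise yields no subtype-associated module in most seeds", {
  hits <- 0L; n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    tx <- toy_expression(n_per = 30, genes = 24, seed = 400 + s)
    mods <- coexpression_modules(tx$expression)
    assoc <- eigengene_association(mods, tx$annotation$subtype == "B")
    if (any(assoc$q < 0.05)) hits <- hits + 1L
  }
  expect_gte((n_seeds - hits) / n_seeds, 0.9)
})

test_that("cluster-level genes are the screen/module intersection", {
  co <- small_cohort(seed = 16)
  cl <- setNames(rep(1:3, each = 2), unique(co$annotation$subtype))
  sub <- names(cl)[1]
  scr <- mwu_screen(co$expression, co$annotation, cl, sub)
  scope <- co$annotation$sample[co$annotation$subtype %in% names(cl)[1:2]]
  mods <- coexpression_modules(co$expression[, scope])
  ind <- co$annotation$subtype[match(scope, co$annotation$sample)] == sub
  got <- cluster_level_genes(scr, mods, ind)
  assoc <- eigengene_association(mods, ind)
  keep <- assoc$module[assoc$q < 0.05]
  manual <- intersect(scr$gene[scr$significant],
                      names(mods$modules)[mods$modules %in% keep])
  expect_setequal(got, manual)
  ## empty screen gives an empty set
  scr0 <- scr; scr0$significant <- FALSE
  expect_length(cluster_level_genes(scr0, mods, ind), 0)
})

test_that("adaptive LASSO keeps discriminative genes and drops noise", {
  ## zero-variance gene is never selected
  set.seed(31)
  x <- cbind(a = rnorm(100), b = rep(1, 100), c = rnorm(100))
  y <- rbinom(100, 1, plogis(2 * x[, "a"]))
  sel <- adaptive_lasso_prune(x, y, seed = 1)
  expect_false("b" %in% sel)
  ## one planted gene among 20 noise genes, n = 200
  hits <- 0L; fps <- integer(0); n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    X <- matrix(rnorm(200 * 21), 200, 21,
                dimnames = list(NULL, paste0("g", 1:21)))
    yy <- rbinom(200, 1, plogis(-2 + 3 * X[, 1]))
    if (min(table(yy)) < 10) next
    sel <- adaptive_lasso_prune(X, yy, seed = s)
    if ("g1" %in% sel) hits <- hits + 1L
    fps <- c(fps, sum(sel != "g1"))
  }
  expect_gte(hits / length(fps), 0.9)
  expect_lte(median(fps), 2)
})

test_that("adaptive LASSO selects nothing under label permutation (median)", {
  counts <- integer(0)
  for (s in 1:20) {
    set.seed(2000 + s)
    X <- matrix(rnorm(150 * 10), 150, 10,
                dimnames = list(NULL, paste0("g", 1:10)))
    yy <- sample(rep(0:1, c(100, 50)))
    counts <- c(counts, length(adaptive_lasso_prune(X, yy, seed = s)))
  }
  expect_equal(median(counts), 0)
})

test_that("bimodal EM recovers a separated mixture and is monotone", {
  set.seed(41)
  x <- c(rnorm(250, 0, 1), rnorm(250, 6, 1))
  fit <- fit_bimodal(x)
  expect_lt(abs(fit$mu2 - 6), 0.3)
  expect_lt(abs(fit$mu1 - 0), 0.3)
  expect_true(fit$converged)
  expect_true(fit$separated)
  expect_true(all(diff(fit$loglik) > -1e-9))
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
  expect_true(fit$sigma1 > 0 && fit$sigma2 > 0)
  ## unimodal data fits without error, ending in overlapping components
  set.seed(42)
  fit1 <- fit_bimodal(rnorm(200))
  expect_s3_class(fit1, "bimodal_fit")
  expect_false(fit1$separated)
  expect_true(all(diff(fit1$loglik) > -1e-9))
  ## degenerate inputs are rejected
  expect_error(fit_bimodal(rep(3, 50)), "zero variance")
  expect_error(fit_bimodal(rnorm(5)), ">= 10")
})

test_that("the mean+2SD rule honours its boundary and scale equivariance", {
  ann <- data.frame(sample = sprintf("s%03d", 1:110),
                    subtype = rep(c("A", "B"), c(100, 10)))
  ## subtype B constant at c; solve c so that B's mean sits exactly on the
  ## cohort mean + 2 SD cutoff (the cutoff moves with c, hence the root)
  set.seed(51)
  a <- rnorm(100)
  gap <- function(c) {
    v <- c(a, rep(c, 10))
    c - (mean(v) + 2 * sd(v))
  }
  c_star <- uniroot(gap, c(0, 100), tol = 1e-12)$root
  expr <- matrix(c(a, rep(c_star, 10)), 1, dimnames = list("g1", ann$sample))
  sel <- two_sd_select("g1", "B", expr, ann)
  expect_true(as.logical(sel))
  expect_lt(abs(attr(sel, "margin")), 1e-8)
  ## epsilon below the cutoff is rejected
  expr2 <- expr
  expr2[1, 101:110] <- expr2[1, 101:110] - 1e-3
  expect_false(as.logical(two_sd_select("g1", "B", expr2, ann)))
  ## affine transforms leave the decision unchanged
  expr3 <- 3.7 * expr + 11
  expect_true(as.logical(two_sd_select("g1", "B", expr3, ann)))
  expect_false(as.logical(two_sd_select("g1", "B", 3.7 * expr2 + 11, ann)))
  ## constant gene: degenerate rule
  expr4 <- matrix(5, 1, 110, dimnames = list("g1", ann$sample))
  sel4 <- two_sd_select("g1", "B", expr4, ann)
  expect_false(as.logical(sel4))
  expect_true(attr(sel4, "degenerate"))
})

test_that("landmark intersection keeps provenance and respects set algebra", {
  a <- list(S1 = c("g1", "g2"), S2 = c("g3"))
  b <- list(S1 = c("g2", "g4"), S2 = c("g5"))
  lm <- intersect_landmarks(a, b)
  expect_equal(lm$gene[lm$landmark & lm$subtype == "S1"], "g2")
  expect_false(any(lm$landmark & lm$subtype == "S2"))
  ## identical sets: everything is a landmark
  lm2 <- intersect_landmarks(a, a)
  expect_true(all(lm2$landmark))
  ## disjoint sets: no landmarks
  lm3 <- intersect_landmarks(list(S1 = "g1"), list(S1 = "g9"))
  expect_false(any(lm3$landmark))
})
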