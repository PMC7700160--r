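test_that("design assembly drops constants, standardizes, and honours maps", {
  co <- small_cohort(seed = 2)
  sub <- co$annotation$subtype[1]
  ## plant a constant column
  co$layers$tf["TF_001", co$annotation$subtype == sub] <- 4
  X <- assemble_design(co$layers, co$annotation, sub)
  expect_false("tf:TF_001" %in% colnames(X))
  ## continuous columns standardized, binary mutation left as 0/1
  cont <- grep("^(tf|program|cna):", colnames(X), value = TRUE)
  expect_true(all(abs(colMeans(X[, cont])) < 1e-10))
  expect_true(all(abs(apply(X[, cont], 2, sd) - 1) < 1e-10))
  mut <- grep("^mutation:", colnames(X), value = TRUE)
  if (length(mut) > 0) expect_true(all(X[, mut] %in% c(0, 1)))
  ## accounting: width = sum of layer widths minus dropped columns
  total <- sum(vapply(co$layers, nrow, integer(1)))
  sub_cols <- co$annotation$sample[co$annotation$subtype == sub]
  n_const <- sum(vapply(names(co$layers), function(l)
    sum(apply(co$layers[[l]][, sub_cols, drop = FALSE], 1, sd) == 0),
    numeric(1)))
  expect_equal(ncol(X), total - n_const)
  ## a TF-target map restricts the TF block to the gene's regulators
  map <- data.frame(regulator = "TF_002", target = "GENE_G")
  Xg <- assemble_design(co$layers, co$annotation, sub, gene = "GENE_G",
                        tf_targets = map)
  expect_equal(grep("^tf:", colnames(Xg), value = TRUE), "tf:TF_002")
  Xother <- assemble_design(co$layers, co$annotation, sub,
                            gene = "OTHER", tf_targets = map)
  expect_length(grep("^tf:", colnames(Xother)), 0)
})

test_that("eligibility honours the 10-patient and 10-nonzero boundaries", {
  set.seed(3)
  genes <- c("g1", "g2")
  ann <- data.frame(sample = sprintf("s%02d", 1:30),
                    subtype = rep(c("A", "B", "C"), c(10, 9, 11)))
  expr <- matrix(rnorm(2 * 30, 5), 2, 30,
                 dimnames = list(genes, ann$sample))
  ## g1 in A: exactly 10 non-zero; g2 in A: 9 non-zero
  expr["g2", ann$subtype == "A"][1] <- 0
  lm <- data.frame(subtype = rep(c("A", "B", "C"), each = 2),
                   gene = rep(genes, 3))
  tasks <- eligibility_filter(ann, expr, lm)
  expect_true(any(tasks$subtype == "A" & tasks$gene == "g1"))   # 10 exactly
  expect_false(any(tasks$subtype == "A" & tasks$gene == "g2"))  # 9 non-zero
  expect_false(any(tasks$subtype == "B"))                       # 9 patients
  expect_true(all(c("g1", "g2") %in% tasks$gene[tasks$subtype == "C"]))
  ## empty landmark set yields no tasks
  expect_equal(nrow(eligibility_filter(ann, expr, lm[0, ])), 0)
})

test_that("sPCR selects a perfectly explanatory regressor", {
  set.seed(11)
  X <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(NULL, paste0("r", 1:12)))
  X <- scale(X)
  y <- X[, 5]
  s <- spcr_fit(y, X, seed = 1)
  expect_true("r5" %in% s$regressor)
  expect_equal(s$component[s$regressor == "r5"], 1L)
})

test_that("sPCR selects nothing on independent noise (median over seeds)", {
  counts <- integer(50)
  for (s in 1:50) {
    set.seed(3000 + s)
    X <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(NULL, paste0("r", 1:20)))
    y <- rnorm(50)
    counts[s] <- nrow(spcr_fit(y, X, seed = s))
  }
  expect_equal(median(counts), 0)
  expect_lt(mean(counts > 0), 0.3)
})

test_that("sPCR recovers a planted linear link in most seeds", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(4000 + s)
    X <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(NULL, paste0("r", 1:20)))
    y <- X[, 7] + rnorm(50, sd = 0.5)
    sel <- spcr_fit(y, X, seed = s)
    if ("r7" %in% sel$regressor) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.8)
})

test_that("RFR ranks a step-function regressor first and respects the null", {
  set.seed(21)
  X <- cbind(b = rbinom(60, 1, 0.5),
             matrix(rnorm(60 * 8), 60, 8,
                    dimnames = list(NULL, paste0("r", 1:8))))
  y <- 2 * X[, "b"] + rnorm(60, sd = 0.3)
  r <- rfr_fit(y, X, seed = 2)
  expect_equal(r$regressor[which.max(r$score)], "b")
  ## all-noise designs select nothing in most seeds
  zeroes <- 0L
  for (s in 1:50) {
    set.seed(5000 + s)
    Xn <- matrix(rnorm(50 * 15), 50, 15,
                 dimnames = list(NULL, paste0("r", 1:15)))
    yn <- rnorm(50)
    if (nrow(rfr_fit(yn, Xn, seed = s)) == 0) zeroes <- zeroes + 1L
  }
  expect_gte(zeroes / 50, 0.9)
})

test_that("RFR recovers a planted monotone nonlinear link in most seeds", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(6000 + s)
    X <- matrix(rnorm(50 * 15), 50, 15,
                dimnames = list(NULL, paste0("r", 1:15)))
    y <- (X[, 3] > 0) * 2 + rnorm(50, sd = 0.5)
    if ("r3" %in% rfr_fit(y, X, seed = s)$regressor) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.8)
})

test_that("selection is invariant to regressor column order", {
  set.seed(31)
  X <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(NULL, paste0("r", 1:10)))
  y <- X[, 4] + rnorm(60, sd = 0.4)
  s1 <- spcr_fit(y, X, seed = 9)
  perm <- sample(ncol(X))
  s2 <- spcr_fit(y, X[, perm], seed = 9)
  expect_setequal(s1$regressor, s2$regressor)
  r1 <- rfr_fit(y, X, seed = 9)
  r2 <- rfr_fit(y, X[, perm], seed = 9)
  expect_true("r4" %in% r1$regressor && "r4" %in% r2$regressor)
})

test_that("sPCR beats RFR on linear links and RFR beats sPCR on threshold links", {
  n_seeds <- 20
  lin_s <- lin_r <- thr_s <- thr_r <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(7000 + s)
    X <- matrix(rnorm(50 * 12), 50, 12,
                dimnames = list(NULL, paste0("r", 1:12)))
    y_lin <- X[, 2] + rnorm(50, sd = 0.8)
    y_thr <- (X[, 2] > 0) * 1.2 + rnorm(50, sd = 0.45)
    lin_s[s] <- "r2" %in% spcr_fit(y_lin, X, seed = s)$regressor
    lin_r[s] <- "r2" %in% rfr_fit(y_lin, X, seed = s)$regressor
    thr_s[s] <- "r2" %in% spcr_fit(y_thr, X, seed = s)$regressor
    thr_r[s] <- "r2" %in% rfr_fit(y_thr, X, seed = s)$regressor
  }
  expect_gte(mean(lin_s), mean(lin_r))
  expect_gte(mean(thr_r), mean(thr_s))
})

test_that("triplet extraction unions selections with source tags", {
  s <- data.frame(subtype = "A", gene = "g", regressor = c("r1", "r2"),
                  layer = "tf", score = c(1, 2))
  r <- data.frame(subtype = "A", gene = "g", regressor = c("r2", "r3"),
                  layer = "tf", score = c(3, 4))
  tri <- extract_triplets(s, r)
  src <- setNames(tri$source, tri$regulator)
  expect_equal(src[["r1"]], "spcr")
  expect_equal(src[["r2"]], "both")
  expect_equal(src[["r3"]], "rfr")
  ## disjoint selections are never tagged both
  tri2 <- extract_triplets(s[1, ], r[2, ])
  expect_false(any(tri2$source == "both"))
  ## stable ordering by (subtype, gene, layer, regulator)
  expect_equal(tri$regulator, sort(tri$regulator))
  ## empty inputs give an empty triplet set
  tri0 <- extract_triplets(list(), list())
  expect_s3_class(tri0, "triplet_set")
  expect_equal(nrow(tri0), 0)
})
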