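test_that("mean-split stratification follows its boundary convention", {
  g <- stratify_by_mean(c(1, 2, 3, 4))          # mean 2.5
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  ## a value exactly at the mean goes to the high group
  g2 <- stratify_by_mean(c(1, 2, 3))            # mean 2
  expect_equal(as.character(g2)[2], "high")
  ## constant input leaves one side empty (all high)
  g3 <- stratify_by_mean(rep(5, 6))
  expect_true(all(g3 == "high"))
})

test_that("log-rank matches a hand-built O-E/V table", {
  ## group A: times 1, 2 (events); group B: times 3, 4 (events)
  ## t=1: nA=2,nB=2,d=1 -> E_A=0.5,  V=2*2*1*3/(16*3)=0.25
  ## t=2: nA=1,nB=2,d=1 -> E_A=1/3,  V=1*2*1*2/(9*2)=2/9
  ## t=3,4: nA=0 -> E_A=0, V=0
  ## O_A=2, E_A=5/6, V=0.25+2/9 -> chi2 = (2-5/6)^2/V
  grp <- factor(c("A", "A", "B", "B"))
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
  lr <- logrank_test(grp, time, event)
  chi_hand <- (2 - 5 / 6)^2 / (0.25 + 2 / 9)
  expect_equal(lr$statistic, chi_hand, tolerance = 1e-6)
  expect_equal(lr$p, pchisq(chi_hand, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("identical survival in both groups gives statistic 0, p = 1", {
  time <- rep(c(1, 2, 3, 4, 5), 2)
  event <- rep(1, 10)
  grp <- factor(rep(c("A", "B"), each = 5))
  lr <- logrank_test(grp, time, event)
  expect_equal(lr$statistic, 0, tolerance = 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-10)
  ## degenerate groupings are rejected
  expect_error(logrank_test(factor(rep("A", 10)), time, event),
               "two groups")
  expect_error(logrank_test(grp, time, c(rep(0, 5), rep(1, 5))),
               "at least one event")
})

test_that("log-rank equals the Cox score test", {
  set.seed(12)
  for (i in 1:5) {
    n <- 60
    grp <- factor(sample(c("low", "high"), n, replace = TRUE),
                  levels = c("low", "high"))
    time <- rexp(n, ifelse(grp == "high", 0.02, 0.01))
    event <- rbinom(n, 1, 0.8)
    if (min(tapply(event, grp, sum)) < 1) next
    lr <- logrank_test(grp, time, event)
    cox <- survival::coxph(survival::Surv(time, event) ~ grp)
    expect_equal(lr$statistic, summary(cox)$sctest[["test"]],
                 tolerance = 1e-6)
  }
})

test_that("log-rank detects a strong hazard ratio in most seeds", {
  hits <- 0L; n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    set.seed(8000 + s)
    n <- 200
    grp <- factor(rep(c("low", "high"), each = n / 2),
                  levels = c("low", "high"))
    time <- rexp(n, ifelse(grp == "high", 0.003, 0.001))
    event <- rbinom(n, 1, 0.7)
    lr <- logrank_test(grp, time, event)
    if (lr$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("results are invariant to time-unit rescaling", {
  set.seed(13)
  n <- 80
  grp <- factor(rep(c("low", "high"), each = 40), levels = c("low", "high"))
  time <- rexp(n, ifelse(grp == "high", 0.004, 0.001))
  event <- rbinom(n, 1, 0.8)
  age <- rnorm(n, 60, 8)
  lr1 <- logrank_test(grp, time, event)
  lr2 <- logrank_test(grp, time * 365.25, event)
  expect_equal(lr1$statistic, lr2$statistic, tolerance = 1e-10)
  cx1 <- cox_age_adjusted(grp, time, event, age)
  cx2 <- cox_age_adjusted(grp, time * 365.25, event, age)
  expect_equal(cx1$hr, cx2$hr, tolerance = 1e-6)
})

test_that("an uninformative age covariate leaves the group HR close to the univariate fit", {
  set.seed(14)
  n <- 150
  grp <- factor(rep(c("low", "high"), each = n / 2),
                levels = c("low", "high"))
  time <- rexp(n, ifelse(grp == "high", 0.004, 0.001))
  event <- rbinom(n, 1, 0.8)
  age <- sample(rnorm(n, 60, 8))  # shuffled, unrelated to survival
  cx <- cox_age_adjusted(grp, time, event, age)
  uni <- survival::coxph(survival::Surv(time, event) ~ grp)
  se <- summary(uni)$coefficients[1, "se(coef)"]
  expect_lt(abs(log(cx$hr) - coef(uni)[1]), 2 * se)
})

test_that("Cox/log-rank type-I error is near nominal under the null", {
  reps <- 200L
  p_lr <- p_cox <- numeric(reps)
  for (s in seq_len(reps)) {
    set.seed(9000 + s)
    n <- 60
    grp <- factor(rep(c("low", "high"), each = n / 2),
                  levels = c("low", "high"))
    time <- rexp(n, 0.002)
    event <- rbinom(n, 1, 0.7)
    age <- rnorm(n, 60, 8)
    if (min(tapply(event, grp, sum)) < 1) { p_lr[s] <- NA; next }
    p_lr[s] <- logrank_test(grp, time, event)$p
    p_cox[s] <- cox_age_adjusted(grp, time, event, age)$p
  }
  expect_lt(abs(mean(p_lr < 0.05, na.rm = TRUE) - 0.05), 0.04)
  expect_lt(abs(mean(p_cox < 0.05, na.rm = TRUE) - 0.05), 0.04)
})

test_that("a collinear covariate warns without crashing", {
  set.seed(15)
  n <- 60
  grp <- factor(rep(c("low", "high"), each = 30), levels = c("low", "high"))
  time <- rexp(n, ifelse(grp == "high", 0.004, 0.001))
  event <- rep(1, n)
  age <- as.numeric(grp) * 10     # proportional duplicate of the group
  expect_warning(cx <- cox_age_adjusted(grp, time, event, age),
                 "collinear|unstable")
  expect_true(is.list(cx))
})

test_that("prognostic scan flags planted hazards and respects age mediation", {
  ## planted prognostic gene: high expression doubles the hazard
  hits <- 0L; n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    set.seed(10000 + s)
    n <- 100
    x <- rnorm(n, 8, 2)
    grp_hi <- x >= mean(x)
    time <- rexp(n, 0.001 * exp(1.0 * grp_hi))
    ann <- data.frame(sample = sprintf("s%03d", 1:n), subtype = "S1",
                      time = time, event = rbinom(n, 1, 0.75),
                      age = rnorm(n, 60, 8))
    expr <- matrix(x, 1, dimnames = list("g1", ann$sample))
    res <- prognostic_scan(data.frame(subtype = "S1", gene = "g1"),
                           expr, ann)
    if (nrow(res) == 1 && res$prognostic) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)

  ## age fully mediating the split: prognostic but not age-independent
  set.seed(16)
  n <- 200
  x <- rnorm(n, 8, 2)
  grp_hi <- x >= mean(x)
  age <- ifelse(grp_hi, 75, 50) + rnorm(n, 0, 0.5)
  time <- rexp(n, 0.0005 * exp(0.08 * (age - 60)))
  ann <- data.frame(sample = sprintf("s%03d", 1:n), subtype = "S1",
                    time = time, event = rbinom(n, 1, 0.85),
                    age = age)
  expr <- matrix(x, 1, dimnames = list("g1", ann$sample))
  res <- prognostic_scan(data.frame(subtype = "S1", gene = "g1"), expr, ann)
  expect_true(res$prognostic)
  expect_false(res$age_independent)

  ## no events in the subtype: empty table
  ann0 <- ann; ann0$event <- 0
  expect_equal(nrow(prognostic_scan(data.frame(subtype = "S1", gene = "g1"),
                                    expr, ann0)), 0)
})
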