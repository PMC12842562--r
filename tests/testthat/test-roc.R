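test_that("AUC handles perfect separation, partial ordering, and ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_warning(r <- roc_auc(rep(2, 6), c(0, 0, 0, 1, 1, 1)), "constant")
  expect_equal(r$auc, 0.5)
  expect_equal(r$var, 0)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both")
})

test_that("placement-value AUC equals exhaustive pair counting", {
  set.seed(61)
  for (rep in 1:150) {
    n <- sample(4:12, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(1:5, n, replace = TRUE)
    expect_equal(suppressWarnings(roc_auc(scores, labels)$auc),
                 brute_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("DeLong variance and p agree with an independent implementation", {
  requireNamespace("pROC", quietly = TRUE)
  set.seed(67)
  for (rep in 1:20) {
    labels <- c(rep(1, 15), rep(0, 60))
    a <- rnorm(75) + labels; b <- rnorm(75) + 0.5 * labels
    mine <- delong_paired(a, b, labels)
    r1 <- pROC::roc(labels, a, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
    r2 <- pROC::roc(labels, b, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
    ref <- pROC::roc.test(r1, r2, method = "delong")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(roc_auc(a, labels)$var, as.numeric(pROC::var(r1)),
                 tolerance = 1e-10)
  }
})

test_that("DeLong paired test is antisymmetric and null on identical scores", {
  set.seed(71)
  labels <- rbinom(80, 1, 0.3)
  a <- rnorm(80); b <- rnorm(80)
  ab <- delong_paired(a, b, labels)
  ba <- delong_paired(b, a, labels)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$z, -ba$z)
  self <- delong_paired(a, a, labels)
  expect_true(self$degenerate)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$p, 1)
})

test_that("DeLong test holds its nominal size with moderate case counts", {
  set.seed(73)
  rej <- 0
  for (i in 1:400) {
    labels <- c(rep(1, 50), rep(0, 150))
    if (delong_paired(rnorm(200), rnorm(200), labels)$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 400, 0.02)
  expect_lt(rej / 400, 0.09)
})

test_that("DeLong standard error shrinks as 1/sqrt(n)", {
  set.seed(79)
  base_s <- c(rnorm(40, 1), rnorm(160))
  base_l <- c(rep(1, 40), rep(0, 160))
  se1 <- roc_auc(base_s, base_l)$se
  se4 <- roc_auc(rep(base_s, 4), rep(base_l, 4))$se
  expect_equal(se4 / se1, 0.5, tolerance = 0.1)
})

test_that("Hanley-McNeil z reduces to closed forms", {
  eq <- hanley_mcneil_z(0.85, 0.02, 0.85, 0.02)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  big <- hanley_mcneil_z(0.9, 0.01, 0.9 - 5 * sqrt(2e-4), 0.01)
  expect_lt(big$p, 1e-5)
  expect_error(hanley_mcneil_z(0.8, 0, 0.7, 0), "zero")
})

test_that("Youden cutoff maximizes J and favors specificity on ties", {
  cut <- youden_cutoff(c(0, 1, 2, 3), c(0, 0, 1, 1))
  expect_equal(cut$cutoff, 2)
  expect_equal(cut$sensitivity, 100)
  expect_equal(cut$specificity, 100)
  set.seed(83)
  scores <- sample(0:10, 300, replace = TRUE)
  labels <- as.integer(scores >= 4)
  c4 <- youden_cutoff(scores, labels)
  expect_equal(c4$cutoff, 4)
  expect_equal(c4$youden_j, 1)
  # invariant under strictly monotone transforms
  labels2 <- rbinom(300, 1, plogis(scores - 5))
  if (length(unique(labels2)) == 2) {
    raw <- youden_cutoff(scores, labels2)
    trans <- youden_cutoff(3 * scores + 7, labels2)
    expect_equal(trans$youden_j, raw$youden_j)
    expect_equal(trans$cutoff, 3 * raw$cutoff + 7)
  }
  # J of the best threshold is never negative
  rand <- youden_cutoff(sample(0:5, 100, TRUE), rbinom(100, 1, 0.3))
  expect_gte(rand$youden_j, 0)
})

test_that("McNemar switches between exact and corrected chi-square", {
  mk <- function(b, cc) {
    list(a = c(rep(TRUE, b), rep(FALSE, cc)),
         b = c(rep(FALSE, b), rep(TRUE, cc)))
  }
  p1 <- mcnemar_paired(mk(10, 10)$a, mk(10, 10)$b)
  expect_equal(p1, 1)
  expect_equal(mcnemar_paired(mk(20, 0)$a, mk(20, 0)$b), 2 * 0.5^20,
               tolerance = 1e-12)
  expect_equal(mcnemar_paired(logical(5), logical(5)), 1)
  # asymptotic branch agrees with stats::mcnemar.test
  pair <- mk(22, 8)
  tab <- matrix(c(0, 8, 22, 0), 2, 2)
  expect_equal(mcnemar_paired(pair$a, pair$b),
               stats::mcnemar.test(tab, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("two-proportion chi-square matches prop.test and edge rules", {
  expect_equal(chisq_two_proportions(30, 100, 30, 100), 1)
  expect_lt(chisq_two_proportions(80, 100, 20, 100), 1e-10)
  expect_warning(p <- chisq_two_proportions(100, 100, 50, 50), "degenerate")
  expect_equal(p, 1)
  expect_error(chisq_two_proportions(1, 0, 1, 10), "positive")
})

test_that("predictive values follow Bayes' rule", {
  expect_equal(unname(predictive_values(1, 1, 0.5)), c(1, 1))
  pv <- predictive_values(0.80, 0.84, 0.20)
  expect_equal(unname(pv["ppv"]), 0.16 / (0.16 + 0.128), tolerance = 1e-12)
  expect_equal(unname(round(pv["ppv"], 2)), 0.56)
  low <- predictive_values(0.80, 0.84, 0.038)
  expect_gt(unname(low["npv"]), 0.99)
  expect_equal(unname(low["npv"]), 0.9907, tolerance = 1e-4)
  expect_error(predictive_values(1.2, 0.8, 0.1), "fractions")
  expect_error(predictive_values(0, 1, 0.5), "denominator")
})

test_that("cutoff sweep reports per-prevalence predictive values", {
  set.seed(89)
  scores <- sample(0:10, 400, TRUE)
  labels <- rbinom(400, 1, plogis(scores - 6))
  tab <- cutoff_sweep(scores, labels)
  expect_true(all(c("ppv_3.8", "npv_20") %in% names(tab)))
  expect_equal(nrow(tab), length(unique(scores)))
  expect_true(all(tab$youden_j >= -1 & tab$youden_j <= 1))
})
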