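test_that("the item characteristic curve matches its closed form", {
  # b is the 50%-endorsement point by definition
  expect_equal(icc(0.60, a = 2.47, b = 0.60), 0.5)
  expect_equal(icc(0, a = 1.70, b = 0.83), 1 / (1 + exp(1.70 * 0.83)))
  expect_equal(icc(50, a = 0.5, b = 2), 1, tolerance = 1e-8)
  expect_true(all(diff(icc(seq(-4, 4, 0.1), 1.3, 0.2)) > 0))
  expect_error(icc(0, a = 0, b = 0), "must be > 0")
})

test_that("item information is unimodal at b with height a^2/4", {
  expect_equal(item_information(0.7, a = 2, b = 0.7), 1)
  grid <- seq(-6, 6, 0.05)
  info <- item_information(grid, a = 1.8, b = 0.4)
  expect_equal(grid[which.max(info)], 0.4, tolerance = 0.051)
  expect_true(all(info <= item_information(0.4, 1.8, 0.4) + 1e-12))
  expect_lt(item_information(12, 1.8, 0.4), 1e-6)
  expect_lt(item_information(-12, 1.8, 0.4), 1e-6)
  # I(theta) = a * P'(theta): check against a numerical derivative of icc
  h <- 1e-5
  num <- 1.8 * (icc(0.9 + h, 1.8, 0.4) - icc(0.9 - h, 1.8, 0.4)) / (2 * h)
  expect_equal(item_information(0.9, 1.8, 0.4), num, tolerance = 1e-6)
})

test_that("expected test information is additive and monotone in items", {
  bank <- gds_item_bank()
  g <- latent_grid()
  sub <- c(1, 4, 6)
  expect_equal(expected_test_information(bank, c(sub, 16), g),
               expected_test_information(bank, sub, g) +
                 expected_test_information(bank, 16, g))
  expect_gt(expected_test_information(bank, NULL, g),
            expected_test_information(bank, gds_scales()$`GDS10-IRT`, g))
  expect_error(expected_test_information(bank, integer(0)), "non-empty")
})

test_that("EM recovers difficulty on a two-item bank at large n", {
  bank <- item_bank(a = c(1.5, 1.5), b = c(-1, 1))
  sim <- simulate_2pl(50000, bank, seed = 31)
  fit <- fit_2pl(sim$responses)
  expect_true(attr(fit, "converged"))
  expect_lt(max(abs(fit$b - bank$b)), 0.05)
  # marginal log-likelihood is non-decreasing across EM cycles
  expect_true(all(diff(attr(fit, "loglik_trace")) > -1e-6))
})

test_that("EM recovers the published 30-item bank structure at n = 5000", {
  bank <- gds_item_bank()
  sim <- simulate_2pl(5000, bank, seed = 37)
  fit <- fit_2pl(sim$responses)
  expect_gt(cor(fit$a, bank$a), 0.9)
  expect_lt(mean(abs(fit$b - bank$b)), 0.25)
  # fitted difficulty anti-correlates with endorsement rate
  expect_lt(cor(fit$b, colMeans(sim$responses), method = "spearman"), -0.8)
})

test_that("items without trait dependence shrink to the discrimination floor", {
  set.seed(41)
  X <- cbind(item_01 = rbinom(5000, 1, 0.5), item_02 = rbinom(5000, 1, 0.5))
  fit <- suppressWarnings(fit_2pl(X))
  expect_true(all(fit$a < 0.3))
})

test_that("degenerate inputs are excluded or rejected", {
  set.seed(43)
  X <- cbind(item_01 = rbinom(200, 1, 0.5), item_02 = rbinom(200, 1, 0.5),
             item_03 = rep(1L, 200))
  expect_warning(fit <- fit_2pl(X), "degenerate")
  expect_equal(nrow(fit), 2)
  expect_equal(attr(fit, "excluded"), 3L)
  X2 <- X[, 1:2]; X2[1, 1] <- 2
  expect_error(fit_2pl(X2), "binary")
  expect_error(fit_2pl(X[, 1, drop = FALSE]), "at least 2")
})

test_that("missing responses are tolerated under MAR", {
  bank <- item_bank(a = c(1.5, 1.2, 1.8), b = c(-0.5, 0.3, 0.8))
  sim <- simulate_2pl(8000, bank, seed = 47)
  X <- sim$responses
  X[sample(length(X), length(X) %/% 10)] <- NA
  X[1, ] <- NA  # one all-missing row
  expect_warning(fit <- fit_2pl(X), "all-missing")
  expect_lt(max(abs(fit$b - bank$b)), 0.2)
})

test_that("items rank by discrimination with AUC then index tie-breaks", {
  bank <- gds_item_bank()
  rk <- rank_items(bank)
  expect_equal(rk[1], 16L)
  expect_setequal(rk[1:10], c(1L, 4L, 6L, 10L, 11L, 16L, 17L, 21L, 22L, 25L))
  flat <- item_bank(a = rep(1, 4), b = c(0, 0, 0, 0), item = c(3, 1, 4, 2))
  expect_equal(rank_items(flat), 1:4)
  tied <- item_bank(a = c(1, 1), b = c(0, 0), item = 1:2,
                    item_auc = c(0.6, 0.7))
  expect_equal(rank_items(tied), c(2L, 1L))
})

test_that("per-item AUC equals exhaustive pair counting", {
  set.seed(53)
  labels <- rbinom(2000, 1, 0.3)
  x <- ifelse(labels == 1, rbinom(2000, 1, 0.8), rbinom(2000, 1, 0.2))
  a1 <- item_auc(x, labels)
  # binary predictor: AUC = (sens + spec) / 2; population value 0.80
  sens <- mean(x[labels == 1]); spec <- mean(1 - x[labels == 0])
  expect_equal(a1, (sens + spec) / 2, tolerance = 1e-12)
  expect_equal(a1, 0.80, tolerance = 0.05)
  small <- sample(2000, 60)
  expect_equal(item_auc(x[small], labels[small]),
               brute_auc(x[small], labels[small]), tolerance = 1e-12)
  expect_equal(item_auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_error(item_auc(c(1, 0), c(1, 1)), "both")
})

test_that("Cronbach's alpha behaves at its boundaries and in simulation", {
  set.seed(59)
  x <- rbinom(500, 1, 0.5)
  expect_equal(cronbach_alpha(cbind(a = x, b = x)), 1)
  indep <- matrix(rbinom(4000, 1, 0.5), ncol = 4)
  expect_lt(abs(cronbach_alpha(indep)), 0.15)
  expect_error(cronbach_alpha(cbind(x)), "at least 2")
  expect_error(cronbach_alpha(cbind(a = x, b = rep(1, 500))), "zero-variance")
  # the IRT-selected 10-item scale is internally consistent in simulation
  al <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(seed = 900 + s))
    cronbach_alpha(co$responses, gds_scales()$`GDS10-IRT`)
  }, numeric(1))
  expect_true(all(al > 0.75 & al < 0.90))
})
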