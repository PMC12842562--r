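test_that("cohort configuration rejects degenerate inputs", {
  expect_error(cohort_config(n_subjects = 0), "positive")
  expect_error(cohort_config(prevalence = 0), "between 0 and 1")
  expect_error(cohort_config(prevalence = 1), "between 0 and 1")
  expect_error(cohort_config(theta_case = c(1.7, 0)), "sd > 0")
  expect_error(cohort_config(dif_offsets = list(female = c("99" = 1))),
               "absent from the item bank")
  expect_error(cohort_config(dif_offsets = list(martian = c("1" = 1))),
               "covariate levels")
})

test_that("generation is deterministic, binary, and prevalence-calibrated", {
  cfg <- cohort_config(n_subjects = 3000, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$responses, b$responses)
  expect_identical(a$diagnosis, b$diagnosis)
  expect_true(all(a$responses %in% 0:1))
  # binomial sampling error around the configured prevalence
  expect_lt(abs(mean(a$diagnosis) - 0.038),
            4 * sqrt(0.038 * 0.962 / 3000))
  # clinic subjects carry a higher diagnosis rate
  big <- generate_cohort(cohort_config(n_subjects = 60000, seed = 8))
  rate <- tapply(big$diagnosis, big$covariates$source, mean)
  expect_gt(rate[["clinic"]], 2.5 * rate[["community"]])
})

test_that("a near-Guttman item behaves as a step function at high trait", {
  bank <- item_bank(a = c(50, 1), b = c(0, 0))
  cfg <- cohort_config(n_subjects = 400, prevalence = 0.5,
                       theta_case = c(2, 1e-6), theta_control = c(-2, 1e-6),
                       item_bank = bank, seed = 3)
  co <- generate_cohort(cfg)
  expect_true(all(co$responses[co$diagnosis == 1, "item_01"] == 1))
  expect_true(all(co$responses[co$diagnosis == 0, "item_01"] == 0))
})

test_that("endorsement frequency decreases in difficulty", {
  bank <- item_bank(a = rep(1.5, 7), b = seq(-1.5, 1.5, by = 0.5))
  co <- generate_cohort(cohort_config(n_subjects = 20000, prevalence = 0.5,
                                      theta_case = c(0, 1),
                                      theta_control = c(0, 1),
                                      item_bank = bank, seed = 5))
  rates <- colMeans(co$responses)
  expect_true(all(diff(rates) < 0))
})

test_that("empirical endorsement converges to the 2PL curve", {
  bank <- item_bank(a = c(2.47, 0.9), b = c(0.6, -0.5))
  sim <- simulate_2pl(50000, bank, seed = 11)
  bins <- cut(sim$theta, seq(-2.5, 2.5, by = 0.25))
  for (j in 1:2) {
    emp <- tapply(sim$responses[, j], bins, mean)
    counts <- table(bins)
    mids <- seq(-2.5 + 0.125, 2.5 - 0.125, by = 0.25)
    keep <- counts >= 300
    dev <- abs(emp[keep] - icc(mids[keep], bank$a[j], bank$b[j]))
    expect_lt(max(dev), 0.03)
  }
})

test_that("without DIF offsets, groups endorse equally at matched trait", {
  co <- generate_cohort(cohort_config(n_subjects = 40000, prevalence = 0.5,
                                      theta_case = c(0, 1),
                                      theta_control = c(0, 1), seed = 13))
  mid <- abs(co$true_theta) < 0.5
  for (j in c(1, 16)) {
    rf <- mean(co$responses[mid & co$covariates$sex == "female", j])
    rm_ <- mean(co$responses[mid & co$covariates$sex == "male", j])
    expect_lt(abs(rf - rm_), 0.03)
  }
})

test_that("DIF offsets shift endorsement for the targeted group only", {
  cfg <- cohort_config(n_subjects = 30000, prevalence = 0.5,
                       theta_case = c(0, 1), theta_control = c(0, 1),
                       dif_offsets = list(female = c("25" = 1.0)), seed = 17)
  co <- generate_cohort(cfg)
  f <- co$covariates$sex == "female"
  expect_gt(mean(co$responses[f, 25]) - mean(co$responses[!f, 25]), 0.1)
  expect_lt(abs(mean(co$responses[f, 16]) - mean(co$responses[!f, 16])), 0.03)
})

test_that("stratified split allocates exact integer counts per stratum", {
  co <- manual_cohort(c(rep(1, 100), rep(0, 2900)))
  sp <- stratified_split(co, 0.5, seed = 1)
  expect_equal(sum(sp$dev$diagnosis), 50)
  expect_equal(sum(sp$val$diagnosis), 50)
  expect_equal(length(sp$dev$diagnosis), 1500)
  # union is a partition
  expect_setequal(c(sp$dev_idx, sp$val_idx), seq_len(3000))
  expect_length(intersect(sp$dev_idx, sp$val_idx), 0)
})

test_that("the default cohort splits into halves of 3262 and 3263", {
  co <- generate_cohort(cohort_config(seed = 21))
  sp <- stratified_split(co, 0.5, seed = 2)
  expect_equal(sort(c(length(sp$dev$diagnosis), length(sp$val$diagnosis))),
               c(3262, 3263))
  # stratification: per-half case counts differ by at most 1 per stratum
  for (src in c("community", "clinic")) {
    nd <- sum(sp$dev$diagnosis[sp$dev$covariates$source == src])
    nv <- sum(sp$val$diagnosis[sp$val$covariates$source == src])
    expect_lte(abs(nd - nv), 1)
  }
  # deterministic given seed
  sp2 <- stratified_split(co, 0.5, seed = 2)
  expect_identical(sp$dev_idx, sp2$dev_idx)
})

test_that("tiny strata are pushed to the larger half with a warning", {
  co <- manual_cohort(c(1, rep(0, 99)),
                      source = c("clinic", rep("community", 99)))
  expect_warning(sp <- stratified_split(co, 0.5, seed = 1),
                 "fewer than 2")
  expect_equal(sum(sp$val$diagnosis), 1)  # ratio 0.5: larger half is val
})

test_that("cohort CSV round-trips through the reader (already keyed)", {
  co <- generate_cohort(cohort_config(n_subjects = 120, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_response_csv(path, keymap = NULL)
  expect_equal(dim(back$responses), dim(co$responses))
  expect_true(all(back$responses == co$responses))
  expect_equal(back$diagnosis, co$diagnosis)
  expect_equal(back$covariates$source, co$covariates$source)
})
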