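# shared fixtures built in code

# exhaustive case-control pair counting; the independent AUC oracle
brute_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  total <- 0
  for (xi in x) for (yj in y) {
    total <- total + (xi > yj) + 0.5 * (xi == yj)
  }
  total / (length(x) * length(y))
}

# simulate 2PL responses with a standard-normal trait (calibration regime)
simulate_2pl <- function(n, bank, seed) {
  set.seed(seed)
  theta <- rnorm(n)
  J <- nrow(bank)
  eta <- outer(theta, bank$a * 0) # n x J zeros
  for (j in seq_len(J)) eta[, j] <- bank$a[j] * (theta - bank$b[j])
  X <- matrix(as.integer(runif(n * J) < plogis(eta)), n, J)
  colnames(X) <- sprintf("item_%02d", bank$item)
  list(responses = X, theta = theta)
}

# hand-build a cohort object from parts (for split tests)
manual_cohort <- function(diagnosis, source = NULL) {
  n <- length(diagnosis)
  if (is.null(source)) source <- rep("community", n)
  structure(list(
    responses = matrix(0L, n, 2, dimnames = list(NULL, c("item_01", "item_02"))),
    diagnosis = as.integer(diagnosis),
    covariates = data.frame(sex = rep("female", n),
                            age_group = rep("young_old", n),
                            source = source, stringsAsFactors = FALSE),
    true_theta = numeric(n),
    config = cohort_config(n_subjects = n)),
    class = "cohort")
}

# minimal reduction trace for stopping-rule tests
manual_trace <- function(k, dev_p, val_p, info = NULL) {
  if (is.null(info)) info <- k  # linear placeholder
  tr <- data.frame(k = k,
                   items = vapply(k, function(kk)
                     paste(seq_len(kk), collapse = ","), character(1)),
                   dev_auc = 0.85, dev_ci_lo = 0.8, dev_ci_hi = 0.9,
                   dev_delta = 0, dev_p = dev_p,
                   val_auc = 0.85, val_ci_lo = 0.8, val_ci_hi = 0.9,
                   val_delta = 0, val_p = val_p,
                   cross_delta = 0, cross_p = 1, info = info)
  attr(tr, "alpha") <- 0.05
  class(tr) <- c("reduction_trace", "data.frame")
  tr
}
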