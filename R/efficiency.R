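# fast Mann-Whitney AUC via midranks (no variance); used inside bootstrap
fast_auc <- function(scores, labels) {
  r <- rank(scores)
  m <- sum(labels == 1L)
  n <- length(labels) - m
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

#' Efficiency ratio: AUC per item
#'
#' The scale-economy statistic AUC divided by the number of items,
#' quantifying diagnostic accuracy achieved per item administered.
#'
#' @param auc AUC in \[0, 1\].
#' @param n_items number of items, at least 1.
#' @return `auc / n_items`.
#' @examples
#' efficiency_ratio(0.883, 30)  # ~0.029
#' @export
efficiency_ratio <- function(auc, n_items) {
  if (n_items < 1) stop("'n_items' must be >= 1", call. = FALSE)
  if (auc < 0 || auc > 1) stop("'auc' must lie in [0, 1]", call. = FALSE)
  auc / n_items
}

#' Efficiency ratio with bootstrap standard error
#'
#' Point efficiency ratio of a scale plus the standard deviation of the
#' ratio over `B` subject resamples (with replacement).
#'
#' @param scores scale sum scores.
#' @param n_items number of items in the scale.
#' @param labels binary diagnosis labels.
#' @param name scale label carried through to reports.
#' @param B bootstrap iterations (default 1000).
#' @param seed RNG seed; resampling is deterministic given it.
#' @return Object of class `efficiency_result`: `name`, `auc`, `n_items`,
#'   `efficiency`, `se`, `B`, `seed`, `n_skipped`.
#' @export
bootstrap_efficiency <- function(scores, n_items, labels, name = "scale",
                                 B = 1000L, seed = 1L) {
  labels <- check_binary_labels(labels)
  set.seed(seed)
  n <- length(scores)
  ratios <- rep(NA_real_, B)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- resample_both_classes(n, labels)
    if (is.null(idx)) { skipped <- skipped + 1L; next }
    ratios[b] <- fast_auc(scores[idx], labels[idx]) / n_items
  }
  ratios <- ratios[!is.na(ratios)]
  structure(list(name = name, auc = fast_auc(scores, labels),
                 n_items = n_items,
                 efficiency = efficiency_ratio(fast_auc(scores, labels),
                                               n_items),
                 se = stats::sd(ratios), B = B, seed = seed,
                 n_skipped = skipped),
            class = "efficiency_result")
}

# one bootstrap index draw, redrawn (up to a cap) if a class is missing
resample_both_classes <- function(n, labels, retry_cap = 10L) {
  for (r in seq_len(retry_cap)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) == 2L) return(idx)
  }
  NULL
}

#' Bootstrap comparison of two efficiency ratios (same subjects)
#'
#' In each of `B` iterations subjects are resampled with replacement
#' (pairing between scales preserved), both AUCs and efficiency ratios are
#' recomputed, and the difference A minus B recorded. Significance by the
#' percentile method: the comparison is significant iff the 95% bootstrap
#' CI of the difference excludes zero. An approximate two-sided bootstrap
#' p-value `2 * min(F(0), 1 - F(0))` is reported alongside; the CI rule is
#' the decision criterion.
#'
#' @param scores_a,scores_b sum scores of the two scales on the same
#'   subjects.
#' @param items_a,items_b their item counts.
#' @param labels binary diagnosis labels.
#' @param B bootstrap iterations (>= 100; default 1000).
#' @param seed RNG seed.
#' @param conf_level CI level (default 0.95).
#' @return List of class `efficiency_comparison`: `diff` (point estimate),
#'   `ci`, `significant`, `boot_p`, `boot_mean`, `B_effective`,
#'   `n_skipped`.
#' @export
bootstrap_compare_within <- function(scores_a, items_a, scores_b, items_b,
                                     labels, B = 1000L, seed = 1L,
                                     conf_level = 0.95) {
  if (length(scores_a) != length(scores_b)) {
    stop("both scales must score the same subjects", call. = FALSE)
  }
  if (B < 100L) stop("'B' must be at least 100", call. = FALSE)
  labels <- check_binary_labels(labels)
  set.seed(seed)
  n <- length(labels)
  diffs <- rep(NA_real_, B)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- resample_both_classes(n, labels)
    if (is.null(idx)) { skipped <- skipped + 1L; next }
    lb <- labels[idx]
    diffs[b] <- fast_auc(scores_a[idx], lb) / items_a -
      fast_auc(scores_b[idx], lb) / items_b
  }
  diffs <- diffs[!is.na(diffs)]
  alpha2 <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(diffs, c(alpha2, 1 - alpha2)))
  point <- fast_auc(scores_a, labels) / items_a -
    fast_auc(scores_b, labels) / items_b
  p_le <- mean(diffs <= 0)
  p_ge <- mean(diffs >= 0)
  structure(list(diff = point, ci = ci,
                 significant = ci[1] > 0 || ci[2] < 0,
                 boot_p = max(2 * min(p_le, p_ge), 2 / length(diffs)),
                 boot_mean = mean(diffs), B_effective = length(diffs),
                 n_skipped = skipped),
            class = "efficiency_comparison")
}

#' @export
print.efficiency_comparison <- function(x, ...) {
  cat(sprintf("efficiency difference %+.4f (95%% boot CI %.4f to %.4f), %s\n",
              x$diff, x$ci[1], x$ci[2],
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Cross-set z-test for efficiency ratios
#'
#' Compares the efficiency ratio of the same scale between two independent
#' samples (development vs validation) using bootstrap standard errors:
#' \eqn{z = (E_{dev} - E_{val})/\sqrt{SE_{dev}^2 + SE_{val}^2}}.
#'
#' @param eff_dev,eff_val efficiency ratios in the two sets.
#' @param se_dev,se_val their bootstrap standard errors (not both zero).
#' @return List with `z` and two-sided `p`.
#' @export
cross_set_z <- function(eff_dev, se_dev, eff_val, se_val) {
  if (se_dev < 0 || se_val < 0) stop("SEs must be >= 0", call. = FALSE)
  if (se_dev == 0 && se_val == 0) {
    stop("both standard errors are zero: z undefined", call. = FALSE)
  }
  z <- (eff_dev - eff_val) / sqrt(se_dev^2 + se_val^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
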