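#' AUC with DeLong variance
#'
#' Mann-Whitney AUC (ties weighted one half) with the DeLong
#' placement-value variance and a Wald 95% confidence interval clipped to
#' \[0, 1\].
#'
#' @param scores numeric predictor (higher = more case-like).
#' @param labels binary diagnosis labels; both classes must be present.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `roc_result`: `auc`, `var`, `se`, `ci`,
#'   `n_cases`, `n_controls`, `degenerate`.
#' @examples
#' roc_auc(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  pl <- placements(scores, labels)
  m <- length(pl$v10); n <- length(pl$v01)
  degenerate <- FALSE
  if (length(unique(scores)) == 1L) {
    warning("constant scores: AUC is 0.5 by convention", call. = FALSE)
    degenerate <- TRUE
  }
  auc <- mean(pl$v10)
  v <- if (degenerate) 0 else
    stats::var(pl$v10) / m + stats::var(pl$v01) / n
  se <- sqrt(v)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * zq * se, 0), 1)
  structure(list(auc = auc, var = v, se = se, ci = ci,
                 n_cases = m, n_controls = n, degenerate = degenerate),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; %d cases / %d controls)\n",
              x$auc, x$ci[1], x$ci[2], x$n_cases, x$n_controls))
  invisible(x)
}

# DeLong placement values: v10[i] = P-hat(case i outranks a control),
# v01[j] = P-hat(a case outranks control j), ties counted 1/2.
placements <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp))
}

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both diagnosis classes must be present", call. = FALSE)
  }
  labels
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects using the
#' paired DeLong covariance of placement values.
#'
#' @param scores_a,scores_b two score vectors over the same subjects.
#' @param labels binary diagnosis labels.
#' @return List of class `delong_test`: `auc_a`, `auc_b`, `delta_auc`
#'   (A minus B), `var`, `z`, `p`, `degenerate`.
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired scores must cover the same subjects", call. = FALSE)
  }
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  v <- stats::var(d10) / m + stats::var(d01) / n
  delta <- auc_a - auc_b
  if (!is.finite(v) || v <= .Machine$double.eps) {
    return(structure(list(auc_a = auc_a, auc_b = auc_b, delta_auc = 0,
                          var = 0, z = 0, p = 1, degenerate = TRUE),
                     class = "delong_test"))
  }
  z <- delta / sqrt(v)
  structure(list(auc_a = auc_a, auc_b = auc_b, delta_auc = delta, var = v,
                 z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC %.3f vs %.3f, dAUC %+.3f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$delta_auc, x$z, x$p))
  invisible(x)
}

#' Hanley-McNeil z-test for independent AUCs
#'
#' Two-sided z-test for an AUC difference across independent samples:
#' \eqn{z = (A_1 - A_2)/\sqrt{SE_1^2 + SE_2^2}}.
#'
#' @param auc_a,auc_b the two AUCs.
#' @param se_a,se_b their standard errors (not both zero).
#' @return List with `delta_auc`, `z`, `p`.
#' @export
hanley_mcneil_z <- function(auc_a, se_a, auc_b, se_b) {
  if (se_a < 0 || se_b < 0) stop("standard errors must be >= 0", call. = FALSE)
  if (se_a == 0 && se_b == 0) {
    stop("both standard errors are zero: z undefined", call. = FALSE)
  }
  z <- (auc_a - auc_b) / sqrt(se_a^2 + se_b^2)
  list(delta_auc = auc_a - auc_b, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Optimal cutoff by Youden's index
#'
#' Evaluates every threshold `t` with the positive-test convention
#' "score >= t" and returns the one maximizing Youden's
#' \eqn{J = \mathrm{sens} + \mathrm{spec} - 1}; ties are broken toward the
#' higher cutoff (favoring specificity).
#'
#' @param scores integer-valued scale scores.
#' @param labels binary diagnosis labels.
#' @return Object of class `cutoff_performance`: `cutoff`, `sensitivity`
#'   and `specificity` (percent), `youden_j` (fraction).
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(t) mean(x >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(y < t), numeric(1))
  j <- sens + spec - 1
  best <- max(which(j == max(j)))  # highest cutoff among ties
  structure(list(cutoff = cand[best],
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 youden_j = j[best]),
            class = "cutoff_performance")
}

#' @export
print.cutoff_performance <- function(x, ...) {
  cat(sprintf("optimal cutoff >= %g: sensitivity %.1f%%, specificity %.1f%% (J = %.3f)\n",
              x$cutoff, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' McNemar test for paired classification accuracy
#'
#' Compares two classifiers applied to the same subjects via their
#' discordant pairs: exact binomial when fewer than 25 discordant pairs,
#' otherwise chi-square with continuity correction.
#'
#' @param correct_a,correct_b logical vectors: was each subject classified
#'   correctly by scale A / scale B.
#' @return Two-sided p-value.
#' @export
mcnemar_paired <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0L) return(1)
  if (b + cc < 25L) {
    return(stats::binom.test(b, b + cc, 0.5)$p.value)
  }
  stat <- (abs(b - cc) - 1)^2 / (b + cc)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Chi-square test for two independent proportions
#'
#' Standard 2x2 chi-square with continuity correction, as used to compare
#' sensitivities or specificities across independent samples.
#'
#' @param x1,n1 successes and trials in sample 1.
#' @param x2,n2 successes and trials in sample 2.
#' @return Two-sided p-value.
#' @export
chisq_two_proportions <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive", call. = FALSE)
  if ((x1 + x2 == 0) || (x1 + x2 == n1 + n2)) {
    warning("degenerate margin: proportions identical at 0 or 1",
            call. = FALSE)
    return(1)
  }
  suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE)$p.value
  )
}

#' Predictive values at a given prevalence
#'
#' Bayes' rule applied to a test's sensitivity and specificity:
#' \eqn{PPV = se \cdot p / (se \cdot p + (1-sp)(1-p))} and
#' \eqn{NPV = sp(1-p) / (sp(1-p) + (1-se)p)}.
#'
#' @param sensitivity,specificity,prevalence fractions in \[0, 1\].
#' @return Named numeric vector `c(ppv, npv)`.
#' @examples
#' predictive_values(0.80, 0.84, 0.20)  # PPV ~ 0.556
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity, specificity, prevalence)
  if (any(args < 0 | args > 1)) {
    stop("sensitivity, specificity and prevalence must be fractions in [0, 1]",
         call. = FALSE)
  }
  ppv_den <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  npv_den <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  if (ppv_den == 0 || npv_den == 0) {
    stop("predictive value undefined: zero denominator", call. = FALSE)
  }
  c(ppv = sensitivity * prevalence / ppv_den,
    npv = specificity * (1 - prevalence) / npv_den)
}

#' Cutoff sweep table with scenario predictive values
#'
#' Sensitivity, specificity, Youden's J, and PPV/NPV under each prevalence
#' scenario, for every observed threshold (positive if score >= cutoff).
#'
#' @param scores integer-valued scale scores.
#' @param labels binary diagnosis labels.
#' @param prevalences prevalence scenarios (defaults: 3.8% community,
#'   13% clinic, 20% high-prevalence settings).
#' @return Data frame, one row per cutoff.
#' @export
cutoff_sweep <- function(scores, labels, prevalences = c(0.038, 0.13, 0.20)) {
  labels <- check_binary_labels(labels)
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  cand <- sort(unique(scores))
  out <- lapply(cand, function(t) {
    sens <- mean(x >= t); spec <- mean(y < t)
    row <- data.frame(cutoff = t, sensitivity = 100 * sens,
                      specificity = 100 * spec, youden_j = sens + spec - 1)
    for (p in prevalences) {
      pv <- tryCatch(predictive_values(sens, spec, p),
                     error = function(e) c(ppv = NA_real_, npv = NA_real_))
      row[[sprintf("ppv_%g", 100 * p)]] <- 100 * pv[["ppv"]]
      row[[sprintf("npv_%g", 100 * p)]] <- 100 * pv[["npv"]]
    }
    row
  })
  do.call(rbind, out)
}
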