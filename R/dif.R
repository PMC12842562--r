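#' Mantel-Haenszel differential item functioning for one item
#'
#' Stratifies subjects by a matching score (by default the total score of
#' the scale under audit, including the studied item), builds a
#' group x endorsement 2x2 table per stratum, and computes the
#' Mantel-Haenszel common odds ratio, the MH chi-square p-value
#' (continuity-corrected, via [stats::mantelhaen.test]), and the ETS delta
#' metric \eqn{\Delta_{MH} = -2.35 \ln \alpha_{MH}}. A 0.5 continuity
#' correction is added to the cells of strata containing a zero cell when
#' forming the common odds ratio. Sparse strata (fewer than `min_stratum`
#' subjects) are merged with the nearest score stratum.
#'
#' @param responses n x J binary matrix (`item_XX` column names).
#' @param item item index to audit.
#' @param group two-level grouping factor/vector; the first level is the
#'   reference, so \eqn{\alpha_{MH} > 1} means the reference group endorses
#'   the item more readily at matched score.
#' @param matching_score optional explicit matching score; default is the
#'   total over all columns of `responses`.
#' @param min_stratum minimal stratum size before merging (default 5).
#' @return Object of class `dif_result`: `item`, `levels`, `alpha_mh`, `p`,
#'   `delta_mh`, `abs_delta_mh`, `ets`, `direction`, `n_strata`.
#' @export
mh_dif <- function(responses, item, group, matching_score = NULL,
                   min_stratum = 5L) {
  X <- as.matrix(responses)
  col <- match(as.integer(item), item_ids_from_names(colnames(X)))
  if (is.na(col)) stop("item not found in the response matrix", call. = FALSE)
  y <- X[, col]
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("'group' must have exactly 2 levels",
                                 call. = FALSE)
  if (is.null(matching_score)) matching_score <- rowSums(X, na.rm = TRUE)

  strata <- merge_sparse_strata(matching_score, min_stratum)
  g1 <- group == levels(group)[1L]

  num <- den <- 0
  chi_tables <- list()
  informative <- 0L
  for (s in unique(strata)) {
    in_s <- strata == s
    a <- sum(g1[in_s] & y[in_s] == 1)       # ref group, endorsed
    b <- sum(g1[in_s] & y[in_s] == 0)
    cc <- sum(!g1[in_s] & y[in_s] == 1)
    d <- sum(!g1[in_s] & y[in_s] == 0)
    N <- a + b + cc + d
    # a stratum is informative only if both groups are present and the
    # item varies within it
    if ((a + b) == 0 || (cc + d) == 0) next
    if ((a + cc) == 0 || (b + d) == 0) next
    informative <- informative + 1L
    chi_tables[[length(chi_tables) + 1L]] <-
      matrix(c(a, b, cc, d), 2, 2, byrow = TRUE)
    if (min(a, b, cc, d) == 0) {             # zero-cell continuity correction
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5; N <- N + 2
    }
    num <- num + a * d / N
    den <- den + b * cc / N
  }
  if (informative == 0L || num == 0 || den == 0) {
    stop("all strata degenerate: MH odds ratio undefined", call. = FALSE)
  }
  alpha_mh <- num / den
  tab <- array(unlist(chi_tables), dim = c(2, 2, length(chi_tables)))
  p <- tryCatch(
    stats::mantelhaen.test(tab, correct = TRUE)$p.value,
    error = function(e) NA_real_)
  delta_mh <- -2.35 * log(alpha_mh)
  structure(list(item = as.integer(item), levels = levels(group),
                 alpha_mh = alpha_mh, p = p, delta_mh = delta_mh,
                 abs_delta_mh = abs(delta_mh),
                 ets = ets_classify(abs(delta_mh), p),
                 direction = if (alpha_mh >= 1) levels(group)[1L] else
                   levels(group)[2L],
                 n_strata = length(chi_tables)),
            class = "dif_result")
}

# merge score strata until all have at least min_n members
merge_sparse_strata <- function(score, min_n) {
  vals <- sort(unique(score))
  # bins as a list of value groups, merged greedily with the nearest side
  bins <- as.list(vals)
  counts <- vapply(bins, function(v) sum(score %in% v), integer(1))
  while (length(bins) > 1L && any(counts < min_n)) {
    i <- which(counts < min_n)[1L]
    j <- if (i == 1L) 2L else if (i == length(bins)) i - 1L else
      if (counts[i - 1L] <= counts[i + 1L]) i - 1L else i + 1L
    bins[[min(i, j)]] <- c(bins[[min(i, j)]], bins[[max(i, j)]])
    bins[[max(i, j)]] <- NULL
    counts <- vapply(bins, function(v) sum(score %in% v), integer(1))
  }
  out <- integer(length(score))
  for (k in seq_along(bins)) out[score %in% bins[[k]]] <- k
  out
}

#' ETS classification of a Mantel-Haenszel delta
#'
#' Educational Testing Service categories: `A` (negligible) when
#' `|delta| < 1` or the MH test is non-significant; `B` (moderate) when
#' `1 <= |delta| < 1.5` with `p < 0.05`; `C` (large) when `|delta| >= 1.5`
#' with `p < 0.05`.
#'
#' @param abs_delta_mh absolute ETS delta, non-negative. Vectorized.
#' @param p MH chi-square p-value.
#' @return Character vector of `"A"`, `"B"`, `"C"`.
#' @examples
#' ets_classify(2.27, 0.001)  # "C"
#' @export
ets_classify <- function(abs_delta_mh, p) {
  if (any(abs_delta_mh < 0, na.rm = TRUE)) {
    stop("'abs_delta_mh' must be non-negative", call. = FALSE)
  }
  ifelse(abs_delta_mh < 1.0 | is.na(p) | p >= 0.05, "A",
         ifelse(abs_delta_mh < 1.5, "B", "C"))
}

#' DIF audit of a whole scale
#'
#' Runs [mh_dif] for every item of a scale against one grouping variable,
#' matching on the scale's own total score.
#'
#' @param responses n x J binary matrix.
#' @param scale a [scale_definition] or integer item indices.
#' @param group two-level grouping vector.
#' @param min_stratum passed to [mh_dif].
#' @return Data frame with one row per item: `item`, `alpha_mh`, `p`,
#'   `delta_mh`, `abs_delta_mh`, `ets`, `direction`.
#' @export
dif_scale <- function(responses, scale, group, min_stratum = 5L) {
  items <- if (inherits(scale, "scale_definition")) scale$items else
    as.integer(scale)
  X <- as.matrix(responses)
  cols <- match(items, item_ids_from_names(colnames(X)))
  if (anyNA(cols)) stop("scale references items absent from the matrix",
                        call. = FALSE)
  Xs <- X[, cols, drop = FALSE]
  total <- rowSums(Xs, na.rm = TRUE)
  rows <- lapply(seq_along(items), function(i) {
    r <- mh_dif(Xs, items[i], group, matching_score = total,
                min_stratum = min_stratum)
    data.frame(item = r$item, alpha_mh = r$alpha_mh, p = r$p,
               delta_mh = r$delta_mh, abs_delta_mh = r$abs_delta_mh,
               ets = r$ets, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Differential test functioning: subgroup AUC comparison
#'
#' Scale-level invariance check: the AUC of the scale score is computed
#' within each group, and the group difference reported. A group lacking
#' one diagnosis class gets an `NA` AUC with a message.
#'
#' @param scores scale sum scores.
#' @param labels binary diagnosis labels.
#' @param group two-level grouping vector; difference is level 1 minus
#'   level 2.
#' @return Object of class `dtf_result`: per-group AUC with CI and
#'   `delta_auc`.
#' @export
dtf_auc <- function(scores, labels, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("'group' must have exactly 2 levels",
                                 call. = FALSE)
  per_group <- lapply(levels(group), function(lv) {
    in_g <- group == lv
    if (length(unique(labels[in_g])) < 2L) {
      message("group '", lv, "' lacks one diagnosis class: AUC undefined")
      return(list(auc = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_)))
    }
    suppressWarnings(roc_auc(scores[in_g], labels[in_g]))
  })
  names(per_group) <- levels(group)
  delta <- per_group[[1L]]$auc - per_group[[2L]]$auc
  structure(list(levels = levels(group), groups = per_group,
                 delta_auc = delta),
            class = "dtf_result")
}

#' @export
print.dtf_result <- function(x, ...) {
  for (lv in x$levels) {
    g <- x$groups[[lv]]
    cat(sprintf("  %s: AUC %.3f (95%% CI %.3f-%.3f)\n", lv, g$auc,
                g$ci[1], g$ci[2]))
  }
  cat(sprintf("  dAUC = %.3f\n", x$delta_auc))
  invisible(x)
}
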