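#' Unit-weighted sum score of an item subset
#'
#' Counts endorsed (keyed) items per subject. Missing responses contribute
#' zero (available-item sum); subjects with any missing scale item are
#' flagged in the `"n_missing"` attribute.
#'
#' @param responses n x J binary matrix with `item_XX` column names.
#' @param scale a [scale_definition] or integer item indices.
#' @return Integer score vector in `0..|scale|` with attribute `n_missing`.
#' @export
sum_score <- function(responses, scale) {
  X <- as.matrix(responses)
  items <- if (inherits(scale, "scale_definition")) scale$items else
    as.integer(scale)
  cols <- match(items, item_ids_from_names(colnames(X)))
  if (anyNA(cols)) {
    stop("scale references items absent from the response matrix",
         call. = FALSE)
  }
  X <- X[, cols, drop = FALSE]
  score <- rowSums(X, na.rm = TRUE)
  structure(score, n_missing = rowSums(is.na(X)))
}

#' Sequential discrimination-ordered item reduction
#'
#' The core abbreviation procedure: starting from the full ranked pool,
#' items are removed one at a time in order of lowest discrimination. At
#' each size `k` the top-`k` scale is sum-scored in both the development
#' and validation cohorts, compared against the full scale within each
#' cohort by the paired DeLong test, and compared across cohorts by the
#' Hanley-McNeil independent z-test; expected test information is recorded
#' for elbow detection.
#'
#' @param dev,val development and validation cohorts (a `cohort`, or any
#'   list with `$responses` and `$diagnosis`).
#' @param bank the [item_bank] calibrated on the development set.
#' @param ranking item ordering from [rank_items]; defaults to
#'   `rank_items(bank)`.
#' @param k_min smallest scale size evaluated (default 4, the smallest
#'   published GDS variant).
#' @param alpha nominal two-sided significance level, strictly in (0, 1).
#' @param grid a [latent_grid] for the information column.
#' @return A data frame of class `reduction_trace` with one row per scale
#'   size `k` (descending): AUC and CI per set, delta-AUC and DeLong p
#'   versus the full scale per set, cross-set delta-AUC and Hanley-McNeil
#'   p, and expected test information.
#' @export
sequential_reduction <- function(dev, val, bank, ranking = NULL,
                                 k_min = 4L, alpha = 0.05,
                                 grid = latent_grid()) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(ranking)) ranking <- rank_items(bank)
  k_max <- length(ranking)
  if (k_min < 2L || k_min > k_max) {
    stop("'k_min' must be between 2 and the ranking length", call. = FALSE)
  }
  full <- ranking
  dev_full <- sum_score(dev$responses, full)
  val_full <- sum_score(val$responses, full)

  rows <- vector("list", k_max - k_min + 1L)
  for (k in seq(k_max, k_min)) {
    items <- ranking[seq_len(k)]
    sd_ <- sum_score(dev$responses, items)
    sv_ <- sum_score(val$responses, items)
    rd <- suppressWarnings(roc_auc(sd_, dev$diagnosis))
    rv <- suppressWarnings(roc_auc(sv_, val$diagnosis))
    dd <- delong_paired(sd_, dev_full, dev$diagnosis)
    dv <- delong_paired(sv_, val_full, val$diagnosis)
    hm <- hanley_mcneil_z(rd$auc, rd$se, rv$auc, rv$se)
    rows[[k_max - k + 1L]] <- data.frame(
      k = k, items = paste(items, collapse = ","),
      dev_auc = rd$auc, dev_ci_lo = rd$ci[1], dev_ci_hi = rd$ci[2],
      dev_delta = dd$delta_auc, dev_p = dd$p,
      val_auc = rv$auc, val_ci_lo = rv$ci[1], val_ci_hi = rv$ci[2],
      val_delta = dv$delta_auc, val_p = dv$p,
      cross_delta = hm$delta_auc, cross_p = hm$p,
      info = expected_test_information(bank, items, grid))
  }
  trace <- do.call(rbind, rows)
  attr(trace, "alpha") <- alpha
  attr(trace, "ranking") <- ranking
  attr(trace, "k_min") <- k_min
  class(trace) <- c("reduction_trace", "data.frame")
  trace
}

#' Select the minimum equivalent scale size
#'
#' The dual-criterion stopping rule: a size `k` passes when its DeLong
#' p-value against the full scale exceeds `alpha` in BOTH the development
#' and validation sets (equivalence maintained; the `"dev_only"` variant
#' checks the development set alone). The selected `k*` is the smallest
#' passing size whose next reduction step (`k - 1`, when evaluated) fails
#' in at least one required set — the fewest items still statistically
#' equivalent to the full scale, with the step below marking where
#' degradation is detected. If every evaluated size passes, `k*` is the
#' smallest evaluated size; if none passes, the full scale is returned
#' with a no-reduction flag.
#'
#' @param trace a `reduction_trace`.
#' @param alpha significance level (defaults to the trace's).
#' @param rule `"dual"` (both sets, the default) or `"dev_only"`.
#' @return List with `k` (selected size), `items` (integer indices),
#'   `no_reduction` flag, and the pass/fail table used.
#' @export
select_minimum <- function(trace, alpha = NULL, rule = c("dual", "dev_only")) {
  stopifnot(inherits(trace, "reduction_trace") || is.data.frame(trace))
  if (nrow(trace) == 0L) stop("empty reduction trace", call. = FALSE)
  rule <- match.arg(rule)
  if (is.null(alpha)) alpha <- attr(trace, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  tr <- trace[order(trace$k), , drop = FALSE]
  pass <- if (rule == "dual") tr$dev_p > alpha & tr$val_p > alpha else
    tr$dev_p > alpha
  pick_items <- function(krow) {
    as.integer(strsplit(tr$items[krow], ",")[[1]])
  }
  pass_table <- data.frame(k = tr$k, pass = pass)
  if (!any(pass)) {
    krow <- nrow(tr)  # largest evaluated size = full scale
    return(list(k = tr$k[krow], items = pick_items(krow),
                no_reduction = TRUE, table = pass_table))
  }
  prev_is_consecutive <- c(FALSE, tr$k[-nrow(tr)] == tr$k[-1L] - 1L)
  prev_pass <- c(NA, pass[-length(pass)])
  candidate <- pass & (!prev_is_consecutive | !prev_pass)
  krow <- which(candidate)[1L]  # smallest qualifying size
  list(k = tr$k[krow], items = pick_items(krow), no_reduction = FALSE,
       table = pass_table)
}

#' Detect the information elbow
#'
#' Computes marginal information gains \eqn{\Delta_k = I(k) - I(k-1)} along
#' the trace and returns the size `k` at which the marginal gain drops the
#' most, i.e. maximizing \eqn{\Delta_k - \Delta_{k+1}}. Reported alongside
#' [select_minimum], never overriding it.
#'
#' @param trace a `reduction_trace` with the `info` column on at least 3
#'   consecutive sizes.
#' @return List with `k_elbow` (NA with `no_elbow = TRUE` when the
#'   information profile is linear), and the table of marginal gains.
#' @export
elbow_detection <- function(trace) {
  tr <- trace[order(trace$k), , drop = FALSE]
  consecutive <- all(diff(tr$k) == 1L)
  if (nrow(tr) < 3L || !consecutive) {
    warning("elbow detection needs >= 3 consecutive scale sizes",
            call. = FALSE)
    return(list(k_elbow = NA_integer_, no_elbow = TRUE, gains = NULL))
  }
  delta <- diff(tr$info)                     # gain at k = tr$k[-1]
  k_gain <- tr$k[-1L]
  drop <- delta[-length(delta)] - delta[-1L]  # Delta_k - Delta_{k+1}
  k_drop <- k_gain[-length(k_gain)]
  gains <- data.frame(k = k_gain, marginal_gain = delta)
  if (all(abs(drop) < 1e-9)) {
    return(list(k_elbow = NA_integer_, no_elbow = TRUE, gains = gains))
  }
  list(k_elbow = k_drop[which.max(drop)], no_elbow = FALSE, gains = gains)
}

#' Write a reduction trace as TSV
#'
#' @param trace a `reduction_trace`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trace <- function(trace, file) {
  utils::write.table(as.data.frame(trace), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
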