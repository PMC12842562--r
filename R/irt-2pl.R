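#' Quadrature grid for the latent trait
#'
#' Equally spaced nodes with standard-normal density weights, renormalized
#' to sum to one. Used both for EM integration in [fit_2pl] and for
#' expected test information.
#'
#' @param n_nodes number of nodes (default 61).
#' @param bounds range of the grid (default \[-6, 6\]).
#' @return List with `nodes` and `weights` (positive, summing to 1).
#' @export
latent_grid <- function(n_nodes = 61L, bounds = c(-6, 6)) {
  stopifnot(n_nodes >= 3L, bounds[1] < bounds[2])
  nodes <- seq(bounds[1], bounds[2], length.out = n_nodes)
  w <- stats::dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

#' 2PL item characteristic curve
#'
#' Endorsement probability \eqn{P(\theta) = 1/(1 + e^{-a(\theta - b)})}.
#' At \eqn{\theta = b} the item is endorsed with probability exactly one
#' half; the curve is strictly increasing in \eqn{\theta}.
#'
#' @param theta latent trait value(s).
#' @param a discrimination, must be > 0.
#' @param b difficulty.
#' @return Endorsement probability in (0, 1).
#' @examples
#' icc(0.60, a = 2.47, b = 0.60)  # 0.5 by definition of b
#' @export
icc <- function(theta, a, b) {
  if (any(a <= 0)) stop("discrimination 'a' must be > 0", call. = FALSE)
  stats::plogis(a * (theta - b))
}

#' 2PL item information function
#'
#' Fisher information \eqn{I(\theta) = a^2 P(\theta)(1 - P(\theta))};
#' non-negative, maximized at \eqn{\theta = b} where it equals
#' \eqn{a^2/4}, and vanishing in both tails.
#'
#' @inheritParams icc
#' @return Item information at `theta`.
#' @export
item_information <- function(theta, a, b) {
  p <- icc(theta, a, b)
  a^2 * p * (1 - p)
}

#' Expected test information of an item subset
#'
#' Sum over the subset's items of the 2PL item information, integrated over
#' the latent-trait grid with standard-normal weights. Additive in items,
#' hence monotone under set inclusion.
#'
#' @param bank an [item_bank].
#' @param subset a [scale_definition], integer item indices, or `NULL` for
#'   the whole bank.
#' @param grid a [latent_grid].
#' @return Scalar expected information.
#' @export
expected_test_information <- function(bank, subset = NULL,
                                      grid = latent_grid()) {
  stopifnot(inherits(bank, "item_bank"))
  if (inherits(subset, "scale_definition")) subset <- subset$items
  if (is.null(subset)) subset <- bank$item
  if (length(subset) == 0L) stop("subset must be non-empty", call. = FALSE)
  rows <- match(subset, bank$item)
  if (anyNA(rows)) stop("subset references items absent from the bank",
                        call. = FALSE)
  total <- 0
  for (r in rows) {
    total <- total +
      sum(grid$weights * item_information(grid$nodes, bank$a[r], bank$b[r]))
  }
  total
}

#' Fit a 2PL model by marginal maximum likelihood (EM)
#'
#' Bock-Aitkin EM over a fixed quadrature grid with a standard-normal prior
#' on the latent trait. The E-step computes posterior node weights per
#' subject; the M-step maximizes each item's expected complete-data
#' log-likelihood by damped Newton iteration in slope-intercept form,
#' converted back to the `a(theta - b)` parameterization on output so that
#' `b` is exactly the 50%-endorsement point.
#'
#' Items endorsed by everyone or no one carry no 2PL information and are
#' excluded with a warning. Missing responses are ignored item-wise in the
#' likelihood (missing-at-random); all-missing rows are dropped.
#'
#' @param responses n x J matrix or data frame of 0/1 (NA allowed).
#' @param grid a [latent_grid].
#' @param tol convergence tolerance: EM stops when the largest absolute
#'   parameter change falls below it (default 1e-4).
#' @param max_iter maximum EM cycles (default 500).
#' @param a_bounds allowed range for discrimination (default \[0.05, 6\]);
#'   hitting a bound raises a warning.
#' @param b_bound difficulty is clamped to \[-b_bound, b_bound\] (default 8).
#' @return An [item_bank] for the retained items with `se_a`/`se_b` columns
#'   (expected-information approximation) and attributes `logLik`,
#'   `loglik_trace`, `iterations`, `converged`, `excluded`, `at_bounds`.
#' @export
fit_2pl <- function(responses, grid = latent_grid(), tol = 1e-4,
                    max_iter = 500L, a_bounds = c(0.05, 6), b_bound = 8) {
  X <- as.matrix(responses)
  storage.mode(X) <- "double"
  if (!all(X %in% c(0, 1) | is.na(X))) {
    stop("responses must be binary (0/1, NA allowed)", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- sprintf("item_%02d", seq_len(ncol(X)))
  item_ids <- item_ids_from_names(colnames(X))

  all_missing <- rowSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing rows dropped", call. = FALSE)
    X <- X[!all_missing, , drop = FALSE]
  }

  rate <- colMeans(X, na.rm = TRUE)
  degenerate <- rate <= 0 | rate >= 1
  if (any(degenerate)) {
    warning("excluding degenerate items (all 0 or all 1): ",
            paste(colnames(X)[degenerate], collapse = ", "), call. = FALSE)
    X <- X[, !degenerate, drop = FALSE]
    item_ids_kept <- item_ids[!degenerate]
    rate <- rate[!degenerate]
  } else {
    item_ids_kept <- item_ids
  }
  J <- ncol(X)
  if (J < 2L) stop("need at least 2 non-degenerate items", call. = FALSE)
  n <- nrow(X)

  nodes <- grid$nodes
  logw <- log(grid$weights)
  Q <- length(nodes)

  has_na <- anyNA(X)
  A <- X; A[is.na(A)] <- 0          # endorsement indicator, 0 where missing
  B <- (1 - X); B[is.na(B)] <- 0    # non-endorsement indicator
  Mobs <- if (has_na) (!is.na(X)) * 1 else NULL

  a <- rep(1, J)
  b <- -stats::qlogis(rate)          # crude start: marginal logit at a = 1
  b <- pmin(pmax(b, -b_bound), b_bound)

  loglik_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- outer(a * -b, rep(1, Q)) + outer(a, nodes)  # J x Q
    P <- stats::plogis(eta)
    eps <- 1e-12
    L <- A %*% log(pmax(P, eps)) + B %*% log(pmax(1 - P, eps))  # n x Q
    L <- sweep(L, 2L, logw, `+`)
    rowmax <- apply(L, 1L, max)
    W <- exp(L - rowmax)
    rs <- rowSums(W)
    loglik <- sum(rowmax + log(rs))
    W <- W / rs
    loglik_trace <- c(loglik_trace, loglik)

    nq_all <- colSums(W)                       # Q
    R <- crossprod(A, W)                       # J x Q expected endorsements
    Nq <- if (has_na) crossprod(Mobs, W) else matrix(nq_all, J, Q, byrow = TRUE)

    a_new <- a; b_new <- b
    for (j in seq_len(J)) {
      fit <- newton_2pl_item(R[j, ], Nq[j, ], nodes, a[j], b[j],
                             a_bounds, b_bound)
      a_new[j] <- fit[1]; b_new[j] <- fit[2]
    }
    delta <- max(abs(a_new - a), abs(b_new - b))
    a <- a_new; b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }

  at_bounds <- a <= a_bounds[1] + 1e-9 | a >= a_bounds[2] - 1e-9 |
    abs(b) >= b_bound - 1e-9
  if (any(at_bounds)) {
    warning("parameter bounds hit for: ",
            paste(colnames(X)[at_bounds], collapse = ", "), call. = FALSE)
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter, " cycles", call. = FALSE)
  }

  # approximate SEs from the expected complete-data information at the MLE
  eta <- outer(a * -b, rep(1, Q)) + outer(a, nodes)
  P <- stats::plogis(eta)
  se_a <- se_b <- rep(NA_real_, J)
  Nq_fin <- if (has_na) Nq else matrix(colSums(W), J, Q, byrow = TRUE)
  for (j in seq_len(J)) {
    v <- Nq_fin[j, ] * P[j, ] * (1 - P[j, ])
    # information in (a, c) with c = -a b, then delta method to (a, b)
    I_ac <- matrix(c(sum(v * nodes^2), sum(v * nodes),
                     sum(v * nodes), sum(v)), 2, 2)
    Vac <- tryCatch(solve(I_ac), error = function(e) matrix(NA_real_, 2, 2))
    Jmat <- matrix(c(1, 0, -b[j], -a[j]), 2, 2, byrow = TRUE)  # d(a,c)/d(a,b)
    Vab <- tryCatch(solve(Jmat) %*% Vac %*% t(solve(Jmat)),
                    error = function(e) matrix(NA_real_, 2, 2))
    se_a[j] <- sqrt(Vab[1, 1]); se_b[j] <- sqrt(Vab[2, 2])
  }

  bank <- item_bank(a = a, b = b, item = item_ids_kept,
                    se_a = se_a, se_b = se_b)
  attr(bank, "logLik") <- loglik_trace[length(loglik_trace)]
  attr(bank, "loglik_trace") <- loglik_trace
  attr(bank, "iterations") <- iter
  attr(bank, "converged") <- converged
  attr(bank, "excluded") <- item_ids[degenerate]
  attr(bank, "at_bounds") <- item_ids_kept[at_bounds]
  bank
}

# Damped Newton maximization of one item's expected log-likelihood
# sum_q r_q log P_q + (N_q - r_q) log(1 - P_q) over (a, c), eta = a*node + c.
newton_2pl_item <- function(r, N, nodes, a0, b0, a_bounds, b_bound,
                            max_steps = 30L) {
  a <- a0; c <- -a0 * b0
  obj <- function(a, c) {
    p <- stats::plogis(a * nodes + c)
    sum(r * log(pmax(p, 1e-12)) + (N - r) * log(pmax(1 - p, 1e-12)))
  }
  f0 <- obj(a, c)
  for (s in seq_len(max_steps)) {
    p <- stats::plogis(a * nodes + c)
    resid <- r - N * p
    g <- c(sum(resid * nodes), sum(resid))
    v <- N * p * (1 - p)
    H11 <- sum(v * nodes^2); H12 <- sum(v * nodes); H22 <- sum(v)
    det <- H11 * H22 - H12^2
    if (!is.finite(det) || det < 1e-12) break
    step_a <- (H22 * g[1] - H12 * g[2]) / det
    step_c <- (H11 * g[2] - H12 * g[1]) / det
    lambda <- 1
    repeat {
      a1 <- a + lambda * step_a; c1 <- c + lambda * step_c
      f1 <- obj(a1, c1)
      if (f1 >= f0 - 1e-10 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (abs(f1 - f0) < 1e-10 && max(abs(g)) < 1e-6) { a <- a1; c <- c1; break }
    a <- a1; c <- c1; f0 <- f1
    if (max(abs(lambda * c(step_a, step_c))) < 1e-9) break
  }
  a <- min(max(a, a_bounds[1]), a_bounds[2])
  b <- min(max(-c / a, -b_bound), b_bound)
  c(a, b)
}

item_ids_from_names <- function(nm) {
  ids <- suppressWarnings(as.integer(sub("^[^0-9]*", "", nm)))
  if (anyNA(ids) || anyDuplicated(ids)) ids <- seq_along(nm)
  ids
}

#' Rank items by discrimination
#'
#' Orders items by descending discrimination `a`; ties are broken by
#' descending per-item AUC (when the bank carries an `item_auc` column),
#' then by ascending item index.
#'
#' @param bank an [item_bank].
#' @return Integer vector of item indices, highest discrimination first.
#' @examples
#' rank_items(gds_item_bank())[1]  # item 16
#' @export
rank_items <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  auc <- if ("item_auc" %in% names(bank)) bank$item_auc else rep(0, nrow(bank))
  auc[is.na(auc)] <- 0
  ord <- order(-bank$a, -auc, bank$item)
  bank$item[ord]
}

#' Per-item AUC against a binary label
#'
#' Mann-Whitney AUC of a single binary item as a predictor of diagnosis;
#' for a 0/1 predictor this equals (sensitivity + specificity) / 2.
#'
#' @param x binary item responses.
#' @param labels binary diagnosis labels (both classes required).
#' @return AUC in \[0, 1\].
#' @export
item_auc <- function(x, labels) {
  roc_auc(x, labels)$auc
}

#' Cronbach's alpha for an item subset
#'
#' Internal consistency \eqn{\alpha = k/(k-1) (1 - \sum_i s_i^2 / s_T^2)}
#' of unit-weighted sum scoring.
#'
#' @param responses n x J binary matrix.
#' @param subset a [scale_definition], integer item indices (matching the
#'   `item_XX` column numbering), or `NULL` for all columns.
#' @return Alpha coefficient (at most 1).
#' @export
cronbach_alpha <- function(responses, subset = NULL) {
  X <- as.matrix(responses)
  if (!is.null(subset)) {
    if (inherits(subset, "scale_definition")) subset <- subset$items
    cols <- match(subset, item_ids_from_names(colnames(X)))
    if (anyNA(cols)) stop("subset references items absent from the matrix",
                          call. = FALSE)
    X <- X[, cols, drop = FALSE]
  }
  k <- ncol(X)
  if (k < 2L) stop("alpha needs at least 2 items", call. = FALSE)
  item_var <- apply(X, 2L, stats::var)
  if (any(item_var == 0)) {
    stop("alpha undefined: zero-variance item present", call. = FALSE)
  }
  total_var <- stats::var(rowSums(X))
  if (total_var == 0) stop("alpha undefined: zero-variance total score",
                           call. = FALSE)
  k / (k - 1) * (1 - sum(item_var) / total_var)
}
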