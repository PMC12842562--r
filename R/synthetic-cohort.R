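#' Configure a synthetic screening cohort
#'
#' Describes the generative model for a simulated late-life depression
#' screening cohort: a binary diagnosis with given prevalence, a
#' diagnosis-conditional normal latent severity trait \eqn{\theta}, and
#' binary item responses drawn from a 2PL model
#' \eqn{P(\mathrm{endorse}) = 1/(1 + e^{-a(\theta - b + s)})}, where `s` is
#' an optional group-specific difficulty shift used to inject differential
#' item functioning (DIF).
#'
#' Recruitment source ("community" vs "clinic") acts on prevalence only:
#' clinic subjects carry a higher diagnosis rate, in the packaged default the
#' 13.2% vs 3.2% contrast of a mixed population cohort, rescaled so the
#' overall rate equals `prevalence`. The response model itself is
#' source-blind unless `dif_offsets` says otherwise.
#'
#' @param n_subjects positive integer, cohort size.
#' @param prevalence overall diagnosis prevalence, strictly in (0, 1).
#' @param theta_control,theta_case `(mean, sd)` of the latent trait for
#'   non-depressed and depressed subjects. The defaults (0, 1) and (1.7, 1)
#'   put the latent-trait AUC near 0.89.
#' @param item_bank an [item_bank]; defaults to the packaged GDS-30 bank.
#' @param dif_offsets optional named list mapping a covariate level
#'   (`"male"`, `"female"`, `"young_old"`, `"old_old"`, `"community"`,
#'   `"clinic"`) to a numeric vector of per-item difficulty shifts, named by
#'   item index. Positive shifts make endorsement easier for that group.
#' @param covariate_spec marginal frequencies: `female`, `old_old`, `clinic`.
#' @param source_prevalence_ratio clinic-to-community ratio of diagnosis
#'   rates used to split `prevalence` across recruitment sources.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 6525,
                          prevalence = 0.038,
                          theta_control = c(0, 1),
                          theta_case = c(1.7, 1),
                          item_bank = gds_item_bank(),
                          dif_offsets = NULL,
                          covariate_spec = list(female = 0.569,
                                                old_old = 0.30,
                                                clinic = 0.061),
                          source_prevalence_ratio = 0.132 / 0.032,
                          seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects <= 0L) {
    stop("'n_subjects' must be a positive integer", call. = FALSE)
  }
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("'prevalence' must lie strictly between 0 and 1", call. = FALSE)
  }
  for (nm in c("theta_control", "theta_case")) {
    v <- get(nm)
    if (length(v) != 2L || !all(is.finite(v)) || v[2] <= 0) {
      stop(sprintf("'%s' must be (mean, sd) with sd > 0", nm), call. = FALSE)
    }
  }
  if (!inherits(item_bank, "item_bank")) {
    stop("'item_bank' must be an item_bank object", call. = FALSE)
  }
  levels_ok <- c("male", "female", "young_old", "old_old",
                 "community", "clinic")
  if (!is.null(dif_offsets)) {
    if (is.null(names(dif_offsets)) ||
        !all(names(dif_offsets) %in% levels_ok)) {
      stop("names of 'dif_offsets' must be covariate levels: ",
           paste(levels_ok, collapse = ", "), call. = FALSE)
    }
    for (off in dif_offsets) {
      if (is.null(names(off))) {
        stop("each DIF offset vector must be named by item index",
             call. = FALSE)
      }
      if (!all(as.integer(names(off)) %in% item_bank$item)) {
        stop("DIF offsets reference items absent from the item bank",
             call. = FALSE)
      }
    }
  }
  structure(list(n_subjects = n_subjects, prevalence = prevalence,
                 theta_control = theta_control, theta_case = theta_case,
                 item_bank = item_bank, dif_offsets = dif_offsets,
                 covariate_spec = covariate_spec,
                 source_prevalence_ratio = source_prevalence_ratio,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws covariates, a source-dependent diagnosis, a diagnosis-conditional
#' latent trait, and 2PL item responses as configured. The true latent trait
#' is retained (for testing and calibration checks only; no analysis step
#' may use it).
#'
#' @param config a [cohort_config].
#' @return An object of class `cohort`: list with `responses` (n x J binary
#'   matrix, columns `item_01`...), `diagnosis` (0/1), `covariates`
#'   (data frame with `sex`, `age_group`, `source`), `true_theta`, and the
#'   generating `config`.
#' @examples
#' co <- generate_cohort(cohort_config(n_subjects = 500, seed = 7))
#' mean(co$diagnosis)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  bank <- config$item_bank
  J <- nrow(bank)
  cs <- config$covariate_spec

  sex <- ifelse(stats::runif(n) < cs$female, "female", "male")
  age_group <- ifelse(stats::runif(n) < cs$old_old, "old_old", "young_old")
  source <- ifelse(stats::runif(n) < cs$clinic, "clinic", "community")

  # split overall prevalence across sources at a fixed rate ratio
  f <- cs$clinic
  rr <- config$source_prevalence_ratio
  p_comm <- config$prevalence / ((1 - f) + f * rr)
  p_clin <- min(rr * p_comm, 0.99)
  p_diag <- ifelse(source == "clinic", p_clin, p_comm)
  diagnosis <- as.integer(stats::runif(n) < p_diag)

  mu <- ifelse(diagnosis == 1L, config$theta_case[1], config$theta_control[1])
  sd <- ifelse(diagnosis == 1L, config$theta_case[2], config$theta_control[2])
  theta <- stats::rnorm(n, mu, sd)

  shift <- matrix(0, n, J)
  if (!is.null(config$dif_offsets)) {
    grp <- cbind(sex, age_group, source)
    for (lev in names(config$dif_offsets)) {
      members <- rowSums(grp == lev) > 0
      off <- config$dif_offsets[[lev]]
      cols <- match(as.integer(names(off)), bank$item)
      shift[members, cols] <- shift[members, cols] +
        rep(off, each = sum(members))
    }
  }

  eta <- (outer(theta, rep(1, J)) - outer(rep(1, n), bank$b) + shift) *
    outer(rep(1, n), bank$a)
  responses <- matrix(as.integer(stats::runif(n * J) < stats::plogis(eta)),
                      n, J)
  colnames(responses) <- sprintf("item_%02d", bank$item)

  structure(list(responses = responses,
                 diagnosis = diagnosis,
                 covariates = data.frame(sex = sex, age_group = age_group,
                                         source = source,
                                         stringsAsFactors = FALSE),
                 true_theta = theta,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects x %d items, prevalence %.1f%% (%d cases)\n",
              nrow(x$responses), ncol(x$responses),
              100 * mean(x$diagnosis), sum(x$diagnosis)))
  invisible(x)
}

#' Subset a cohort by row index
#'
#' @param cohort a `cohort`.
#' @param idx integer row indices.
#' @return A `cohort` restricted to the given subjects.
#' @export
cohort_subset <- function(cohort, idx) {
  structure(list(responses = cohort$responses[idx, , drop = FALSE],
                 diagnosis = cohort$diagnosis[idx],
                 covariates = cohort$covariates[idx, , drop = FALSE],
                 true_theta = cohort$true_theta[idx],
                 config = cohort$config),
            class = "cohort")
}

#' Stratified split into development and validation sets
#'
#' Partitions a cohort by stratified sampling on diagnosis x recruitment
#' source. Each stratum is split as close to `ratio` as integer counts
#' allow (largest-remainder allocation, so the development set totals
#' exactly `round(ratio * n)`); strata with fewer than 2 members are
#' assigned wholly to the larger half with a warning.
#'
#' @param cohort a `cohort`.
#' @param ratio development-set fraction, strictly in (0, 1).
#' @param seed integer seed; the split is deterministic given it.
#' @return List with elements `dev` and `val`, each a `cohort`, plus
#'   `dev_idx`/`val_idx` giving the original row indices.
#' @export
stratified_split <- function(cohort, ratio = 0.5, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1) {
    stop("'ratio' must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- length(cohort$diagnosis)
  strata <- interaction(cohort$diagnosis, cohort$covariates$source,
                        drop = TRUE)
  sizes <- table(strata)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("strata with fewer than 2 members assigned to the larger half: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  usable <- setdiff(names(sizes), small)
  n_usable <- sum(sizes[usable])
  target_dev <- round(ratio * n_usable)

  base <- floor(ratio * as.numeric(sizes[usable]))
  frac <- ratio * as.numeric(sizes[usable]) - base
  extra <- target_dev - sum(base)
  take <- base
  if (extra > 0) {
    ord <- order(frac, decreasing = TRUE)
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
  }

  set.seed(seed)
  dev_idx <- integer(0)
  for (k in seq_along(usable)) {
    ids <- which(strata == usable[k])
    dev_idx <- c(dev_idx, sort(sample(ids, take[k])))
  }
  # tiny strata go wholly to the larger half
  if (length(small)) {
    small_ids <- which(strata %in% small)
    if (ratio > 0.5) dev_idx <- c(dev_idx, small_ids)
  }
  dev_idx <- sort(dev_idx)
  val_idx <- setdiff(seq_len(n), dev_idx)
  list(dev = cohort_subset(cohort, dev_idx),
       val = cohort_subset(cohort, val_idx),
       dev_idx = dev_idx, val_idx = val_idx)
}

#' Write a cohort to CSV with a JSON sidecar
#'
#' One row per subject with columns `item_01..item_J`, `diagnosis`, `sex`,
#' `age_group`, `source`. The sidecar (`<path>.json`) records the generating
#' configuration and seed.
#'
#' @param cohort a `cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(cohort$responses, diagnosis = cohort$diagnosis,
                   cohort$covariates, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  meta <- list(n_subjects = cfg$n_subjects, prevalence = cfg$prevalence,
               theta_control = cfg$theta_control,
               theta_case = cfg$theta_case,
               covariate_spec = cfg$covariate_spec,
               source_prevalence_ratio = cfg$source_prevalence_ratio,
               dif_offsets = cfg$dif_offsets, seed = cfg$seed,
               items = cfg$item_bank$item)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
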