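#' Construct an item bank
#'
#' An item bank holds per-item two-parameter logistic (2PL) parameters:
#' discrimination `a` (slope, unitless, positive) and difficulty `b`
#' (location on the latent-trait scale at which endorsement probability is
#' one half). Optional columns carry standard errors and the per-item
#' Mann-Whitney AUC against a diagnostic label.
#'
#' @param a numeric vector of discrimination parameters, all > 0.
#' @param b numeric vector of difficulty parameters, all finite.
#' @param item integer item indices (defaults to `seq_along(a)`).
#' @param content optional character vector of item wording.
#' @param se_a,se_b optional standard errors.
#' @param item_auc optional per-item AUC values in \[0, 1\].
#' @return A data frame of class `item_bank` with one row per item.
#' @examples
#' item_bank(a = c(1.5, 0.8), b = c(-1, 1))
#' @export
item_bank <- function(a, b, item = seq_along(a), content = NULL,
                      se_a = NULL, se_b = NULL, item_auc = NULL) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("all discrimination parameters 'a' must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(b))) {
    stop("all difficulty parameters 'b' must be finite", call. = FALSE)
  }
  bank <- data.frame(item = as.integer(item), a = a, b = b)
  if (!is.null(content)) bank$content <- as.character(content)
  if (!is.null(se_a)) bank$se_a <- as.numeric(se_a)
  if (!is.null(se_b)) bank$se_b <- as.numeric(se_b)
  if (!is.null(item_auc)) {
    item_auc <- as.numeric(item_auc)
    if (any(item_auc < 0 | item_auc > 1, na.rm = TRUE)) {
      stop("'item_auc' values must lie in [0, 1]", call. = FALSE)
    }
    bank$item_auc <- item_auc
  }
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("2PL item bank: %d items (a in [%.2f, %.2f], b in [%.2f, %.2f])\n",
              nrow(x), min(x$a), max(x$a), min(x$b), max(x$b)))
  conv <- attr(x, "converged")
  if (!is.null(conv)) {
    cat(sprintf("  fitted by EM: %s after %d cycles (logLik %.2f)\n",
                if (conv) "converged" else "NOT converged",
                attr(x, "iterations"), attr(x, "logLik")))
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' Packaged GDS-30 item bank
#'
#' The 30-item Geriatric Depression Scale bank shipped with the package:
#' published 2PL discrimination/difficulty calibrations and per-item AUCs for
#' a Korean older-adult screening population, together with the item wording
#' and reverse-keying flags. Item 16 ("Downhearted and blue?") is the most
#' discriminating item (a = 2.47).
#'
#' @return An [item_bank] with 30 rows and columns `item`, `a`, `b`,
#'   `content`, `item_auc`; the logical reverse-keying flag is kept in
#'   attribute `"reverse_keyed"` (see [gds_reverse_items]).
#' @export
gds_item_bank <- function() {
  path <- system.file("extdata", "gds30_item_bank.csv", package = "gdsirt",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  bank <- item_bank(a = raw$a, b = raw$b, item = raw$item,
                    content = raw$content, item_auc = raw$item_auc)
  attr(bank, "reverse_keyed") <- raw$item[raw$reverse_keyed == 1]
  bank
}

#' GDS items keyed in the non-depressive direction
#'
#' Indices of the GDS-30 items worded positively (e.g. "Satisfied with
#' life?"), for which the depressive answer is "no". [read_response_csv]
#' flips these columns so that 1 always means "symptom endorsed".
#'
#' @return Integer vector of item indices.
#' @export
gds_reverse_items <- function() {
  bank <- gds_item_bank()
  attr(bank, "reverse_keyed")
}

#' Define a named item subset (a scale)
#'
#' @param name scale label, e.g. `"GDS10-IRT"`.
#' @param items integer item indices (1-based, referring to the full-pool
#'   numbering); must be unique.
#' @param n_items optional pool size to validate indices against.
#' @return An object of class `scale_definition`.
#' @examples
#' scale_definition("GDS4", c(1, 3, 9, 15))
#' @export
scale_definition <- function(name, items, n_items = NULL) {
  items <- as.integer(items)
  if (length(items) == 0L) stop("a scale needs at least one item", call. = FALSE)
  if (anyDuplicated(items)) stop("scale items must be unique", call. = FALSE)
  if (any(items < 1L)) stop("item indices are 1-based", call. = FALSE)
  if (!is.null(n_items) && any(items > n_items)) {
    stop(sprintf("scale '%s' references items beyond the %d-item pool",
                 name, n_items), call. = FALSE)
  }
  structure(list(name = as.character(name), items = items),
            class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("scale '%s': %d items (%s)\n", x$name, length(x$items),
              paste(x$items, collapse = ", ")))
  invisible(x)
}

#' @export
length.scale_definition <- function(x) length(x$items)

#' Packaged GDS scale definitions
#'
#' Published GDS short forms as shipped: the full `GDS30`, the 15-item
#' `GDS15`, the 4-item `GDS4`, and the IRT-derived 10-item `GDS10-IRT`
#' (items 1, 4, 6, 10, 11, 16, 17, 21, 22, 25). The classical 10-item
#' Almeida short form is not packaged and must be supplied by the user.
#'
#' @param file optional path to a two-column CSV (`scale_name,item_index`)
#'   to read user-supplied definitions instead of the packaged ones.
#' @return Named list of [scale_definition] objects.
#' @export
gds_scales <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "gds_scales.csv", package = "gdsirt",
                        mustWork = TRUE)
  }
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("scale_name", "item_index") %in% names(raw))) {
    stop("scale file needs columns 'scale_name' and 'item_index'",
         call. = FALSE)
  }
  defs <- lapply(split(raw$item_index, raw$scale_name), function(ii) ii)
  out <- lapply(names(defs), function(nm) scale_definition(nm, defs[[nm]]))
  names(out) <- names(defs)
  out[unique(raw$scale_name)]
}

#' Write scale definitions to a two-column CSV
#'
#' @param scales list of [scale_definition] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_scales <- function(scales, file) {
  if (inherits(scales, "scale_definition")) scales <- list(scales)
  rows <- do.call(rbind, lapply(scales, function(s) {
    data.frame(scale_name = s$name, item_index = s$items)
  }))
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
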