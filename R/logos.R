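## Sequence-logo matrices of the top discriminative n-grams' source
## phosphopeptides: position frequency matrix plus per-position information
## content in bits with the small-sample correction.

#' Select a species' top discriminative n-grams by ratio
#'
#' Signature entries with `top_species == species` and ratio score at least
#' `cutoff`; infinite-flagged scores are always included. The default cutoff
#' is the 95th percentile of the species' finite ratio scores (or, when all
#' its scores are infinite, selects those).
#'
#' @param sig a `phospho_signature` built in ratio mode.
#' @param species a training species label occurring in the signature.
#' @param cutoff positive ratio threshold, or `NULL` for the percentile
#'   default.
#' @return character vector of n-grams.
#' @export
select_top_ngrams <- function(sig, species, cutoff = NULL) {
  stopifnot(inherits(sig, "phospho_signature"))
  if (sig$params$score_mode != "ratio")
    stop("top n-gram selection requires ratio-mode scores")
  e <- sig$entries[sig$entries$top_species == species, , drop = FALSE]
  if (!nrow(e)) stop("species not present in signature: ", species)
  if (is.null(cutoff)) {
    fin <- e$score[is.finite(e$score)]
    cutoff <- if (length(fin)) unname(quantile(fin, 0.95)) else Inf
  }
  if (cutoff <= 0) stop("cutoff must be positive")
  e$ngram[e$score >= cutoff | is.infinite(e$score)]
}

#' Build a logo matrix from aligned phosphopeptide windows
#'
#' Aligns windows on the central phosphosite (column 11 of 21; truncated
#' windows placed by offset), tabulates the per-position residue frequencies
#' (PFM), and computes the information content per position,
#' `ic_p = log2(20) - (H_p + e(n_p))` clamped to `[0, log2 20]`, with
#' Shannon entropy `H_p` in bits and the small-sample correction
#' `e(n) = 19 / (2 ln(2) n)` over the `n_p` unmasked sequences at position
#' `p` (switchable off).
#'
#' @param windows a nonempty `phospho_windows` data.frame.
#' @param width alignment width (default 21).
#' @param small_sample apply the small-sample correction (default `TRUE`).
#' @return a `logo_matrix`: `pfm` (width x 20, unmasked columns sum to 1),
#'   `ic` (bits per position), `n_per_position`, `n_sequences`.
#' @export
build_logo <- function(windows, width = 21L, small_sample = TRUE) {
  if (is.null(nrow(windows)) || nrow(windows) == 0L)
    stop("build_logo needs at least one window")
  center <- (width + 1L) %/% 2L
  counts <- matrix(0L, nrow = width, ncol = length(AA_ALPHABET),
                   dimnames = list(seq_len(width), AA_ALPHABET))
  for (i in seq_len(nrow(windows))) {
    chars <- strsplit(windows$window[i], "", fixed = TRUE)[[1]]
    cols <- seq_along(chars) - (windows$offset[i] + 1L) + center
    keep <- cols >= 1L & cols <= width & chars %in% AA_ALPHABET
    idx <- cbind(cols[keep], match(chars[keep], AA_ALPHABET))
    counts[idx] <- counts[idx] + 1L
  }
  n_p <- unname(rowSums(counts))
  pfm <- counts / pmax(n_p, 1L)
  pfm[n_p == 0L, ] <- NA_real_
  H <- apply(pfm, 1, function(p) {
    p <- p[is.finite(p) & p > 0]
    if (!length(p)) return(NA_real_)
    -sum(p * log2(p))
  })
  corr <- if (small_sample) 19 / (2 * log(2) * pmax(n_p, 1L)) else 0
  ic <- unname(pmin(pmax(log2(20) - (H + corr), 0), log2(20)))
  structure(list(pfm = pfm, ic = ic, n_per_position = n_p,
                 n_sequences = nrow(windows)),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("logo_matrix: %d sequences, %d positions, max ic %.2f bits\n",
              x$n_sequences, nrow(x$pfm), max(x$ic, na.rm = TRUE)))
  invisible(x)
}

#' Logo matrix of a species' top discriminative n-grams
#'
#' Convenience wrapper: selects the top n-grams with [select_top_ngrams()],
#' collects the union of their source windows from `counts`, and builds the
#' logo.
#'
#' @inheritParams select_top_ngrams
#' @param counts the species' `ngram_counts` (with `sources`).
#' @param windows the `phospho_windows` the counts were built from.
#' @return a `logo_matrix` with the n-grams in attribute `"ngrams"` and the
#'   cutoff used in attribute `"cutoff"`.
#' @export
species_logo <- function(sig, species, counts, windows, cutoff = NULL) {
  .query_top <- select_top_ngrams(sig, species, cutoff)
  wids <- unique(counts$sources[J(.query_top), wid, nomatch = NULL])
  if (!length(wids))
    stop("no source windows found for the top n-grams of ", species)
  lm <- build_logo(windows[match(wids, windows$wid), , drop = FALSE])
  attr(lm, "ngrams") <- .query_top
  attr(lm, "cutoff") <- cutoff
  lm
}

#' Write a logo matrix as TSV
#'
#' One row per position: `position`, the 20 residue frequencies, `ic`, `n`.
#'
#' @param lm a `logo_matrix`.
#' @param path output file path.
#' @export
write_logo_tsv <- function(lm, path) {
  d <- data.frame(position = seq_len(nrow(lm$pfm)), lm$pfm,
                  ic = lm$ic, n = lm$n_per_position, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
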