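## n-gram enumeration and per-dataset counting.
## An n-gram is every contiguous substring of a window with length in
## [n_min, n_max]; substrings containing the unknown-residue marker 'X'
## are dropped so the n-gram alphabet stays exact.

.enumerate_many <- function(windows, wids, n_min, n_max) {
  lens <- nchar(windows)
  maxL <- min(n_max, max(lens, 0L))
  if (maxL < n_min)
    return(data.table(ngram = character(), wid = character()))
  out <- vector("list", maxL - n_min + 1L)
  for (L in n_min:maxL) {
    el <- which(lens >= L)
    if (!length(el)) next
    ns <- lens[el] - L + 1L
    starts <- sequence(ns)
    sub <- substring(rep(windows[el], ns), starts, starts + L - 1L)
    out[[L - n_min + 1L]] <- data.table(ngram = sub,
                                        wid = rep(wids[el], ns))
  }
  dt <- rbindlist(out)
  dt[!grepl("X", ngram, fixed = TRUE)]
}

#' Enumerate the n-grams of one window
#'
#' Returns every contiguous substring of length `n_min` to `n_max` of
#' `window`, with multiplicity, in deterministic order (by length, then
#' position). Substrings containing `X` are omitted. For an X-free window of
#' length `|w|` the total count is `sum over L of (|w| - L + 1)`; a full
#' 21-mer with `n_min = 6`, `n_max = 21` yields 136 instances.
#'
#' @param window an amino-acid string.
#' @param n_min,n_max n-gram length range (defaults 6 and 21).
#' @return character vector of n-gram instances (possibly empty).
#' @export
enumerate_ngrams <- function(window, n_min = 6L, n_max = 21L) {
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 1L || n_min > n_max) stop("need 1 <= n_min <= n_max")
  if (length(window) != 1L) stop("enumerate_ngrams takes a single window")
  if (is.na(window) || nchar(window) == 0L) return(character())
  .enumerate_many(window, "w", n_min, n_max)$ngram
}

#' Count n-grams of one dataset's windows
#'
#' Sums n-gram multiplicities over all windows of a single
#' (species, dataset) scope and records which windows contain each n-gram
#' (used later to map discriminative n-grams back to their phosphopeptides).
#'
#' @param windows a `phospho_windows` data.frame sharing one species and
#'   dataset.
#' @param n_min,n_max n-gram length range.
#' @return an `ngram_counts` object: fields `species`, `dataset`, `counts`
#'   (data.table `ngram`, `count`), `sources` (data.table `ngram`, `wid`),
#'   `n_min`, `n_max`.
#' @export
count_dataset <- function(windows, n_min = 6L, n_max = 21L) {
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 1L || n_min > n_max) stop("need 1 <= n_min <= n_max")
  sp <- unique(windows$species); ds <- unique(windows$dataset)
  if (nrow(windows) == 0L) { sp <- NA_character_; ds <- NA_character_ }
  if (length(sp) > 1L || length(ds) > 1L)
    stop("count_dataset requires a single (species, dataset) scope; got ",
         paste(sp, collapse = ","), " / ", paste(ds, collapse = ","))
  dt <- .enumerate_many(windows$window, windows$wid, n_min, n_max)
  counts <- dt[, list(count = .N), by = "ngram"]
  setkey(counts, ngram)
  sources <- unique(dt)
  setkey(sources, ngram)
  structure(list(species = sp, dataset = ds,
                 counts = counts, sources = sources,
                 n_min = n_min, n_max = n_max),
            class = "ngram_counts")
}

#' @export
print.ngram_counts <- function(x, ...) {
  cat(sprintf("ngram_counts [%s / %s]: %d distinct n-grams, %d instances (n %d..%d)\n",
              x$species, x$dataset, nrow(x$counts),
              if (nrow(x$counts)) sum(x$counts$count) else 0L,
              x$n_min, x$n_max))
  invisible(x)
}

#' Dump an n-gram count table as TSV
#'
#' Columns `ngram`, `count`, in lexicographic n-gram order for diffability.
#'
#' @param x an `ngram_counts` object.
#' @param path output file path.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "ngram_counts"))
  d <- as.data.frame(x$counts[order(ngram)])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
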