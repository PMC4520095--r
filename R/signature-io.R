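#' Construct a phosphoproteome signature
#'
#' A signature is the set of kingdom/phylum-specific discriminative n-grams:
#' for each entry, the n-gram, the training species it discriminates
#' (`top_species`), that species' kingdom/phylum, its discriminative score
#' and its frozen dampening weight. The selection parameters (n-gram length
#' range, threshold `T`, score mode) travel with the signature so it acts as
#' a fixed model when projected onto new species.
#'
#' @param entries data.frame with columns `ngram`, `top_species`, `kingdom`,
#'   `score`, `weight`; n-grams must be unique, weights positive.
#' @param n_min,n_max n-gram length range used at selection.
#' @param threshold the discriminative threshold `T`.
#' @param score_mode `"ratio"` or `"difference"`.
#' @return a `phospho_signature` object.
#' @export
phospho_signature <- function(entries, n_min = 6L, n_max = 21L,
                              threshold = 0.05, score_mode = "ratio") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("ngram", "top_species", "kingdom", "score", "weight")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("signature entries missing column(s): ", paste(miss, collapse = ", "))
  entries <- entries[, need]
  if (nrow(entries)) {
    dup <- entries$ngram[duplicated(entries$ngram)]
    if (length(dup))
      stop("duplicate n-gram(s) in signature: ",
           paste(head(unique(dup), 5), collapse = ", "))
    if (any(!is.finite(entries$weight) | entries$weight <= 0))
      stop("signature weights must be positive and finite")
    if (any(entries$score < 0)) stop("signature scores must be non-negative")
  }
  structure(list(entries = entries,
                 params = list(n_min = as.integer(n_min),
                               n_max = as.integer(n_max),
                               threshold = as.numeric(threshold),
                               score_mode = match.arg(score_mode,
                                                      c("ratio", "difference")))),
            class = "phospho_signature")
}

#' @export
print.phospho_signature <- function(x, ...) {
  cat("phospho_signature:", nrow(x$entries), "n-grams |",
      "mode =", x$params$score_mode, "T =", x$params$threshold,
      sprintf("| n in [%d,%d]\n", x$params$n_min, x$params$n_max))
  if (nrow(x$entries)) {
    tab <- table(x$entries$kingdom)
    for (k in names(tab)) cat(sprintf("  %-16s %d\n", k, tab[[k]]))
  }
  invisible(x)
}

#' @export
`==.phospho_signature` <- function(e1, e2) {
  isTRUE(all.equal(e1$params, e2$params)) &&
    nrow(e1$entries) == nrow(e2$entries) &&
    isTRUE(all.equal(e1$entries, e2$entries, tolerance = 1e-12))
}

#' Write or read a signature file
#'
#' Tab-separated, columns `ngram`, `top_species`, `kingdom`, `score`,
#' `weight`, preceded by `#key=value` header lines carrying the selection
#' parameters. Round trips are identities.
#'
#' @param sig a `phospho_signature`.
#' @param path file path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "phospho_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- sig$params
  writeLines(sprintf("#%s=%s", names(p),
                     vapply(p, format, character(1), digits = 17)), con)
  e <- sig$entries
  e$score <- format(e$score, digits = 17, trim = TRUE)
  e$weight <- format(e$weight, digits = 17, trim = TRUE)
  write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#([A-Za-z_]+)=(.*)$", hdr))
  kv <- kv[lengths(kv) == 3L]
  if (!length(kv)) stop("signature file ", path, " has no parameter header")
  pars <- setNames(vapply(kv, `[`, character(1), 3L),
                   vapply(kv, `[`, character(1), 2L))
  need <- c("n_min", "n_max", "threshold", "score_mode")
  miss <- setdiff(need, names(pars))
  if (length(miss))
    stop("malformed signature header, missing: ",
         paste(miss, collapse = ", "))
  body <- lines[!grepl("^#", lines)]
  e <- read.delim(text = paste(body, collapse = "\n"),
                  stringsAsFactors = FALSE,
                  colClasses = c(ngram = "character",
                                 top_species = "character",
                                 kingdom = "character",
                                 score = "numeric", weight = "numeric"))
  if (nrow(e) && anyDuplicated(e$ngram))
    stop("duplicate n-gram row(s) in ", path, ": ",
         paste(head(unique(e$ngram[duplicated(e$ngram)]), 5), collapse = ", "))
  phospho_signature(e,
                    n_min = as.integer(pars[["n_min"]]),
                    n_max = as.integer(pars[["n_max"]]),
                    threshold = as.numeric(pars[["threshold"]]),
                    score_mode = pars[["score_mode"]])
}
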