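## Enriched counts, dampened normalized frequencies, discriminative scores
## and signature assembly.

#' Sum a species' per-dataset counts into enriched counts
#'
#' Element-wise sums of n-gram counts over one species' replicate datasets;
#' source-window sets are unioned.
#'
#' @param tables list of `ngram_counts` sharing one species label.
#' @return an `ngram_counts` with `dataset = "enriched"`.
#' @export
enriched_counts <- function(tables) {
  if (!length(tables)) stop("enriched_counts needs at least one table")
  sp <- unique(vapply(tables, `[[`, character(1), "species"))
  if (length(sp) > 1L)
    stop("enriched_counts: species mismatch: ", paste(sp, collapse = ", "))
  counts <- rbindlist(lapply(tables, `[[`, "counts"))
  counts <- counts[, list(count = sum(count)), by = "ngram"]
  setkey(counts, ngram)
  sources <- unique(rbindlist(lapply(tables, `[[`, "sources")))
  setkey(sources, ngram)
  structure(list(species = sp, dataset = "enriched",
                 counts = counts, sources = sources,
                 n_min = tables[[1]]$n_min, n_max = tables[[1]]$n_max),
            class = "ngram_counts")
}

#' Dampening weight of an n-gram
#'
#' IDF-style weight `w = log2(N / s) + 1` for an n-gram present in `s` of
#' `N` training species: strictly decreasing in `s`, equal to 1 for an
#' n-gram present in every species, so rarer n-grams are boosted when
#' frequencies from unbalanced datasets are compared.
#'
#' @param s_g integer (vector), number of species containing the n-gram,
#'   in `1..N`.
#' @param N number of training species.
#' @return positive weight(s).
#' @export
dampening_weight <- function(s_g, N) {
  if (any(s_g < 1L | s_g > N))
    stop("s_g must be in 1..N (an n-gram absent everywhere has no weight)")
  log2(N / s_g) + 1
}

#' Build the dampened normalized frequency matrix
#'
#' Over the union vocabulary of all species' enriched counts: per-species
#' relative frequencies (columns sum to 1), species presence `s(g)`,
#' dampening weights `w(g)` and the dampened normalized frequencies
#' `normfreq = relfreq * w(g)`.
#'
#' @param per_species named list (species -> `ngram_counts`, enriched).
#' @return a `frequency_matrix`: fields `ngrams`, `species`, `raw`,
#'   `relfreq`, `weights`, `normfreq`, `s`, `n_min`, `n_max`.
#' @export
build_frequency_matrix <- function(per_species) {
  if (length(per_species) < 2L)
    stop("build_frequency_matrix needs at least 2 species")
  if (is.null(names(per_species)))
    names(per_species) <- vapply(per_species, `[[`, character(1), "species")
  species <- names(per_species)
  vocab <- sort(unique(unlist(lapply(per_species,
                                     function(t) t$counts$ngram))))
  if (!length(vocab)) stop("union n-gram vocabulary is empty")
  raw <- matrix(0, nrow = length(vocab), ncol = length(species),
                dimnames = list(NULL, species))
  for (i in seq_along(species)) {
    ct <- per_species[[i]]$counts
    raw[match(ct$ngram, vocab), i] <- ct$count
  }
  tot <- colSums(raw)
  if (any(tot == 0))
    stop("species with zero total n-gram count: ",
         paste(species[tot == 0], collapse = ", "))
  relfreq <- sweep(raw, 2, tot, "/")
  s <- as.integer(rowSums(raw > 0))
  weights <- dampening_weight(s, length(species))
  structure(list(ngrams = vocab, species = species, raw = raw,
                 relfreq = relfreq, weights = weights,
                 normfreq = relfreq * weights, s = s,
                 n_min = per_species[[1]]$n_min,
                 n_max = per_species[[1]]$n_max),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("frequency_matrix: %d n-grams x %d species (%s)\n",
              length(x$ngrams), length(x$species),
              paste(x$species, collapse = ", ")))
  invisible(x)
}

## top-3 values and argmax per row without apply(); ties for the top are
## broken by column (species) order
.top3 <- function(m) {
  n <- nrow(m)
  i1 <- max.col(m, ties.method = "first")
  f1 <- m[cbind(seq_len(n), i1)]
  tie <- rowSums(m == f1) > 1L
  m[cbind(seq_len(n), i1)] <- -Inf
  i2 <- max.col(m, ties.method = "first")
  f2 <- m[cbind(seq_len(n), i2)]
  m[cbind(seq_len(n), i2)] <- -Inf
  f3 <- m[cbind(seq_len(n), max.col(m, ties.method = "first"))]
  list(i1 = i1, f1 = f1, f2 = f2, f3 = f3, tie = tie)
}

#' Discriminative scores of all n-grams
#'
#' Per n-gram, species are ranked by dampened normalized frequency; the
#' score compares the top species' frequency `f1` with the mean of the
#' second- and third-highest, `(f2 + f3)/2`: `f1 / ((f2+f3)/2)` in ratio
#' mode (flagged infinite when `f2 = f3 = 0`) or `f1 - (f2+f3)/2` in
#' difference mode. Ties for the top species are broken by species order in
#' the matrix and flagged.
#'
#' @param fm a `frequency_matrix` with at least 3 species.
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return data.frame `ngram`, `top_species`, `f1`, `f2`, `f3`, `score`,
#'   `infinite`, `tie`, with the mode in attribute `"mode"`.
#' @export
discriminative_scores <- function(fm, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  if (length(fm$species) < 3L)
    stop("discriminative scoring references the 2nd and 3rd highest ",
         "species and needs >= 3 species")
  t3 <- .top3(fm$normfreq)
  denom <- (t3$f2 + t3$f3) / 2
  if (mode == "ratio") {
    score <- ifelse(denom == 0, Inf, t3$f1 / denom)
    infinite <- denom == 0
  } else {
    score <- t3$f1 - denom
    infinite <- rep(FALSE, length(score))
  }
  out <- data.frame(ngram = fm$ngrams,
                    top_species = fm$species[t3$i1],
                    f1 = t3$f1, f2 = t3$f2, f3 = t3$f3,
                    score = score, infinite = infinite, tie = t3$tie,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Select discriminative n-grams per species
#'
#' Keeps n-grams with score strictly greater than `T` (infinite-flagged
#' ratio scores are always kept) and groups them by top species.
#'
#' @param scores output of [discriminative_scores()].
#' @param T positive threshold (default 0.05).
#' @return named list species -> character vector of n-grams.
#' @export
select_discriminative <- function(scores, T = 0.05) {
  if (T <= 0) stop("T must be positive")
  keep <- scores$score > T | scores$infinite
  split(scores$ngram[keep], scores$top_species[keep])
}

#' Assemble the kingdom/phylum signature
#'
#' A discriminative n-gram of training species `i` enters the signature iff
#' it is also present (raw count > 0) in the test species paired with `i`.
#' Entries carry the score and the frozen training dampening weight.
#'
#' @param train_discr named list species -> discriminative n-grams (from
#'   [select_discriminative()]).
#' @param test_tables named list test species -> `ngram_counts` (enriched).
#' @param design a `study_design`.
#' @param fm the training `frequency_matrix` (source of frozen weights).
#' @param scores the score table the selection was made from.
#' @param threshold the selection threshold `T`, recorded in the signature
#'   parameters.
#' @return a `phospho_signature`.
#' @export
build_signature <- function(train_discr, test_tables, design, fm, scores,
                            threshold = NA_real_) {
  mode <- attr(scores, "mode")
  train_of <- setNames(names(design$pairing), design$pairing)  # train -> test
  rows <- lapply(design$train_species, function(sp) {
    g <- train_discr[[sp]]
    if (is.null(g) || !length(g)) return(NULL)
    ts <- train_of[[sp]]
    if (is.na(ts) || is.null(test_tables[[ts]]))
      stop("no test table for the species paired with ", sp)
    present <- g %in% test_tables[[ts]]$counts$ngram
    g <- g[present]
    if (!length(g)) return(NULL)
    idx <- match(g, scores$ngram)
    data.frame(ngram = g, top_species = sp,
               kingdom = design$kingdom_of[[sp]],
               score = scores$score[idx],
               weight = fm$weights[match(g, fm$ngrams)],
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(entries))
    entries <- data.frame(ngram = character(), top_species = character(),
                          kingdom = character(), score = numeric(),
                          weight = numeric(), stringsAsFactors = FALSE)
  phospho_signature(entries, n_min = fm$n_min, n_max = fm$n_max,
                    threshold = threshold, score_mode = mode)
}

#' Project species onto a signature's vocabulary
#'
#' Recomputes relative frequencies over the signature n-grams only and
#' multiplies by the signature's FROZEN weights, so the signature acts as a
#' fixed model applied to new species. A species containing none of the
#' signature n-grams yields an all-zero column with a warning.
#'
#' @param sig a nonempty `phospho_signature`.
#' @param species_tables named list species -> `ngram_counts` (enriched).
#' @return a `frequency_matrix` restricted to the signature vocabulary.
#' @export
project_frequencies <- function(sig, species_tables) {
  stopifnot(inherits(sig, "phospho_signature"))
  if (!nrow(sig$entries)) stop("cannot project an empty signature")
  vocab <- sig$entries$ngram
  species <- names(species_tables)
  raw <- matrix(0, nrow = length(vocab), ncol = length(species),
                dimnames = list(NULL, species))
  for (i in seq_along(species)) {
    ct <- species_tables[[i]]$counts[ngram %in% vocab]
    raw[match(ct$ngram, vocab), i] <- ct$count
  }
  tot <- colSums(raw)
  if (any(tot == 0))
    warning("species with no signature n-grams (all-zero column): ",
            paste(species[tot == 0], collapse = ", "))
  relfreq <- sweep(raw, 2, pmax(tot, 1), "/")
  weights <- sig$entries$weight
  structure(list(ngrams = vocab, species = species, raw = raw,
                 relfreq = relfreq, weights = weights,
                 normfreq = relfreq * weights,
                 s = as.integer(rowSums(raw > 0)),
                 n_min = sig$params$n_min, n_max = sig$params$n_max),
            class = "frequency_matrix")
}

#' Write or read a frequency matrix as TSV
#'
#' Columns `ngram`, `s`, `weight`, then one column per species; `#` header
#' lines record which value matrix is stored. Raw counts, relative and
#' normalized frequencies are selectable; round trips restore the stored
#' matrix along with weights and `s(g)`.
#'
#' @param fm a `frequency_matrix`.
#' @param path file path.
#' @param what which matrix to store: `"normfreq"`, `"relfreq"` or `"raw"`.
#' @export
write_frequency_matrix <- function(fm, path,
                                   what = c("normfreq", "relfreq", "raw")) {
  what <- match.arg(what)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#matrix=%s", what),
               sprintf("#n_min=%d", fm$n_min),
               sprintf("#n_max=%d", fm$n_max)), con)
  d <- data.frame(ngram = fm$ngrams, s = fm$s,
                  weight = format(fm$weights, digits = 17, trim = TRUE),
                  format(fm[[what]], digits = 17, trim = TRUE),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_matrix
#' @export
read_frequency_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#([A-Za-z_]+)=(.*)$", hdr))
  pars <- setNames(vapply(kv, `[`, character(1), 3L),
                   vapply(kv, `[`, character(1), 2L))
  d <- read.delim(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                  stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -(1:3), drop = FALSE])
  what <- pars[["matrix"]]
  out <- list(ngrams = d$ngram, species = colnames(m), raw = NULL,
              relfreq = NULL, weights = as.numeric(d$weight),
              normfreq = NULL, s = as.integer(d$s),
              n_min = as.integer(pars[["n_min"]]),
              n_max = as.integer(pars[["n_max"]]))
  out[[what]] <- m
  structure(out, class = "frequency_matrix")
}
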