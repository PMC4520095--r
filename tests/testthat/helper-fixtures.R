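# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

# brute-force nested-loop n-gram oracle (independent of the implementation)
brute_ngrams <- function(w, n_min, n_max) {
  out <- list()
  for (L in n_min:n_max) {
    if (L > nchar(w)) next
    for (s in seq_len(nchar(w) - L + 1L)) {
      sub <- substr(w, s, s + L - 1L)
      if (!grepl("X", sub, fixed = TRUE)) out[[length(out) + 1L]] <- sub
    }
  }
  unlist(out) %||% character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_window <- function(len, p_x = 0) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  chars <- sample(aa, len, replace = TRUE)
  if (p_x > 0) chars[runif(len) < p_x] <- "X"
  paste(chars, collapse = "")
}

# windows row(s) without the strict-serine constraint, for combinatorial tests
make_windows <- function(windows, species = "sp1", dataset = "d1",
                         offset = NULL) {
  n <- length(windows)
  if (is.null(offset)) offset <- pmin(10L, nchar(windows) - 1L)
  phospho_windows(rep(species, n), rep(dataset, n),
                  sprintf("P%d", seq_len(n)), site = offset + 1L,
                  window = windows, offset = offset, strict = FALSE)
}

# ngram_counts object straight from a named count vector
make_counts <- function(species, counts, dataset = "enriched",
                        n_min = 6L, n_max = 21L) {
  ct <- data.table::data.table(ngram = names(counts),
                               count = as.integer(counts))
  data.table::setkey(ct, ngram)
  src <- data.table::data.table(ngram = names(counts),
                                wid = paste0(species, "_w",
                                             seq_along(counts)))
  data.table::setkey(src, ngram)
  structure(list(species = species, dataset = dataset, counts = ct,
                 sources = src, n_min = n_min, n_max = n_max),
            class = "ngram_counts")
}

# frequency_matrix stub with a prescribed normfreq (for scoring tests)
make_fm <- function(normfreq, species = colnames(normfreq),
                    ngrams = NULL) {
  if (is.null(ngrams)) ngrams <- paste0("g", seq_len(nrow(normfreq)))
  structure(list(ngrams = ngrams, species = species, raw = normfreq,
                 relfreq = normfreq, weights = rep(1, nrow(normfreq)),
                 normfreq = normfreq,
                 s = as.integer(rowSums(normfreq > 0)),
                 n_min = 6L, n_max = 21L),
            class = "frequency_matrix")
}

# adjusted Rand index between two hard partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

# tiny 3-kingdom study with planted species-exclusive n-grams on a small
# vocabulary: each species' datasets hold `n_motif` windows carrying its
# private motif and `n_bg` copies of a background window shared by all
toy_study <- function(n_motif = 10L, n_bg = 2L) {
  motifs <- c(A = "KKKKKKKKKK", B = "DDDDDDDDDD", C = "PPPPPPPPPP")
  bg <- paste0(strrep("G", 10), "S", strrep("G", 10))
  mkwin <- function(m) paste0(substr(m, 1, 10), "S", substr(m, 1, 10))
  rows <- list()
  for (sp in names(motifs)) {
    for (role in c("train", "test")) {
      nds <- if (role == "train") 2L else 1L
      spname <- if (role == "train") paste0(sp, "_tr") else paste0(sp, "_te")
      for (d in seq_len(nds)) {
        win <- c(rep(mkwin(motifs[[sp]]), n_motif), rep(bg, n_bg))
        rows[[length(rows) + 1L]] <- data.frame(
          species = spname, dataset = paste0(spname, "_d", d),
          protein = paste0(spname, "_p", seq_along(win)),
          site = 11L, window = win, offset = 10L,
          stringsAsFactors = FALSE)
      }
    }
  }
  all <- do.call(rbind, rows)
  windows <- phospho_windows(all$species, all$dataset, all$protein,
                             all$site, all$window, all$offset,
                             wid = paste0("w", seq_len(nrow(all))))
  train <- paste0(names(motifs), "_tr")
  test <- paste0(names(motifs), "_te")
  design <- study_design(
    train, test,
    pairing = setNames(train, test),
    kingdom_of = setNames(rep(paste0("K", names(motifs)), 2),
                          c(train, test)),
    datasets_of = c(setNames(lapply(train, function(s)
                      paste0(s, "_d", 1:2)), train),
                    setNames(lapply(test, function(s)
                      paste0(s, "_d1")), test)))
  list(windows = windows, design = design, motifs = motifs)
}
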