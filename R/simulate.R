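## Seeded synthetic multi-species phosphopeptide studies with planted
## kingdom-specific motifs, emulating a 5-kingdom train/test design: per
## kingdom one training species (two replicate datasets) and one paired
## test species (one dataset), all sharing that kingdom's motif set.

.default_species <- function() {
  list(train = c(Chordata = "H.sapiens", Arthropoda = "D.melanogaster",
                 Plantae = "A.thaliana", Ascomycota = "S.cerevisiae",
                 Oomycota = "P.infestans"),
       test = c(Chordata = "M.musculus", Arthropoda = "A.mellifera",
                Plantae = "O.sativa", Ascomycota = "S.pombe",
                Oomycota = "P.ramorum"))
}

## one contiguous 9-mer motif per kingdom, anchored with its single serine
## at the window center: animal kingdoms basic/arginine-flanked, plants
## C-terminally acidic, fungi C-terminally proline-rich
.default_motifs <- function() {
  list(Chordata = list(list(pattern = "KRRRSFRRK", insertion_prob = 0.3)),
       Arthropoda = list(list(pattern = "RQRRSARKR", insertion_prob = 0.3)),
       Plantae = list(list(pattern = "GSDDEEDED", insertion_prob = 0.3)),
       Ascomycota = list(list(pattern = "TASPPLPPP", insertion_prob = 0.3)),
       Oomycota = list(list(pattern = "AGYGSGGYG", insertion_prob = 0.3)))
}

#' Configure a synthetic phosphopeptide study
#'
#' Defaults emulate the real study design: 5 training species from 5
#' kingdoms/phyla with 2 datasets each, 5 paired test species with one
#' dataset each, 500 windows of 21 residues per dataset drawn i.i.d. from a
#' uniform residue background with the central serine forced, and one
#' kingdom motif stamped (anchored on the central serine) with probability
#' `insertion_prob = 0.3` per window.
#'
#' Motif patterns are strings over the amino-acid alphabet plus `x`
#' wildcards, containing exactly one `S` which is anchored at the window
#' center; wildcard positions stay background.
#'
#' @param seed integer seed; every random draw flows from it.
#' @param windows_per_dataset windows per dataset (default 500).
#' @param background residue probabilities over the 20-letter alphabet
#'   (default uniform).
#' @param motifs per-kingdom list of `list(pattern=, insertion_prob=)`;
#'   default plants one contiguous 9-mer per kingdom (animal kingdoms
#'   basic/arginine, plant acidic-C, fungal proline-C).
#' @param species list with named vectors `train` and `test` (names are
#'   kingdoms); defaults to a 5-kingdom design.
#' @param datasets_per_train replicate datasets per training species.
#' @param width window width (default 21).
#' @return a `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, windows_per_dataset = 500L,
                              background = NULL, motifs = .default_motifs(),
                              species = .default_species(),
                              datasets_per_train = 2L, width = 21L) {
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  if (!setequal(names(background), AA_ALPHABET))
    stop("background must be named by the 20-letter alphabet")
  background <- background[AA_ALPHABET]
  if (abs(sum(background) - 1) > 1e-9)
    stop("background probabilities must sum to 1")
  if (!setequal(names(species$train), names(species$test)))
    stop("train and test species must cover the same kingdoms")
  half <- (as.integer(width) - 1L) %/% 2L
  for (kg in names(motifs)) for (m in motifs[[kg]]) {
    if (m$insertion_prob < 0 || m$insertion_prob > 1)
      stop("insertion_prob outside [0,1] for kingdom ", kg)
    chars <- strsplit(m$pattern, "", fixed = TRUE)[[1]]
    if (sum(chars == "S") != 1L)
      stop("motif pattern must contain exactly one anchoring 'S': ",
           m$pattern)
    if (!all(chars %in% c(AA_ALPHABET, "x")))
      stop("motif pattern has characters outside the alphabet (+x): ",
           m$pattern)
    anchor <- which(chars == "S")
    if (anchor - 1L > half || length(chars) - anchor > half)
      stop("motif pattern overruns the window: ", m$pattern)
  }
  structure(list(seed = as.integer(seed),
                 windows_per_dataset = as.integer(windows_per_dataset),
                 background = background, motifs = motifs,
                 species = species,
                 datasets_per_train = as.integer(datasets_per_train),
                 width = as.integer(width)),
            class = "simulation_config")
}

#' Draw one synthetic phosphopeptide window
#'
#' A `width`-mer drawn i.i.d. from the background with `S` forced at the
#' center; with the motif's insertion probability, one motif of the kingdom
#' (chosen uniformly when several) is stamped with its `S` on the center,
#' wildcards left as background. Uses (and advances) the current RNG state;
#' seed via `set.seed()` or use [generate_study()].
#'
#' @param cfg a `simulation_config`.
#' @param kingdom kingdom label (may have an empty motif list).
#' @return a window string.
#' @export
generate_window <- function(cfg, kingdom) {
  w <- sample(AA_ALPHABET, cfg$width, replace = TRUE,
              prob = cfg$background)
  center <- (cfg$width + 1L) %/% 2L
  w[center] <- "S"
  motifs <- cfg$motifs[[kingdom]]
  if (length(motifs)) {
    m <- motifs[[if (length(motifs) > 1L)
      sample.int(length(motifs), 1L) else 1L]]
    if (runif(1) < m$insertion_prob) {
      chars <- strsplit(m$pattern, "", fixed = TRUE)[[1]]
      pos <- center - which(chars == "S") + seq_along(chars)
      fix <- chars != "x"
      w[pos[fix]] <- chars[fix]
    }
  }
  paste(w, collapse = "")
}

#' Generate a complete synthetic study
#'
#' Produces all training and test datasets, the matching `study_design`,
#' and the ground-truth motif map. Window ids are globally unique; proteins
#' are synthetic placeholders (one per window) with the site placed so the
#' windows are canonical full-width windows.
#'
#' @param cfg a `simulation_config`.
#' @return list with `windows` (one `phospho_windows` covering every
#'   dataset), `design` (a `study_design`) and `truth` (per-kingdom planted
#'   motifs).
#' @export
generate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  kingdoms <- names(cfg$species$train)
  rows <- list()
  emit <- function(sp, ds, kg) {
    win <- vapply(seq_len(cfg$windows_per_dataset), function(i)
      generate_window(cfg, kg), character(1))
    data.frame(species = sp, dataset = ds,
               protein = sprintf("%s_prot%05d", ds,
                                 seq_len(cfg$windows_per_dataset)),
               site = (cfg$width + 1L) %/% 2L + 10L,
               window = win, offset = (cfg$width - 1L) %/% 2L,
               stringsAsFactors = FALSE)
  }
  for (kg in kingdoms) {
    sp <- cfg$species$train[[kg]]
    for (d in seq_len(cfg$datasets_per_train))
      rows[[length(rows) + 1L]] <- emit(sp, paste0(sp, "_d", d), kg)
  }
  for (kg in kingdoms) {
    sp <- cfg$species$test[[kg]]
    rows[[length(rows) + 1L]] <- emit(sp, paste0(sp, "_d1"), kg)
  }
  all <- do.call(rbind, rows)
  windows <- phospho_windows(all$species, all$dataset, all$protein,
                             all$site, all$window, all$offset,
                             wid = sprintf("w%06d", seq_len(nrow(all))))
  train <- unname(cfg$species$train)
  test <- unname(cfg$species$test)
  kingdom_of <- c(setNames(kingdoms, cfg$species$train),
                  setNames(kingdoms, cfg$species$test))
  datasets_of <- c(
    setNames(lapply(train, function(sp)
      paste0(sp, "_d", seq_len(cfg$datasets_per_train))), train),
    setNames(lapply(test, function(sp) paste0(sp, "_d1")), test))
  design <- study_design(
    train_species = train, test_species = test,
    pairing = setNames(unname(cfg$species$train[kingdoms]),
                       unname(cfg$species$test[kingdoms])),
    kingdom_of = kingdom_of, datasets_of = datasets_of)
  list(windows = windows, design = design, truth = cfg$motifs)
}

#' Write a synthetic study to disk
#'
#' Emits one window-table TSV per dataset plus a `design.yaml`, the formats
#' consumed unchanged by the analysis pipeline.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp_ds <- unique(study$windows[, c("species", "dataset")])
  for (i in seq_len(nrow(sp_ds))) {
    sel <- study$windows$dataset == sp_ds$dataset[i]
    write_window_table(study$windows[sel, , drop = FALSE],
                       file.path(dir, paste0(sp_ds$dataset[i], ".tsv")))
  }
  write_study_design(study$design, file.path(dir, "design.yaml"))
  invisible(dir)
}
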