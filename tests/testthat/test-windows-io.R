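test_that("window tables read canonical, truncated and offset-column rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "species\tdataset\tprotein\tsite\twindow",
               paste("Ath", "d1", "P1", 42,
                     paste0(strrep("A", 10), "S", strrep("A", 10)),
                     sep = "\t"),
               paste("Ath", "d1", "P2", 2, "MSAAAA", sep = "\t")), f)
  w <- read_window_table(f)
  expect_s3_class(w, "phospho_windows")
  expect_equal(nrow(w), 2L)
  expect_equal(w$offset, c(10L, 1L))
  expect_equal(substr(w$window, w$offset + 1, w$offset + 1), c("S", "S"))

  # explicit offset column wins over inference
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tdataset\tprotein\tsite\twindow\toffset",
               paste("Ath", "d1", "P3", 7, "AAASAA", 3, sep = "\t")), f2)
  expect_equal(read_window_table(f2)$offset, 3L)
})

test_that("window validation rejects bad rows with diagnostics", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tdataset\tprotein\tsite\twindow",
               paste("Ath", "d1", "P1", 42,
                     paste0(strrep("A", 10), "T", strrep("A", 10)),
                     sep = "\t")), f)
  expect_error(read_window_table(f), "central residue")
  expect_s3_class(read_window_table(f, strict = FALSE), "phospho_windows")
  expect_s3_class(read_window_table(f, center = c("S", "T", "Y")),
                  "phospho_windows")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tprotein\tsite\twindow", "a\tb\t1\tSSS"), f2)
  expect_error(read_window_table(f2), "missing column")

  expect_error(phospho_windows("s", "d", "p", 1, "ZZZZ", 0, strict = FALSE),
               "alphabet")
  expect_error(phospho_windows("s", "d", "p", 1, "SAAA", 4, strict = FALSE),
               "geometry")
})

test_that("window table writer round-trips losslessly", {
  w <- make_windows(c("AAASAAAAAA", paste0(strrep("C", 9), "S")),
                    offset = c(3L, 9L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_window_table(w, f)
  w2 <- read_window_table(f, strict = FALSE)
  expect_equal(as.data.frame(w2), as.data.frame(w))
})

test_that("FASTA window extraction truncates at termini, never pads", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">prot1 some description", "MKSDEFGHIKLMNPQRSTVWYAA",
               ">prot2", "MKSDEFGHIKL",
               ">prot3", "AAAASAAAA"), fa)
  sites <- data.frame(species = "sp", dataset = "d",
                      protein = c("prot1", "prot2", "prot3"),
                      site = c(17L, 3L, 5L))
  w <- extract_windows_from_fasta(fa, sites, width = 21)
  # site 17 of a 23-mer: residues 7..23, length 17, phosphosite at offset 10
  expect_equal(w$window[1], "GHIKLMNPQRSTVWYAA")
  expect_equal(nchar(w$window[1]), 17L)
  expect_equal(w$offset[1], 10L)
  # site 3: left-truncated to residues 1..13 = the whole 11-mer protein
  expect_equal(w$window[2], "MKSDEFGHIKL")
  expect_equal(w$offset[2], 2L)
  # protein shorter than the window: whole protein, offset = site - 1
  expect_equal(w$window[3], "AAAASAAAA")
  expect_equal(w$offset[3], 4L)

  expect_error(extract_windows_from_fasta(
    fa, data.frame(species = "sp", dataset = "d", protein = "prot2",
                   site = 99L)), "outside protein length")
  expect_error(extract_windows_from_fasta(
    fa, data.frame(species = "sp", dataset = "d", protein = "nope",
                   site = 1L)), "absent from FASTA")
})

test_that("extracted windows always equal the protein substring", {
  set.seed(7)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "T", "V", "W", "Y")
  fa <- withr::local_tempfile(fileext = ".fasta")
  prots <- vapply(1:20, function(i) {
    chars <- sample(aa, sample(10:60, 1), replace = TRUE)
    pos <- sample(seq_along(chars), 1)
    chars[pos] <- "S"
    paste(chars, collapse = "")
  }, character(1))
  writeLines(as.vector(rbind(paste0(">p", 1:20), prots)), fa)
  site <- vapply(prots, function(p)
    as.integer(regexpr("S", p, fixed = TRUE)), integer(1))
  w <- extract_windows_from_fasta(
    fa, data.frame(species = "sp", dataset = "d",
                   protein = paste0("p", 1:20), site = site))
  for (i in 1:20) {
    from <- site[i] - w$offset[i]
    expect_identical(w$window[i],
                     substr(prots[i], from, from + nchar(w$window[i]) - 1L))
    expect_equal(nchar(w$window[i]),
                 min(21L, min(site[i] + 10L, nchar(prots[i])) -
                       max(1L, site[i] - 10L) + 1L))
  }
})

test_that("signature files round-trip, including parameters and Inf scores", {
  e <- data.frame(ngram = c("KKKKKK", "DDDDDD", "PPPPPP"),
                  top_species = c("A", "B", "C"),
                  kingdom = c("KA", "KB", "KC"),
                  score = c(3.25, Inf, 0.5),
                  weight = c(2.584962500721156, 1, 1.584962500721156),
                  stringsAsFactors = FALSE)
  sig <- phospho_signature(e, n_min = 6, n_max = 21, threshold = 0.05,
                           score_mode = "ratio")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, f)
  expect_true(sig == read_signature(f))

  empty <- phospho_signature(e[0, ], score_mode = "difference")
  write_signature(empty, f)
  back <- read_signature(f)
  expect_equal(nrow(back$entries), 0L)
  expect_true(empty == back)
})

test_that("signature reader enforces n-gram uniqueness and header format", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#n_min=6", "#n_max=21", "#threshold=0.05",
               "#score_mode=ratio",
               "ngram\ttop_species\tkingdom\tscore\tweight",
               "AAAAAA\tX\tKX\t1\t1",
               "AAAAAA\tY\tKY\t2\t1"), f)
  expect_error(read_signature(f), "duplicate n-gram.*AAAAAA")
  writeLines(c("ngram\ttop_species\tkingdom\tscore\tweight"), f)
  expect_error(read_signature(f), "parameter header")
})

test_that("study designs validate pairing and survive YAML round trips", {
  d <- toy_study()$design
  f <- withr::local_tempfile(fileext = ".yaml")
  write_study_design(d, f)
  d2 <- read_study_design(f)
  expect_equal(d2$pairing, d$pairing)
  expect_equal(d2$kingdom_of[names(d$kingdom_of)], d$kingdom_of)
  expect_equal(d2$datasets_of, d$datasets_of)

  expect_error(study_design(c("A", "B"), c("a", "b"),
                            pairing = c(a = "A", b = "A"),
                            kingdom_of = c(A = "k", B = "k", a = "k", b = "k"),
                            datasets_of = list()),
               "bijection")
  expect_error(study_design("A", "a", c(a = "A"),
                            kingdom_of = c(A = "k1", a = "k2"),
                            datasets_of = list(A = "d", a = "d")),
               "crosses kingdoms")
})

test_that("frequency matrix TSV round-trips the stored matrix", {
  tabs <- list(A = make_counts("A", c(KKKKKK = 4, GGGGGG = 1)),
               B = make_counts("B", c(DDDDDD = 2, GGGGGG = 2)),
               C = make_counts("C", c(PPPPPP = 3, GGGGGG = 3)))
  fm <- build_frequency_matrix(tabs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_matrix(fm, f, what = "normfreq")
  back <- read_frequency_matrix(f)
  expect_equal(back$ngrams, fm$ngrams)
  expect_equal(back$species, fm$species)
  expect_equal(back$weights, fm$weights)
  expect_equal(back$s, fm$s)
  expect_equal(unname(back$normfreq), unname(fm$normfreq))
})
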