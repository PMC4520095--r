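test_that("enriched counts sum element-wise and union sources", {
  a <- make_counts("sp", c(GGGGGG = 2), dataset = "d1")
  b <- make_counts("sp", c(GGGGGG = 3), dataset = "d2")
  e <- enriched_counts(list(a, b))
  expect_equal(e$counts[ngram == "GGGGGG", count], 5L)
  expect_equal(e$dataset, "enriched")

  d <- enriched_counts(list(make_counts("sp", c(GGGGGG = 2)),
                            make_counts("sp", c(HHHHHH = 3))))
  expect_equal(setNames(d$counts$count, d$counts$ngram),
               c(GGGGGG = 2L, HHHHHH = 3L))

  single <- enriched_counts(list(a))
  expect_equal(single$counts, a$counts)

  expect_error(enriched_counts(list(a, make_counts("other", c(A = 1)))),
               "species mismatch")
})

test_that("dampening weight is IDF-like: unit at N, boosted when rare", {
  expect_equal(dampening_weight(5, 5), 1)
  expect_equal(dampening_weight(1, 5), log2(5) + 1)
  w <- dampening_weight(1:5, 5)
  expect_true(all(diff(w) < 0))
  expect_gt(dampening_weight(2, 5), 1)
  expect_lt(dampening_weight(2, 5), dampening_weight(1, 5))
  expect_error(dampening_weight(0, 5), "1..N")
  expect_error(dampening_weight(6, 5), "1..N")
})

test_that("frequency matrix normalizes per species and weights by rarity", {
  fm <- build_frequency_matrix(list(A = make_counts("A", c(KKKKKK = 3)),
                                    B = make_counts("B", c(DDDDDD = 7))))
  # two species, one private n-gram each: relfreq is the 2x2 identity
  expect_equal(unname(fm$relfreq[match(c("KKKKKK", "DDDDDD"), fm$ngrams), ]),
               diag(2))
  expect_equal(unname(fm$relfreq[match("KKKKKK", fm$ngrams), "A"]), 1)
  expect_equal(unname(fm$relfreq[match("DDDDDD", fm$ngrams), "B"]), 1)
  expect_equal(fm$s, c(1L, 1L))
  expect_equal(fm$weights, c(2, 2))   # log2(2/1) + 1
  expect_equal(unname(fm$normfreq[match("KKKKKK", fm$ngrams), "A"]), 2)
  expect_equal(sum(fm$normfreq[, "A"] == 0), 1L)
})

test_that("identical species get unit weights and identical columns", {
  ct <- c(AAAAAA = 2, CCCCCC = 5, DDDDDD = 3)
  fm <- build_frequency_matrix(list(A = make_counts("A", ct),
                                    B = make_counts("B", ct),
                                    C = make_counts("C", ct)))
  expect_true(all(fm$s == 3L))
  expect_true(all(fm$weights == 1))
  expect_equal(fm$normfreq[, "A"], fm$normfreq[, "C"])
  expect_equal(colSums(fm$relfreq), c(A = 1, B = 1, C = 1))
})

test_that("relative frequencies are invariant under count doubling", {
  set.seed(21)
  cts <- lapply(1:3, function(i)
    setNames(sample(1:20, 8), paste0(random_window(6), 1:8)))
  names(cts) <- c("A", "B", "C")
  mk <- function(mult = 1) build_frequency_matrix(
    lapply(names(cts), function(sp)
      make_counts(sp, cts[[sp]] * if (sp == "B") mult else 1)) |>
      setNames(names(cts)))
  expect_equal(mk(1)$normfreq[, "B"], mk(2)$normfreq[, "B"])
  expect_error(build_frequency_matrix(list(A = make_counts("A", c(X = 1)))),
               "at least 2 species")
})

test_that("discriminative scores match hand-computed toy rows", {
  sp <- paste0("S", 1:5)
  fm <- make_fm(rbind(c(0.6, 0.2, 0.2, 0, 0),
                      c(0.2, 0.2, 0.2, 0.2, 0.2),
                      c(0.5, 0, 0, 0, 0)) |>
                  `colnames<-`(sp))
  r <- discriminative_scores(fm, "ratio")
  d <- discriminative_scores(fm, "difference")
  expect_equal(r$score[1], 3.0)
  expect_equal(d$score[1], 0.4)
  expect_equal(r$top_species[1], "S1")
  expect_equal(r$score[2], 1.0)
  expect_equal(d$score[2], 0.0)
  expect_true(r$tie[2])
  expect_true(is.infinite(r$score[3]) && r$infinite[3])
  expect_equal(d$score[3], 0.5)
  expect_false(any(d$infinite))

  expect_error(discriminative_scores(make_fm(matrix(1, 2, 2,
    dimnames = list(NULL, c("A", "B"))))), ">= 3 species")
})

test_that("scores are invariant under permutation of non-top species", {
  set.seed(22)
  sp <- paste0("S", 1:5)
  for (i in 1:25) {
    row <- sort(runif(5), decreasing = TRUE)
    row[1] <- row[1] + 0.1          # unique top
    m <- matrix(row, 1, 5, dimnames = list(NULL, sp))
    base_r <- discriminative_scores(make_fm(m), "ratio")$score
    base_d <- discriminative_scores(make_fm(m), "difference")$score
    perm <- c(1, 1 + sample(4))
    m2 <- m[, perm, drop = FALSE]
    fm2 <- make_fm(m2, species = colnames(m)[perm])
    expect_equal(discriminative_scores(fm2, "ratio")$score, base_r)
    expect_equal(discriminative_scores(fm2, "difference")$score, base_d)
    expect_equal(discriminative_scores(fm2, "ratio")$top_species, "S1")
  }
})

test_that("selection keeps strictly-above-threshold and infinite scores", {
  sc <- data.frame(ngram = c("g", "h", "i"),
                   top_species = c("A", "A", "B"),
                   f1 = c(0.4, 0.05, 0.5), f2 = 0, f3 = 0,
                   score = c(0.4, 0.04, Inf),
                   infinite = c(FALSE, FALSE, TRUE), tie = FALSE)
  attr(sc, "mode") <- "difference"
  kept <- select_discriminative(sc, T = 0.05)
  expect_equal(kept$A, "g")
  expect_equal(kept$B, "i")

  expect_length(select_discriminative(sc[0, ], 0.05), 0L)
  # boundary: equal-to-T is excluded
  sc$score <- c(0.05, 0.05, 0.05); sc$infinite <- FALSE
  expect_length(select_discriminative(sc, 0.05), 0L)
  expect_error(select_discriminative(sc, 0), "positive")
})

test_that("signature keeps only train-discriminative n-grams present in the paired test species", {
  st <- toy_study()
  res <- run_signature_pipeline(st$windows, st$design, n_min = 6,
                                n_max = 6, T = 0.05, mode = "difference")
  sig <- res$signature
  # the defining rule: planted exclusive n-grams enter with their kingdom
  expect_true(all(c("KKKKKK", "DDDDDD", "PPPPPP") %in% sig$entries$ngram))
  expect_equal(sig$entries$kingdom[match("DDDDDD", sig$entries$ngram)], "KB")
  # every signature n-gram is discriminative for its species AND in the test pair
  for (i in seq_len(nrow(sig$entries))) {
    sp <- sig$entries$top_species[i]
    expect_true(sig$entries$ngram[i] %in% res$discriminative[[sp]])
    ts <- names(st$design$pairing)[st$design$pairing == sp]
    expect_true(sig$entries$ngram[i] %in%
                  res$test_tables[[ts]]$counts$ngram)
  }
  # a train-discriminative n-gram absent from the paired test is excluded:
  # remove KKKKKK from A's test table and rebuild
  tt <- res$test_tables
  tt[["A_te"]]$counts <- tt[["A_te"]]$counts[ngram != "KKKKKK"]
  sig2 <- build_signature(res$discriminative, tt, st$design, res$fm,
                          res$scores, threshold = 0.05)
  expect_false("KKKKKK" %in% sig2$entries$ngram)
  # and a test-present but non-discriminative n-gram never enters
  expect_false(any(!sig$entries$ngram %in%
                     unlist(res$discriminative[sig$entries$top_species])))
})

test_that("planted species-exclusive n-grams are recovered in both score modes", {
  st <- toy_study(n_motif = 10, n_bg = 2)
  for (mode in c("difference", "ratio")) {
    res <- run_signature_pipeline(st$windows, st$design, n_min = 6,
                                  n_max = 6, T = 0.05, mode = mode)
    for (sp in names(st$motifs)) {
      g <- substr(strrep(substr(st$motifs[[sp]], 1, 1), 6), 1, 6)
      idx <- match(g, res$signature$entries$ngram)
      expect_false(is.na(idx), info = paste(mode, g))
      expect_equal(res$signature$entries$top_species[idx],
                   paste0(sp, "_tr"), info = mode)
    }
  }
})

test_that("projection renormalizes over the signature vocabulary with frozen weights", {
  st <- toy_study()
  res <- run_signature_pipeline(st$windows, st$design, n_min = 6,
                                n_max = 6, T = 0.05, mode = "difference")
  sig <- res$signature
  proj <- project_frequencies(sig, res$train_tables)
  expect_equal(proj$weights, sig$entries$weight)
  expect_equal(colSums(proj$relfreq), setNames(rep(1, 3),
                                               st$design$train_species))
  # relfreq = raw counts renormalized over the restricted vocabulary
  expect_equal(proj$relfreq, sweep(proj$raw, 2, colSums(proj$raw), "/"))
  # doubling a test dataset's counts leaves its projected column unchanged
  tt <- res$test_tables
  tt[["A_te"]]$counts <- data.table::copy(tt[["A_te"]]$counts)
  tt[["A_te"]]$counts[, count := count * 2L]
  proj2 <- project_frequencies(sig, tt)
  expect_equal(proj2$normfreq[, "A_te"],
               project_frequencies(sig, res$test_tables)$normfreq[, "A_te"])
  # species with none of the signature n-grams: zero column plus warning
  none <- list(Z = make_counts("Z", c(WWWWWW = 4)))
  expect_warning(pz <- project_frequencies(sig, none), "no signature n-grams")
  expect_true(all(pz$normfreq == 0))
  expect_error(project_frequencies(
    phospho_signature(sig$entries[0, ]), res$train_tables), "empty")
})
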