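## Physico-chemical characterization of discriminative n-grams: binary
## property encodings of their source phosphopeptides, per-property k-means
## partitions and a soft least-squares Euclidean consensus partition.

#' Default binary physico-chemical property table
#'
#' Four residue classes used to profile phosphopeptide windows:
#' hydrophobic (A,C,F,I,L,M,V), negative (D,E), positive (K,R,H) and
#' proline (P). Override with your own table via [read_property_table()] to
#' substitute a different classification scheme.
#'
#' @return named list property -> character vector of residues.
#' @export
default_property_table <- function() {
  list(hydrophobic = c("A", "C", "F", "I", "L", "M", "V"),
       negative = c("D", "E"),
       positive = c("K", "R", "H"),
       proline = "P")
}

#' Read a property table
#'
#' TSV with columns `property` and `residues` (comma-separated one-letter
#' codes).
#'
#' @param path file path.
#' @return named list property -> residues.
#' @export
read_property_table <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("property", "residues") %in% names(d)))
    stop("property table needs columns 'property' and 'residues'")
  if (anyDuplicated(d$property)) stop("duplicate property names")
  props <- lapply(strsplit(d$residues, ","), trimws)
  names(props) <- d$property
  bad <- !vapply(props, function(p) all(p %in% AA_ALPHABET), logical(1))
  if (any(bad))
    stop("residues outside the 20-letter alphabet in property: ",
         paste(names(props)[bad], collapse = ", "))
  props
}

#' Encode one window by binary physico-chemical properties
#'
#' Aligns the window on its central phosphosite (column 11 of 21) and marks
#' each position 1 if the residue belongs to the property set, 0 otherwise.
#' Positions outside a truncated window and `X` residues are `NA` (masked).
#'
#' @param window a window sequence (single string).
#' @param offset 0-based offset of the phosphosite within the window.
#' @param props property table (default [default_property_table()]).
#' @param width alignment width (default 21).
#' @return numeric matrix properties x width with `NA` masks.
#' @export
encode_window <- function(window, offset, props = default_property_table(),
                          width = 21L) {
  center <- (width + 1L) %/% 2L
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  cols <- seq_along(chars) - (offset + 1L) + center
  keep <- cols >= 1L & cols <= width
  out <- matrix(NA_real_, nrow = length(props), ncol = width,
                dimnames = list(names(props), NULL))
  for (p in seq_along(props)) {
    v <- as.numeric(chars %in% props[[p]])
    v[chars == "X"] <- NA_real_
    out[p, cols[keep]] <- v[keep]
  }
  out
}

## encodings of many windows -> array (window x property x position)
.encode_all <- function(windows, props, width = 21L) {
  n <- nrow(windows)
  arr <- array(NA_real_, dim = c(n, length(props), width),
               dimnames = list(windows$wid, names(props), NULL))
  for (i in seq_len(n))
    arr[i, , ] <- encode_window(windows$window[i], windows$offset[i],
                                props, width)
  arr
}

#' Average physico-chemical profile of an n-gram
#'
#' Maps the n-gram back to the windows that contain it and averages the
#' binary property encodings position-wise, ignoring masked positions.
#'
#' @param ngram an n-gram string.
#' @param counts an `ngram_counts` whose `sources` cover the n-gram.
#' @param windows the `phospho_windows` the counts were built from (or any
#'   superset containing the source `wid`s).
#' @param props property table.
#' @return a `physchem_profile`: `ngram`, `profile` (properties x 21, values
#'   in `[0,1]`, `NaN` where every window is masked) and `n_windows`.
#' @export
profile_ngram <- function(ngram, counts, windows,
                          props = default_property_table()) {
  .query_ngram <- ngram
  wids <- counts$sources[J(.query_ngram), wid, nomatch = NULL]
  if (!length(wids)) stop("n-gram has no source windows: ", ngram)
  w <- windows[match(wids, windows$wid), , drop = FALSE]
  if (anyNA(w$wid)) stop("source window ids not found in `windows`")
  arr <- .encode_all(w, props)
  prof <- apply(arr, c(2, 3), function(v) mean(v, na.rm = TRUE))
  dimnames(prof) <- list(names(props), NULL)
  structure(list(ngram = ngram, profile = prof, n_windows = nrow(w)),
            class = "physchem_profile")
}

#' Fixed-length profile vectors for a set of n-grams
#'
#' Concatenates each n-gram's per-property 21-vectors into one row of an
#' (n-grams x properties*21) matrix suitable for k-means and the consensus
#' step. Positions masked in every source window are imputed with the
#' property's global mean over all supplied windows.
#'
#' @param ngrams character vector.
#' @inheritParams profile_ngram
#' @return numeric matrix with n-gram rownames; per-property column blocks
#'   are recorded in attribute `"blocks"`.
#' @export
physchem_profiles <- function(ngrams, counts, windows,
                              props = default_property_table()) {
  width <- 21L
  chars <- unlist(strsplit(windows$window, "", fixed = TRUE))
  chars <- chars[chars != "X"]
  global_mean <- vapply(props, function(set) mean(chars %in% set),
                        numeric(1))
  .query <- unique(ngrams)
  src <- counts$sources[J(.query), , nomatch = NULL]
  miss <- setdiff(ngrams, src$ngram)
  if (length(miss))
    stop("n-gram(s) with no source windows: ",
         paste(head(miss, 5), collapse = ", "))
  wids_needed <- unique(src$wid)
  w <- windows[match(wids_needed, windows$wid), , drop = FALSE]
  if (anyNA(w$wid)) stop("source window ids not found in `windows`")
  arr <- .encode_all(w, props, width)  # windows x properties x positions
  rowidx <- split(match(src$wid, wids_needed), src$ngram)
  out <- matrix(NA_real_, nrow = length(ngrams),
                ncol = length(props) * width,
                dimnames = list(ngrams, NULL))
  for (i in seq_along(ngrams)) {
    idx <- rowidx[[ngrams[i]]]
    for (p in seq_along(props)) {
      v <- colMeans(arr[idx, p, , drop = FALSE], na.rm = TRUE, dims = 1)
      v <- as.numeric(v)
      v[!is.finite(v)] <- global_mean[p]
      out[i, (p - 1L) * width + seq_len(width)] <- v
    }
  }
  attr(out, "blocks") <- setNames(lapply(seq_along(props), function(p)
    (p - 1L) * width + seq_len(width)), names(props))
  out
}

#' Per-property k-means partition of n-gram profiles
#'
#' Lloyd's k-means (squared-Euclidean objective) with k-means++ (D^2)
#' seeding, keeping the best of `restarts` starts; a degenerate start
#' producing an empty cluster is discarded.
#'
#' @param profiles numeric matrix (items x features), e.g. one property
#'   block of [physchem_profiles()].
#' @param k number of clusters (default 10).
#' @param seed integer seed.
#' @param restarts random restarts (default 10).
#' @return integer cluster labels (1..k) named by rownames, with the
#'   within-cluster sum of squares in attribute `"tot_withinss"`.
#' @export
kmeans_partition <- function(profiles, k = 10L, seed = 1L, restarts = 10L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < k)
    stop("need at least k = ", k, " items, got ", nrow(profiles))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- tryCatch(
      suppressWarnings(kmeans(profiles, centers = .kmeanspp(profiles, k),
                              algorithm = "Lloyd", iter.max = 200L)),
      error = function(e) NULL)
    if (is.null(fit) || length(unique(fit$cluster)) < k) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("k-means found no valid k-cluster partition in ", restarts,
         " starts (too few distinct profiles?)")
  structure(as.integer(best$cluster),
            names = rownames(profiles), tot_withinss = best$tot.withinss)
}

## k-means++ D^2 seeding: spread the initial centers so every well
## separated group is hit with high probability
.kmeanspp <- function(x, k) {
  n <- nrow(x)
  ids <- integer(k)
  ids[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2, x[ids[1], ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    ids[j] <- if (sum(d2) == 0) sample.int(n, 1L)
              else sample.int(n, 1L, prob = d2 / sum(d2))
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[ids[j], ])^2))
  }
  x[ids, , drop = FALSE]
}

## n x k indicator matrix of a hard partition
.indicator <- function(labels, k) {
  M <- matrix(0, nrow = length(labels), ncol = k)
  M[cbind(seq_along(labels), labels)] <- 1
  M
}

#' Soft least-squares Euclidean consensus partition
#'
#' Reconciles several hard partitions of the same items into one soft
#' consensus membership `M` minimizing `sum_b ||M - M_b P_b||^2` over
#' simplex-row memberships and per-input label permutations `P_b`, by
#' alternating optimal label matching (linear assignment) with averaging of
#' the matched memberships. The objective is non-increasing across
#' iterations; the best of one start per input partition is returned.
#'
#' @param partitions list of >= 2 integer label vectors over the same items
#'   (values in 1..k), e.g. several [kmeans_partition()] results.
#' @param k number of consensus classes (defaults to the max input label).
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   objective.
#' @return a `consensus_clustering`: `membership` (items x k, rows sum
#'   to 1), `labels` (hardened argmax, named like the inputs), `objective`,
#'   `trace` (objective per iteration) and the matched input partitions.
#' @export
consensus_partition <- function(partitions, k = NULL, max_iter = 100L,
                                tol = 1e-9) {
  if (length(partitions) < 2L) stop("need >= 2 input partitions")
  n <- length(partitions[[1]])
  if (any(lengths(partitions) != n))
    stop("partitions cover different item sets")
  nm <- names(partitions[[1]])
  if (!is.null(nm)) {
    same <- vapply(partitions, function(p) identical(names(p), nm),
                   logical(1))
    if (!all(same)) stop("partitions cover different item sets")
  }
  if (is.null(k)) k <- max(unlist(partitions))
  memb <- lapply(partitions, function(p) .indicator(as.integer(p), k))
  run <- function(M0) {
    M <- M0
    trace <- numeric(0)
    obj_prev <- Inf
    matched <- memb
    for (it in seq_len(max_iter)) {
      matched <- lapply(memb, function(Mb) {
        sigma <- .best_label_match(crossprod(Mb, M))
        Mb %*% .indicator(sigma, k)   # permute input labels onto consensus
      })
      M <- Reduce(`+`, matched) / length(matched)
      obj <- sum(vapply(matched, function(Mb) sum((M - Mb)^2), numeric(1)))
      trace <- c(trace, obj)
      if (obj_prev - obj < tol) break
      obj_prev <- obj
    }
    list(M = M, obj = obj, trace = trace, matched = matched)
  }
  best <- NULL
  for (M0 in memb) {
    res <- run(M0)
    if (is.null(best) || res$obj < best$obj) best <- res
  }
  labels <- max.col(best$M, ties.method = "first")
  names(labels) <- nm
  rownames(best$M) <- nm
  structure(list(membership = best$M, labels = labels,
                 objective = best$obj, trace = best$trace, k = k,
                 partitions = partitions),
            class = "consensus_clustering")
}

#' @export
print.consensus_clustering <- function(x, ...) {
  cat(sprintf("consensus_clustering: %d items, k = %d, objective %.6g (%d inputs)\n",
              nrow(x$membership), x$k, x$objective, length(x$partitions)))
  invisible(x)
}

#' Per-species distribution of consensus clusters
#'
#' For each species, among the signature n-grams present in it (raw count
#' > 0), the fraction belonging to each consensus cluster. Rows sum to 1
#' for species containing at least one signature n-gram.
#'
#' @param consensus a `consensus_clustering` over the signature n-grams.
#' @param sig the `phospho_signature`.
#' @param species_tables named list species -> `ngram_counts`.
#' @return matrix species x cluster of proportions.
#' @export
cluster_distribution <- function(consensus, sig, species_tables) {
  gn <- names(consensus$labels)
  miss <- setdiff(sig$entries$ngram, gn)
  if (length(miss))
    stop("consensus does not cover signature n-gram(s): ",
         paste(head(miss, 5), collapse = ", "))
  species <- names(species_tables)
  out <- matrix(0, nrow = length(species), ncol = consensus$k,
                dimnames = list(species, paste0("cluster", seq_len(consensus$k))))
  for (i in seq_along(species)) {
    present <- intersect(sig$entries$ngram,
                         species_tables[[i]]$counts$ngram)
    if (!length(present)) next
    lab <- consensus$labels[present]
    out[i, ] <- tabulate(lab, consensus$k) / length(lab)
  }
  out
}
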