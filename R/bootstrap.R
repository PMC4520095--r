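## Multiscale bootstrap support for the species dendrogram: per-edge
## bootstrap probabilities (BP) at several resampling scales and
## approximately-unbiased (AU) p-values from the probit fit
## qnorm(1 - BP_r) = v*sqrt(r) + c/sqrt(r).

## leaf sets of each internal node of an hclust, encoded as bitmasks over
## column indices (requires < 31 leaves, plenty for species trees)
.clade_masks <- function(merge) {
  n <- nrow(merge)
  masks <- integer(n)
  for (i in seq_len(n)) {
    a <- merge[i, 1L]; b <- merge[i, 2L]
    ma <- if (a < 0L) bitwShiftL(1L, -a - 1L) else masks[a]
    mb <- if (b < 0L) bitwShiftL(1L, -b - 1L) else masks[b]
    masks[i] <- bitwOr(ma, mb)
  }
  masks
}

## probit fit of one edge's per-scale bootstrap probabilities:
## qnorm(1 - BP_r) = v*sqrt(r) + c/sqrt(r) by WLS with delta-method
## binomial weights; AU = 1 - pnorm(v - c), BP reported at the scale
## closest to 1. BP_r of exactly 0/1 are clamped into
## [1/(n_boot+1), n_boot/(n_boot+1)]; an edge at the same boundary at
## every scale gets AU 1 (or 0) without a fit.
.fit_au <- function(bp, scales, n_boot) {
  if (all(bp == 1)) return(c(bp1 = 1, au = 1, v = 0, c = 0))
  if (all(bp == 0)) return(c(bp1 = 0, au = 0, v = 0, c = 0))
  lo <- 1 / (n_boot + 1)
  bpc <- pmin(pmax(bp, lo), 1 - lo)
  z <- qnorm(1 - bpc)
  w <- n_boot * dnorm(z)^2 / (bpc * (1 - bpc))
  sq <- sqrt(scales)
  X <- cbind(v = sq, c = 1 / sq)
  cf <- tryCatch(lm.wfit(X, z, w)$coefficients,
                 error = function(e) c(v = mean(z) / 2, c = mean(z) / 2))
  cf[!is.finite(cf)] <- 0
  c(bp1 = unname(bp[which.min(abs(scales - 1))]),
    au = 1 - pnorm(cf[["v"]] - cf[["c"]]), v = cf[["v"]], c = cf[["c"]])
}

#' Multiscale bootstrap of the species dendrogram
#'
#' Reclusters `n_boot` row-resamples of the frequency matrix at each scale
#' `r` (resampling `round(r * G)` of the `G` n-gram rows with replacement),
#' records each original edge's presence frequency `BP_r`, fits
#' `qnorm(1 - BP_r) = v*sqrt(r) + c/sqrt(r)` per edge by weighted least
#' squares (delta-method binomial weights), and reports `AU = 1 -
#' pnorm(v - c)` plus the plain bootstrap probability at `r = 1`. Degenerate
#' `BP_r` of 0 or 1 are clamped to `[1/(n_boot+1), n_boot/(n_boot+1)]`
#' before the probit transform; an edge recovered in every (no) replicate
#' at every scale gets `AU = 1` (`0`) without a fit.
#'
#' @param fm a `frequency_matrix` (species columns are clustered).
#' @param scales resampling scale factors (default `seq(0.5, 1.4, 0.1)`).
#' @param n_boot bootstrap replicates per scale (>= 100).
#' @param seed integer seed; all resampling flows from it.
#' @param distance,linkage as in [hierarchical_cluster()].
#' @return a `bootstrap_dendrogram`: the base `hclust`, an `edges` table
#'   (members, `bp`, `au`, `v`, `c`), the per-scale `bp_table`, and the
#'   parameters used.
#' @export
multiscale_bootstrap <- function(fm, scales = seq(0.5, 1.4, by = 0.1),
                                 n_boot = 1000L, seed = 1L,
                                 distance = c("correlation", "euclidean"),
                                 linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (any(scales <= 0)) stop("scales must be positive")
  if (n_boot < 100L) stop("n_boot must be >= 100")
  method <- if (linkage == "ward") "ward.D2" else linkage
  m <- fm$normfreq
  colnames(m) <- fm$species
  if (ncol(m) >= 31L) stop("more than 30 species not supported")
  base <- hclust(.species_dist(m, distance), method = method)
  base$labels <- fm$species
  base_masks <- .clade_masks(base$merge)
  G <- nrow(m)
  set.seed(as.integer(seed))
  bp_table <- matrix(0, nrow = length(base_masks), ncol = length(scales),
                     dimnames = list(NULL, paste0("r", scales)))
  for (si in seq_along(scales)) {
    msize <- max(2L, as.integer(round(scales[si] * G)))
    hits <- integer(length(base_masks))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(G, msize, replace = TRUE)
      hc <- hclust(.species_dist(m[idx, , drop = FALSE], distance,
                                 strict = FALSE), method = method)
      hits <- hits + (base_masks %in% .clade_masks(hc$merge))
    }
    bp_table[, si] <- hits / n_boot
  }
  fits <- t(apply(bp_table, 1, .fit_au, scales = scales, n_boot = n_boot))
  members <- vapply(base_masks, function(msk)
    paste(fm$species[bitwAnd(bitwShiftL(1L, seq_along(fm$species) - 1L),
                             msk) != 0L], collapse = "|"),
    character(1))
  edges <- data.frame(members = members, bp = fits[, "bp1"],
                      au = fits[, "au"], v = fits[, "v"], c = fits[, "c"],
                      stringsAsFactors = FALSE)
  structure(list(hclust = base, edges = edges, bp_table = bp_table,
                 scales = scales, n_boot = n_boot, distance = distance,
                 linkage = linkage, seed = seed),
            class = "bootstrap_dendrogram")
}

#' @export
print.bootstrap_dendrogram <- function(x, ...) {
  cat(sprintf("bootstrap_dendrogram: %d species, %d edges, n_boot %d (%s/%s)\n",
              length(x$hclust$labels), nrow(x$edges), x$n_boot,
              x$distance, x$linkage))
  print(x$edges[, c("members", "bp", "au")], row.names = FALSE)
  invisible(x)
}

#' Edge support of a species pair
#'
#' Convenience lookup: BP and AU of the dendrogram edge whose members are
#' exactly the given species set, or `NA` if the tree has no such edge.
#'
#' @param bd a `bootstrap_dendrogram`.
#' @param species character vector of member species.
#' @return named numeric `c(bp =, au =)`.
#' @export
edge_support <- function(bd, species) {
  key <- vapply(strsplit(bd$edges$members, "|", fixed = TRUE),
                function(s) paste(sort(s), collapse = "|"), character(1))
  i <- match(paste(sort(species), collapse = "|"), key)
  if (is.na(i)) return(c(bp = NA_real_, au = NA_real_))
  c(bp = bd$edges$bp[i], au = bd$edges$au[i])
}

#' Export the bootstrap dendrogram as Newick
#'
#' Internal nodes are labelled `AUxx/BPyy` (percentages), the convention
#' used for annotated support trees.
#'
#' @param bd a `bootstrap_dendrogram`.
#' @param path output file path.
#' @export
write_dendrogram_newick <- function(bd, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("write_dendrogram_newick requires the ape package")
  phy <- ape::as.phylo(bd$hclust)
  nt <- length(phy$tip.label)
  parts <- ape::prop.part(phy)
  tipidx <- match(phy$tip.label, bd$hclust$labels)
  node_keys <- vapply(parts, function(p)
    paste(sort(bd$hclust$labels[tipidx[p]]), collapse = "|"), character(1))
  edge_keys <- vapply(strsplit(bd$edges$members, "|", fixed = TRUE),
                      function(s) paste(sort(s), collapse = "|"),
                      character(1))
  i <- match(node_keys, edge_keys)
  phy$node.label <- ifelse(is.na(i), "",
                           sprintf("AU%.0f/BP%.0f", 100 * bd$edges$au[i],
                                   100 * bd$edges$bp[i]))
  ape::write.tree(phy, file = path)
  invisible(path)
}
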