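## Supervised evaluation of the signature: kernel SVM over species
## frequency profiles, plus plain hierarchical clustering.

#' Normalized polynomial kernel
#'
#' `K~(x,y) = K(x,y) / sqrt(K(x,x) K(y,y))` with
#' `K(x,y) = (x . y + 1)^d`, so `K~(x,x) = 1` for every `x`.
#'
#' @param degree polynomial degree `d` (default 2).
#' @return a `kernlab`-compatible kernel function (class `"kernel"`).
#' @export
normalized_poly_kernel <- function(degree = 2) {
  force(degree)
  k <- function(x, y = NULL) {
    if (is.null(y)) y <- x
    raw <- function(a, b) (sum(a * b) + 1)^degree
    raw(x, y) / sqrt(raw(x, x) * raw(y, y))
  }
  class(k) <- "kernel"
  k
}

#' Classify test species against training species with a kernel SVM
#'
#' Trains a multi-class (one-vs-one) support vector classifier with the
#' normalized polynomial kernel on the training species' signature-restricted
#' normalized frequency profiles, then assigns each test species to one
#' training class. Feature spaces must be aligned on an identical n-gram
#' ordering (both matrices from [project_frequencies()] on the same
#' signature).
#'
#' @param train_fm training `frequency_matrix` (columns are feature vectors).
#' @param test_fm projected test `frequency_matrix` on the same vocabulary.
#' @param labels optional named vector mapping training species to class
#'   labels; defaults to the species labels themselves.
#' @param design optional `study_design`; when given, accuracy is the
#'   fraction of test species assigned to their paired training species.
#' @param degree,C kernel degree and SVM cost (defaults 2 and 1).
#' @return a `classification_result`: `assigned` (named vector test species
#'   -> predicted class), `confusion` (0/1 matrix test x train classes, rows
#'   sum to 1) and `accuracy` (NA without `design`).
#' @export
train_and_classify <- function(train_fm, test_fm, labels = NULL,
                               design = NULL, degree = 2, C = 1) {
  if (!identical(train_fm$ngrams, test_fm$ngrams))
    stop("train and test matrices are not aligned on the same n-grams")
  x <- t(train_fm$normfreq)
  classes <- if (is.null(labels)) setNames(train_fm$species, train_fm$species)
             else labels[train_fm$species]
  y <- factor(unname(classes), levels = unique(unname(classes)))
  zero <- colSums(abs(test_fm$normfreq)) == 0
  if (any(zero))
    warning("all-zero test feature column(s), assignment is degenerate: ",
            paste(test_fm$species[zero], collapse = ", "))
  fit <- kernlab::ksvm(x, y, type = "C-svc",
                       kernel = normalized_poly_kernel(degree),
                       C = C, scaled = FALSE)
  pred <- as.character(kernlab::predict(fit, t(test_fm$normfreq)))
  assigned <- setNames(pred, test_fm$species)
  confusion <- matrix(0L, nrow = length(assigned), ncol = nlevels(y),
                      dimnames = list(test_fm$species, levels(y)))
  confusion[cbind(seq_along(assigned), match(pred, levels(y)))] <- 1L
  accuracy <- NA_real_
  if (!is.null(design)) {
    expected <- unname(classes[design$pairing[test_fm$species]])
    accuracy <- mean(pred == expected)
  }
  structure(list(assigned = assigned, confusion = confusion,
                 accuracy = accuracy),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("classification_result",
      if (!is.na(x$accuracy)) sprintf("(accuracy %.3f)", x$accuracy), "\n")
  print(x$confusion)
  invisible(x)
}

#' Write a confusion matrix as TSV
#'
#' @param result a `classification_result`.
#' @param path output file path.
#' @export
write_confusion <- function(result, path) {
  d <- data.frame(test_species = rownames(result$confusion),
                  result$confusion, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.species_dist <- function(m, distance, strict = TRUE) {
  if (distance == "correlation") {
    sds <- apply(m, 2, function(v) sd(v))
    if (any(sds == 0)) {
      if (strict)
        stop("constant column under correlation distance: ",
             paste(colnames(m)[sds == 0], collapse = ", "))
      ## bootstrap replicates: treat a degenerate column as uncorrelated
      cc <- suppressWarnings(cor(m))
      cc[!is.finite(cc)] <- 0
      diag(cc) <- 1
      return(as.dist(1 - cc))
    }
    as.dist(1 - cor(m))
  } else {
    dist(t(m))
  }
}

#' Hierarchical clustering of species frequency profiles
#'
#' Agglomerative clustering of the species columns of a frequency matrix,
#' by default with correlation distance (`1 - cor`) and average linkage.
#'
#' @param fm a `frequency_matrix` with >= 2 species.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage `"average"`, `"complete"` or `"ward"` (ward.D2).
#' @return an `hclust` object with species labels.
#' @export
hierarchical_cluster <- function(fm, distance = c("correlation", "euclidean"),
                                 linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (length(fm$species) < 2L) stop("need >= 2 species columns")
  m <- fm$normfreq
  colnames(m) <- fm$species
  d <- .species_dist(m, distance)
  hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
}
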