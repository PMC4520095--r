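#' Define a train/test study design
#'
#' Describes which species are used for training and testing, the
#' kingdom/phylum of each species, the fixed pairing of each test species
#' with the training species of the same kingdom/phylum, and the datasets
#' available per species.
#'
#' @param train_species,test_species ordered character vectors of species
#'   labels (opaque strings; taxonomy is never inferred).
#' @param pairing named character vector mapping each test species to its
#'   paired training species; must be a bijection onto `train_species`.
#' @param kingdom_of named character vector mapping every species to its
#'   kingdom/phylum label.
#' @param datasets_of named list mapping every species to its dataset ids.
#' @return a `study_design` object.
#' @export
study_design <- function(train_species, test_species, pairing, kingdom_of,
                         datasets_of) {
  train_species <- as.character(train_species)
  test_species <- as.character(test_species)
  if (!setequal(names(pairing), test_species))
    stop("pairing must be keyed by exactly the test species")
  if (!setequal(unname(pairing), train_species) ||
      anyDuplicated(unname(pairing)))
    stop("pairing must be a bijection onto the training species")
  all_sp <- c(train_species, test_species)
  miss <- setdiff(all_sp, names(kingdom_of))
  if (length(miss))
    stop("kingdom_of is missing species: ", paste(miss, collapse = ", "))
  bad <- vapply(test_species, function(ts)
    kingdom_of[[ts]] != kingdom_of[[pairing[[ts]]]], logical(1))
  if (any(bad))
    stop("pairing crosses kingdoms for: ",
         paste(test_species[bad], collapse = ", "))
  miss <- setdiff(all_sp, names(datasets_of))
  if (length(miss))
    stop("datasets_of is missing species: ", paste(miss, collapse = ", "))
  structure(list(train_species = train_species,
                 test_species = test_species,
                 pairing = pairing[test_species],
                 kingdom_of = kingdom_of,
                 datasets_of = datasets_of),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", length(x$train_species), "training /",
      length(x$test_species), "test species\n")
  for (ts in x$test_species)
    cat(sprintf("  %s -> %s  [%s]\n", ts, x$pairing[[ts]],
                x$kingdom_of[[ts]]))
  invisible(x)
}

#' Read or write a study design as YAML
#'
#' The YAML file holds keys `train_species`, `test_species`, `pairing`
#' (map test -> train), `kingdom_of` (map species -> kingdom/phylum) and
#' `datasets_of` (map species -> list of dataset ids).
#'
#' @param path file path.
#' @return `read_study_design` returns a `study_design`;
#'   `write_study_design` returns `path` invisibly.
#' @export
read_study_design <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("train_species", "test_species", "pairing", "kingdom_of",
            "datasets_of")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("study design ", path, " is missing key(s): ",
         paste(miss, collapse = ", "))
  study_design(unlist(y$train_species), unlist(y$test_species),
               unlist(y$pairing), unlist(y$kingdom_of), y$datasets_of)
}

#' @rdname read_study_design
#' @param design a `study_design` object.
#' @export
write_study_design <- function(design, path) {
  yaml::write_yaml(list(train_species = design$train_species,
                        test_species = design$test_species,
                        pairing = as.list(design$pairing),
                        kingdom_of = as.list(design$kingdom_of),
                        datasets_of = design$datasets_of),
                   path)
  invisible(path)
}
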