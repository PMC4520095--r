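## End-to-end convenience wrapper: windows -> counts -> enriched counts ->
## frequency matrix -> discriminative selection -> signature -> projections.

#' Run the discriminative n-gram signature pipeline
#'
#' From a window table covering every training and test dataset of a study
#' design: counts n-grams per dataset, sums per-species enriched counts,
#' builds the training frequency matrix with dampening weights, scores and
#' selects discriminative n-grams, assembles the kingdom/phylum signature
#' (training discriminative n-grams also present in the paired test
#' species), and projects both the training species and all species onto
#' the signature vocabulary.
#'
#' @param windows a `phospho_windows` data.frame containing every dataset
#'   listed in `design`.
#' @param design a `study_design`.
#' @param n_min,n_max n-gram length range (defaults 6 and 21).
#' @param T discriminative threshold (default 0.05).
#' @param mode score mode, `"ratio"` (default) or `"difference"`.
#' @return list with `dataset_tables` (per dataset `ngram_counts`),
#'   `train_tables` and `test_tables` (per species enriched counts), `fm`
#'   (training frequency matrix), `scores`, `discriminative` (per-species
#'   n-gram sets), `signature`, `proj_train` and `proj_all` (projected
#'   frequency matrices over the signature vocabulary).
#' @export
run_signature_pipeline <- function(windows, design, n_min = 6L,
                                   n_max = 21L, T = 0.05,
                                   mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  all_species <- c(design$train_species, design$test_species)
  dataset_tables <- list()
  for (sp in all_species) {
    for (ds in design$datasets_of[[sp]]) {
      sel <- windows$species == sp & windows$dataset == ds
      if (!any(sel)) stop("no windows for dataset ", ds, " of ", sp)
      dataset_tables[[ds]] <- count_dataset(windows[sel, , drop = FALSE],
                                            n_min, n_max)
    }
  }
  per_species <- function(sps) setNames(lapply(sps, function(sp)
    enriched_counts(dataset_tables[design$datasets_of[[sp]]])), sps)
  train_tables <- per_species(design$train_species)
  test_tables <- per_species(design$test_species)
  fm <- build_frequency_matrix(train_tables)
  scores <- discriminative_scores(fm, mode)
  discr <- select_discriminative(scores, T)
  sig <- build_signature(discr, test_tables, design, fm, scores,
                         threshold = T)
  proj_train <- proj_all <- NULL
  if (nrow(sig$entries)) {
    proj_train <- project_frequencies(sig, train_tables)
    proj_all <- project_frequencies(sig, c(train_tables, test_tables))
  }
  list(dataset_tables = dataset_tables, train_tables = train_tables,
       test_tables = test_tables, fm = fm, scores = scores,
       discriminative = discr, signature = sig,
       proj_train = proj_train, proj_all = proj_all)
}
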