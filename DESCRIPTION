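Package: phosphosig
Title: Discriminative N-Gram Signatures for Comparative Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of serine phosphorylation across species
    through discriminative n-grams. Extracts serine-centered phosphopeptide
    windows, enumerates and counts n-grams (6-21mers), computes dampened
    (IDF-weighted) normalized frequencies, selects n-grams that discriminate
    species, and assembles a kingdom/phylum signature validated on paired test
    species. The signature is evaluated by a support vector classifier with a
    normalized polynomial kernel and by hierarchical clustering with multiscale
    bootstrap support (BP and AU values). Discriminative n-grams are grouped by
    binary physico-chemical profiles using per-property k-means and a soft
    least-squares Euclidean consensus partition, and summarized as sequence
    logo matrices (position frequencies and information content). A seeded
    synthetic-data generator plants kingdom-specific motifs so the whole
    pipeline can be exercised against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    kernlab,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
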