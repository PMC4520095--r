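---
title: "Discriminative n-gram signatures for comparative phosphoproteomics"
author: "phosphosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative n-gram signatures for comparative phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphosig)
```

## The problem

High-throughput phosphoproteomics has produced serine-phosphosite catalogues
for many eukaryotes. Classical motif finders (motif-x, MMFPh) assign each
phosphopeptide to a single motif and degrade on datasets of very different
sizes, which makes them poor instruments for asking a *comparative* question:
which short sequence patterns around phosphoserines are characteristic of a
kingdom or phylum rather than of an individual dataset?

`phosphosig` approaches the question with n-grams. Every contiguous substring
(6–21 residues) of every serine-centered 21-mer window is a feature; a
pattern does not have to be anchored on the phosphosite, windows may support
many patterns at once, and frequency normalization plus an IDF-style
dampening factor make differently sized datasets comparable. The package
covers the full analysis: window extraction, n-gram counting, dampened
normalized frequencies, discriminative selection, a kingdom/phylum signature
validated on paired test species, supervised (SVM) and unsupervised
(bootstrap dendrogram) evaluation, physico-chemical consensus clusters of
the discriminative n-grams, and sequence-logo matrices of the top n-grams.

## Data model

A *phosphopeptide window* is up to 21 residues centered on a phosphoserine.
At protein termini windows are **truncated, never padded**: padding
characters would pollute the n-gram alphabet, and the bookkeeping (a 0-based
`offset` of the phosphosite inside the window) keeps truncated windows
alignable. Windows admit the 20-letter alphabet plus `X` for unknown
residues; any n-gram that would span an `X` is dropped so the n-gram
alphabet stays exact. Strict mode (the default) requires the central residue
to be serine; a `center` switch admits T/Y for reuse on other acceptor
types.

A *study design* fixes the training species (two replicate datasets each),
the test species (one dataset each), each species' kingdom/phylum, and the
bijective pairing of each test species with the training species of the same
kingdom/phylum. Pairing is always supplied explicitly — the package never
infers taxonomy from labels.

## The frequency model

Per species, counts from replicate datasets are summed into *enriched
counts* (multiplicity counting: a window containing an n-gram twice
contributes two). Over the union vocabulary of `G` n-grams and `N` training
species:

* relative frequency: `relfreq[g, i] = count[g, i] / sum_g count[g, i]`
  (columns sum to 1);
* species presence: `s(g)` = number of training species with `count > 0`;
* dampening weight: `w(g) = log2(N / s(g)) + 1`, strictly decreasing in
  `s(g)` and exactly 1 for an n-gram present in every species;
* dampened normalized frequency: `normfreq = relfreq * w(g)`.

The weight is the IDF form familiar from document retrieval: n-grams
confined to few species are boosted, ubiquitous ones are left alone. The
qualitative contract (more weight to n-grams in fewer species) admits many
formulas; this one is the simplest that is unit-normalized at `s = N`,
and it is recorded in the signature so projections reuse it unchanged.

## Discriminative scores and the signature

For each n-gram the species are ranked by `normfreq`; with `f1 >= f2 >= f3`
the three largest values, two score modes are available:

* **ratio** (default): `f1 / ((f2 + f3) / 2)`, flagged infinite when
  `f2 = f3 = 0`;
* **difference**: `f1 - (f2 + f3) / 2`.

An n-gram is *discriminative for its top species* when its score exceeds the
threshold `T` (default 0.05, strict inequality; infinite-flagged ratios are
always kept). The default is ratio mode: on any realistically sized
vocabulary (10^5–10^6 n-grams) every individual relative frequency is of
order 10^-3 or far smaller, so no *difference* of relative frequencies can
clear a fixed threshold like 0.05 — difference mode with that threshold
selects nothing outside of toy vocabularies. In ratio mode the threshold is
deliberately permissive; the selectivity of the method comes from the next
step. Difference mode remains available (`mode = "difference"`) and is the
natural choice when a user wants a threshold on the frequency scale itself,
e.g. on small controlled vocabularies.

The *signature* applies the filter that makes the selection biological
rather than statistical noise: a discriminative n-gram of training species
`i` enters the signature only if it is also observed in the test species
paired with `i` (same kingdom/phylum). Species-exclusive background strings
almost never recur in an independent dataset of the same kingdom, while
genuinely kingdom-specific patterns do. Each signature entry freezes its
score and its training dampening weight, so the signature is a fixed model:
projecting any species onto it recomputes relative frequencies **over the
signature vocabulary only** and multiplies by the frozen weights. Training
projections use the same rule, so train and test columns are directly
comparable.

Ties for the top species are broken by the training-species order of the
study design and flagged in the score table; determinism was preferred over
any attempt to split ties "fairly".

## Classification

*Supervised.* One feature vector per species (the signature-restricted
normalized frequencies), labelled by training species; a one-vs-one SVM with
the normalized polynomial kernel
`K~(x, y) = K(x, y) / sqrt(K(x, x) K(y, y))`, `K(x, y) = (x·y + 1)^d`,
`d = 2`, `C = 1`. The kernel normalization is implemented and unit-tested in
the package; the max-margin optimization is delegated to `kernlab::ksvm`.
Species-level features match the species-by-species confusion matrix the
method is evaluated with; a per-dataset variant (10 training vectors) can be
had by projecting per-dataset count tables instead.

*Unsupervised.* Hierarchical clustering of the species columns (correlation
distance, average linkage by default) with multiscale bootstrap support.
For each scale `r` in 0.5–1.4 (step 0.1), `round(r * G)` n-gram rows are
resampled with replacement `n_boot` times and the tree recomputed; each
original edge's recovery frequency `BP_r` is recorded. Per edge, the probit
transform `qnorm(1 - BP_r)` is fitted as `v * sqrt(r) + c / sqrt(r)` by
weighted least squares (delta-method binomial weights), and
`AU = 1 - pnorm(v - c)`; the plain bootstrap probability is reported at
`r = 1`. Degenerate `BP_r` values of 0 or 1 are clamped to
`[1/(n_boot+1), n_boot/(n_boot+1)]` before the transform. An edge recovered
in *every* replicate at *every* scale carries no information about the
curvature `c`; the basis functions `sqrt(r)` and `1/sqrt(r)` are nearly
collinear over the scale range and the fitted `v - c` is then an artifact of
the collinearity, so such edges are assigned `AU = 1` (respectively 0 for
never-recovered edges) directly. `BP_r = 0.5` at every scale is a fixed
point of the fit (`v = c = 0`, `AU = 0.5`), which the tests verify. In
bootstrap replicates a resampled column can become constant under
correlation distance; the replicate treats it as uncorrelated (distance 1)
rather than aborting, while the top-level clustering of the observed matrix
treats a constant column as a hard error.

Defaults (distance, linkage, scales, `n_boot = 1000`, row-wise resampling)
follow common multiscale-bootstrap practice for feature-resampled trees.

## Physico-chemical consensus clusters

Discriminative n-grams are mapped back to their source windows; each window
is encoded by four binary properties per aligned position — hydrophobic
`{A,C,F,I,L,M,V}`, negative `{D,E}`, positive `{K,R,H}`, proline `{P}` —
with truncated positions and `X` masked. The property table is a deliberate,
overridable default (`read_property_table()`): different binary
classification schemes exist and users can substitute their own. Per n-gram
and property, the position-wise mean over its windows gives a 21-vector in
`[0, 1]`; the four vectors are concatenated to an 84-vector, with positions
masked in every source window imputed by the property's global mean so all
profiles have equal length.

Each property block is partitioned by k-means (`k = 10`, Lloyd's algorithm
via `stats::kmeans`, k-means++ seeding implemented in the package, best of
10 starts). The four hard partitions are reconciled by a *soft
least-squares Euclidean consensus*: minimize `sum_b ||M - M_b P_b||^2` over
a soft membership matrix `M` (rows on the simplex) and per-input label
permutations `P_b`, alternating optimal label matching (Hungarian
assignment, O(k^3), verified against brute-force enumeration) with
averaging of the matched memberships. Both steps are exact conditional
minimizers, so the objective is non-increasing; one start per input
partition is run and the best kept. The hardened labels (row argmax) define
the consensus clusters, and the per-species cluster distribution is computed
over the signature n-grams *present* in each species, so paired species can
be compared across all clusters.

The spec question of whether to consense the four per-property partitions or
cluster the concatenated profiles directly was decided for the former: it
keeps each property's own structure visible (the per-property partitions are
returned too) and matches the stated consensus construction.

## Logo matrices

For a species, the top n-grams are the signature entries with ratio score at
least a cutoff; infinite-flagged scores always qualify. Cutoffs are
species-specific by nature (species differ in their maximal ratios), so the
default is the 95th percentile of the species' finite ratio scores, and any
explicit value can be passed. The union of the top n-grams' source windows
is aligned on the central serine and summarized as a 21 x 20 position
frequency matrix plus per-position information content
`ic_p = log2(20) - (H_p + 19 / (2 ln(2) n_p))` in bits, clamped to
`[0, log2 20]`, with the small-sample correction switchable off. Output is
numeric (TSV); graphical rendering is left to external logo tools, for which
the contributing windows can be exported as FASTA-ready sequences.

## The synthetic-data generator

`generate_study()` emulates the real study design so every stage has a known
ground truth: 5 training species from 5 kingdoms/phyla with 2 datasets each,
5 paired test species with one dataset each, 500 windows per dataset.
Windows are drawn i.i.d. from a uniform residue background with the central
serine forced; with probability 0.3 one kingdom motif is stamped, anchored
with its single serine on the center. The default motifs follow the
qualitative kingdom characteristics of serine phosphosites — animal motifs
basic with arginine flanks (`KRRRSFRRK`, `RQRRSARKR`), plant motifs
C-terminally acidic (`GSDDEEDED`), fungal motifs C-terminally proline-rich
(`TASPPLPPP`) — plus a glycine-rich filler (`AGYGSGGYG`) for the fifth
group. The patterns are contiguous 9-mers on purpose: only determined
(wildcard-free) stretches of at least 6 residues produce n-grams that recur
across windows, so a wildcard-heavy pattern would plant no recoverable
n-gram at all. Wildcards (`x`) are supported in user-supplied patterns.

What the generator does **not** emulate: species-specific residue
composition (uniform background isolates the motif signal; a composition
table can be supplied), dataset-size imbalance, correlated phosphosites
within proteins, missed-cleavage or detection biases of mass spectrometry,
and kinase-motif degeneracy. Passing the end-to-end tests therefore shows
that the pipeline recovers planted, exactly recurring patterns under clean
conditions — it does not certify performance on real data, where
discriminative frequencies are weaker and backgrounds are structured.

## Numerical choices and degenerate inputs

* Zero-denominator ratios are flagged infinite and sort above all finite
  scores; no arbitrary cap is introduced.
* Selection uses strict inequality (`score > T`); a score exactly at the
  threshold is excluded.
* A species with zero total count is a hard error at training; a projected
  species with none of the signature n-grams yields an all-zero column plus
  a warning (it can still be clustered, and the SVM warns about the
  degenerate assignment).
* `offset` inference for window tables without an explicit offset column is
  `min(site - 1, 10)`, exact for terminal truncation; an explicit column
  always wins.
* All randomness (generator, bootstrap, k-means seeding) flows from
  explicit integer seeds; no global state is relied upon.

## Problem sizes

The test suite runs the full default study (15 datasets x 500 windows,
~10^6 n-gram instances, ~6 x 10^5 distinct n-grams, bootstrap with
`n_boot = 1000`) in well under two minutes on a single core; unit tests use
purpose-built toy studies with vocabularies small enough that expected
values are hand-computable. These sizes are the package's own test design
choices; the functions themselves take arbitrary sizes.

## Limitations

* The signature presence filter is binary (`count > 0` in the paired test
  species); no abundance requirement is imposed.
* No per-n-gram significance testing or multiple-testing control is
  performed — the signature is a descriptive, validated feature set, not a
  set of hypothesis tests.
* More than 30 species in one dendrogram are unsupported (edge bookkeeping
  uses bitmasks).
* Ratio-mode selection with the permissive default threshold relies on the
  test-presence filter for specificity; users with controlled vocabularies
  should consider difference mode and a threshold on the frequency scale.
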