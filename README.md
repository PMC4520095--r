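# phosphosig

Discriminative n-gram signatures for comparative phosphoproteomics.

Serine phosphorylation is catalogued at scale for many eukaryotes, but the
classical motif finders (motif-x, MMFPh) assign each phosphopeptide to one
motif and behave poorly on datasets of very different sizes, which makes
cross-species comparison unreliable. `phosphosig` instead treats every
contiguous substring (n-gram, 6–21 residues) of every serine-centered
21-mer phosphopeptide window as a feature and asks which n-grams
discriminate species — and, after validation against an independent paired
species of the same kingdom/phylum, which of them form a kingdom/phylum
*phosphoproteome signature*.

## The method

For `N` training species (two replicate datasets each), per-dataset n-gram
counts are summed into enriched counts and normalized per species
(`relfreq` columns sum to 1). An IDF-style dampening weight

    w(g) = log2(N / s(g)) + 1

(`s(g)` = number of species containing n-gram `g`) boosts n-grams confined
to few species; the dampened normalized frequency is `relfreq × w(g)`. With
`f1 ≥ f2 ≥ f3` the three largest values of an n-gram across species, the
discriminative ratio

    f1 / ((f2 + f3) / 2)

(infinite when `f2 = f3 = 0`; a difference mode `f1 − (f2 + f3)/2` is also
available) scores how strongly the top species dominates. N-grams above the
threshold enter the signature only if they are also observed in the test
species paired with the top species — the filter that separates
kingdom-specific biology from species-private noise. The signature is then
a fixed model: any species is projected onto its vocabulary with the frozen
weights, classified against the training species by a one-vs-one SVM with
the normalized polynomial kernel `K(x,y)/sqrt(K(x,x)K(y,y))`,
`K(x,y) = (x·y+1)^2`, and clustered hierarchically with multiscale
bootstrap support (BP, and AU from the probit fit
`qnorm(1−BP_r) = v√r + c/√r`, `AU = 1 − Φ(v−c)`). Discriminative n-grams
are further grouped by binary physico-chemical profiles (per-property
k-means, k = 10, reconciled by a soft least-squares Euclidean consensus
partition) and summarized as sequence-logo matrices (position frequencies
and information content in bits, small-sample corrected).

A seeded synthetic-data module generates multi-species studies with planted
kingdom motifs (animal: basic/arginine flanks; plant: C-terminal acidic;
fungi: C-terminal prolines) so the whole pipeline is testable against a
known ground truth. See the vignette
(`vignettes/discriminative-ngram-signatures.Rmd`) for the full model,
parameter meanings and design rationale.

## Worked example

```r
library(phosphosig)

study <- generate_study(simulation_config(seed = 1))   # 15 datasets x 500 windows
res   <- run_signature_pipeline(study$windows, study$design)
res$signature
#> phospho_signature: 5757 n-grams | mode = ratio T = 0.05 | n in [6,21]
#>   Arthropoda       1167
#>   Ascomycota       1171
#>   Chordata         1142
#>   Oomycota         1146
#>   Plantae          1131
```

5757 n-grams discriminate one training species and recur in its paired
test species, spread evenly over the five kingdoms/phyla. The paired test
species classify perfectly against the training species:

```r
cls <- train_and_classify(res$proj_train,
                          project_frequencies(res$signature, res$test_tables),
                          design = study$design)
cls
#> classification_result (accuracy 1.000)
#>             H.sapiens D.melanogaster A.thaliana S.cerevisiae P.infestans
#> M.musculus          1              0          0            0           0
#> A.mellifera         0              1          0            0           0
#> O.sativa            0              0          1            0           0
#> S.pombe             0              0          0            1           0
#> P.ramorum           0              0          0            0           1
```

and the unsupervised dendrogram puts each train/test pair together with
full bootstrap support:

```r
bd <- multiscale_bootstrap(res$proj_all, n_boot = 1000, seed = 1)
edge_support(bd, c("O.sativa", "A.thaliana"))
#> bp au
#>  1  1
```

The top discriminative n-grams of the plant training species yield a logo
whose C-terminal side is acidic — the planted plant motif:

```r
lg <- species_logo(res$signature, "A.thaliana",
                   res$train_tables[["A.thaliana"]], study$windows)
lg
#> logo_matrix: 293 sequences, 21 positions, max ic 4.28 bits
round(lg$pfm[12:15, c("D", "E", "S")], 2)
#>    D E S
#> 12 1 0 0
#> 13 1 0 0
#> 14 0 1 0
#> 15 0 1 0
```

Positions 12–15 (C-terminal to the central serine at position 11) are
dominated by aspartate/glutamate, exactly the planted acidic stretch.

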