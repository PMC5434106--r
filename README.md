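# hcbprimer

Tools for asking a practical question in marine microbiology: **will a
given universal bacterial 16S rRNA gene primer pair actually detect the
obligate hydrocarbon-degrading bacteria (HCB)** — genera such as
*Alcanivorax*, *Cycloclasticus*, *Marinobacter*, *Oleispira* and
*Thalassospira* that bloom after oil spills — and will the resulting
amplicons be classified to the right genus?

The package implements the full in-silico evaluation chain:

1. **Curation** — dereplication, greedy centroid OTU clustering at 97%
   identity (representative = most abundant unique sequence),
   template-based alignment with fixed coordinates, and removal of
   alignment columns that are gaps in ≥ 90% of sequences.
2. **Phylogenetic validation** — Jukes–Cantor distances with pairwise
   deletion, neighbor-joining trees with bootstrap support, and a
   type-strain-anchored monophyly rule that decides which sequences enter
   each validated genus set.
3. **Primer evaluation** — IUPAC-aware perfect-match scanning of
   degenerate primer pairs, amplicon extraction (both binding regions
   included, shortest valid span wins), per-taxon coverage
   `coverage = n_matched / n_targets`, amplicon size classes (small
   100–400 bp, medium >400–<1000 bp, large ≥1000 bp), a ≥95%
   coverage-for-every-taxon filter, and 10%-bin coverage histograms.
4. **Classification testing** — a word-based naive Bayesian genus
   classifier (8-mers, presence/absence, prior `(n(w)+0.5)/(N+1)`,
   conditional `(m_g(w)+prior)/(M_g+1)`) with bootstrap confidence
   (⌊W/8⌋ words per replicate, 100 replicates), evaluated on amplicons
   from held-out sequences.

Because the reference databases behind such analyses are external
resources, the package ships a **synthetic 16S-like sequence generator**
with controlled within-/between-genus divergence, engineered
primer-binding sites with per-genus perfect-match fractions, and a truth
table — so every stage is testable with known answers. See the methods
vignette (`vignettes/primer-evaluation-methods.Rmd`) for the model and
design decisions.

## Worked example

```r
library(hcbprimer)

gen <- generate_reference_set(synth_config(n_genera = 4, seqs_per_genus = 6,
                                           seq_length = 1200, seed = 11))
cfg <- pipeline_config(tree_boot_reps = 20, nbc_boot_reps = 50, seed = 11)
bundle <- run_pipeline(gen$refs, default_primer_pairs(), gen$truth$template,
                       outgroup_genus = "Genus04", config = cfg)
writeLines(bundle$log)
#> seed: 11
#> input sequences: 24
#> dereplicated: 24
#> otus: 24
#> alignment: 24 rows x 1200 columns
#> post-filter unique rows: 24
#> validated taxa: 3 (Genus01=6, Genus02=6, Genus03=6)
#> pairs passing 95% coverage: 2
#> recommended pair: Bact0343_0908
#> amplicons classified: 9

report <- make_report(bundle)
report$ranked_pairs
#>         pair_id size_class mean_coverage min_coverage passes
#> 1 Bact0343_0908     medium             1            1   TRUE
#> 2 Custom343_908     medium             1            1   TRUE
#> 3 Bact0515_0930     medium             0            0  FALSE

report$classification
#>     genus n accuracy conf_fraction
#> 1 Genus01 3        1             1
#> 2 Genus02 3        1             1
#> 3 Genus03 3        1             1
```

Reading the output: 24 generated sequences from four genera (the fourth
serves as the rooting outgroup) pass curation and tree building; all
three target genera come back monophyletic around their type strains, so
each validated taxon holds its full truth membership. Of the three primer
pairs in the default panel, the two whose binding motifs are engineered
into the sequences reach coverage 1.0 for every taxon and pass the 95%
filter; the pair with absent motifs covers nothing. The recommended pair
is the medium-amplicon survivor with the highest mean coverage — the
343F/908R-style pair whose nomenclature-derived span is 583 bp. Its
amplicons, extracted from held-out sequences and classified against a
model trained on full-length sequences, are all assigned to the correct
genus with bootstrap confidence ≥ 0.80.

Single operations are exported too:

```r
parse_primer_name("S-D-Bact-0343-a-S-15")   # position 343, sense, 15 nt
nominal_amplicon_length(343, 908, 18)        # 583
find_sites("TACGGRAGGCAGCAG", some_sequence) # perfect-match 5' positions
pairwise_identity("ACGT", "ACGA")            # 0.75
```

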