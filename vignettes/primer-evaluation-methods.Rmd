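---
title: "Evaluating universal 16S rRNA gene primer pairs for hydrocarbon-degrading bacteria: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating universal 16S rRNA gene primer pairs for hydrocarbon-degrading bacteria: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcbprimer)
```

## The problem

Obligate hydrocarbonoclastic bacteria (HCB) — genera such as
*Alcanivorax*, *Cycloclasticus*, *Marinobacter*, *Oleispira* or
*Thalassospira* — dominate marine microbial communities after oil spills,
and amplicon sequencing surveys are the main tool used to detect them.
Whether a survey sees them at all depends on two things this package
quantifies:

1. **Primer coverage** — does a given universal bacterial 16S rRNA gene
   primer pair perfectly match the rRNA genes of these taxa, and
2. **Classifiability** — once the targeted region is amplified, can a
   standard naive Bayesian taxonomy classifier place the amplicon in the
   correct genus?

The workflow has four stages: curation of a genus-validated reference set,
phylogenetic validation of genus labels, perfect-match primer-pair
evaluation, and classification testing of extracted amplicons. Because the
reference databases behind the original analysis are large external
resources, the package ships a synthetic-sequence generator with a known
truth table so that every stage can be exercised and verified end to end.

## Curation

**Dereplication** collapses identical sequences, summing their
abundances; output order is descending abundance with lexicographic id
tie-breaks, which fixes the processing order of everything downstream.

**Pairwise identity.** The literature rarely states the identity metric
behind "97% identity" clustering. This package defines it explicitly:
global (end-gap penalized) affine alignment with match +1, mismatch −1,
gap open −2 and gap extension −1 per position; identity is the fraction of
matching columns among alignment columns, excluding terminal-gap columns.
The aligner is a banded dynamic program written in C; with the default
band it is exact for any pair similar enough to matter near the 0.97
threshold, and callers can request the full (unbanded) alignment. Ties
among co-optimal alignments are resolved deterministically
(diagonal first, then gap in the query, then gap in the reference).

**OTU clustering** is greedy centroid clustering: records are processed in
the fixed dereplication order; each record joins the first centroid at
identity ≥ the threshold (0.97 default) or founds a new OTU. The centroid
is therefore always the most abundant unique sequence of its OTU and
serves as its representative. A `assign = "best"` dialect joins the
highest-identity centroid instead; both are deterministic. An 8-mer
shared-word prescreen skips alignments for pairs that could not possibly
reach the threshold (pairs near 97% identity share the large majority of
their 8-mers; the prescreen cutoff of 40% corresponds to identities far
below 0.93, where the clustering decision is never in doubt).

**Template alignment.** To obtain fixed coordinates for column filtering,
each sequence is aligned to a single reference template and projected onto
the template's columns; bases inserted relative to the template are
discarded and counted per record. A record aligning over less than half
its length is dropped with a warning. This mirrors fixed-column
(NAST-style) alignment used by standard rRNA pipelines, which is exactly
what makes a downstream "remove columns that are ≥ 90% gaps" step
well-defined.

**Gap-column filtering** removes alignment columns whose gap fraction is
at least the threshold (0.90 default) — "at least", so the boundary column
with exactly 90% gaps is removed. Identical rows that emerge after
filtering are dereplicated again before tree building.

## Phylogeny

Distances use pairwise deletion (columns with a gap or ambiguous base in
either row are skipped for that pair) and default to the Jukes–Cantor
correction −(3/4)·ln(1 − 4p/3), consistent with the generator's uniform
substitution model; p-distances are available. A pair with p ≥ 0.75 under
correction, or with no comparable columns, is an error naming the pair.

Trees are built by neighbor joining (Saitou–Nei Q-criterion). Two details
are pinned down for determinism where the literature is silent: ties in Q
break toward the smallest (i, j) index pair, and a negative estimated
branch length is clamped to zero with the deficit moved to its sister
branch, preserving the joined pair's path length. On additive matrices the
implementation recovers the generating topology and branch lengths to
numerical precision, which the test suite verifies against randomly
generated trees.

Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per replicate, and reports for each internal edge the percentage
of replicates containing the same bipartition. The package default is 100
replicates — enough to separate strong from weak edges at desk scale —
with the replicate count a parameter for users who want the conventional
1,000.

**Monophyly validation.** The genus-assignment rule is: root the tree on
the designated outgroup, take the smallest clade containing all
type-strain anchors together with every leaf labeled with that genus, and
call the genus monophyletic iff no leaf of a *different* genus sits inside
that clade. Leaves with no genus label do not break monophyly — clade
membership is precisely how environmental sequences get their genus call.
When the genus is monophyletic the whole clade is selected into the
validated set; otherwise only the anchors are kept, the conservative
fallback used for poorly supported groups.

## Primer-pair evaluation

A primer position matches a target base iff the target base belongs to
the IUPAC set of the primer's code; ambiguity codes in the *target* never
satisfy a perfect match. This is deliberately conservative — an N in a
reference sequence is unknown, not a wildcard — and matches the
perfect-match convention of in-silico coverage tools. Antisense primers
are scanned as their IUPAC-aware reverse complement against the sense
strand, so all coordinates refer to the sense strand.

An amplicon pairs a forward site strictly upstream of a reverse binding
site and includes **both** primer-binding regions; among candidate site
pairs within the span guards (50–3000 bp by default), the shortest span
wins, mimicking the preferential amplification of shorter products, with
ties broken by the smaller forward position. Coverage of a (pair, taxon)
cell is the fraction of the taxon's sequences yielding an amplicon; pairs
with coverage ≥ 95% for *every* target taxon pass the high-coverage
filter and are re-scored against the full reference set.

Primer names following the standardized nomenclature
(`S-D-Bact-<pos>-<variant>-<S|A>-<len>`) provide a nominal position and
length; the nominal amplicon span is the inclusive distance from the
forward primer's start to the reverse primer's 3'-terminal position. For
the recommended pair S-D-Bact-0343-a-S-15 / S-D-Bact-0908-a-A-18 this is
(908 + 18 − 1) − 343 + 1 = 583 bp. Size classes follow the published
grouping: small 100–400 bp, medium >400–<1000 bp, large >1000 bp. The
interval notation leaves exactly 1000 bp unassigned; this package places
it in the large class. Pairs with free-form names get their class from
the median realized amplicon length across matched targets. Coverage
histograms use 10-percent bins, half-open with a closed top bin, so a
pair at exactly 10% falls in [10, 20) and a pair at 100% in [90, 100].

## Naive Bayesian classification

The classifier is the word-presence naive Bayes scheme standard in rRNA
taxonomy. Words are the distinct 8-mers of a sequence (presence/absence,
not counts). With n(w) of N training sequences containing word w, the
prior is (n(w) + 0.5)/(N + 1); within genus g holding M_g sequences of
which m_g(w) contain w, the conditional probability is
(m_g(w) + prior(w))/(M_g + 1). A query is assigned the genus maximizing
the summed log conditionals of its words, ties broken lexicographically.
Bootstrap confidence draws ⌊W/8⌋ of the query's W words (with
replacement, minimum one) per replicate and reports the fraction of 100
replicates agreeing with the full-word call. Word size 8, the one-eighth
subsample and 100 replicates are the cited defaults of this classifier
family. Per-query RNG streams derive from the run seed and the query id,
so batch results do not depend on evaluation order.

Classification testing trains on full-length sequences and evaluates on
amplicons extracted from *held-out* sequences (the training and
evaluation sets are disjoint at the sequence level; amplicons are
dereplicated before classification). The report gives, per genus, the
fraction classified correctly and the fraction of correct calls with
confidence ≥ 0.80.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes: a
uniform-random root sequence; genus ancestors derived from it by
substitutions at the between-genus rate; tips derived from their ancestor
at the within-genus rate plus short (1–3 nt) indels; conserved
primer-binding motifs written into the root at fixed coordinates, with
degenerate positions instantiated to a recorded concrete base. Primer
sites are shielded from background mutation and indels, so a site's match
status is controlled solely by the engineered per-genus perfect fraction:
exactly round(fraction × n) tips keep a perfect site, and each designated
broken site receives exactly one substitution to a base incompatible with
the motif — the minimal perturbation that defeats a perfect match. The
truth table records every genus label, site status and post-indel site
coordinate, and generation is a pure function of the configuration
including its seed.

Default conditions are 5 genera × 40 sequences of 1500 nt,
between-genus divergence 0.15 and within-genus divergence 0.02
substitutions per site, indel rate 0.005 per site, one type strain per
genus, and two engineered sites: a V3 forward motif at position 343 and
the sense-strand binding motif of a V5 reverse primer at position 908 —
the same region targeted by the recommended pair, whose engineered
amplicon is the 583-bp medium-class span. Under the uniform substitution
model the expected within-genus identity is (1−w)² + w²/3 ≈ 0.961 and the
closed form (verified against a Monte-Carlo site oracle in the tests)
extends to the between-genus case via the transition-matrix product of
the two branches.

What the generator does **not** emulate: rRNA secondary-structure
conservation and covariation, chimeras, amplification and sequencing
error, realistic rate heterogeneity across sites, and taxonomy that
disagrees with phylogeny. Passing tests on synthetic data therefore show
that the algorithms are correct and internally consistent under the
stated model — not that any particular coverage number will be attained
on a real reference database.

## Numerical and design choices

- Substitutions draw uniformly from the three alternative bases, matching
  the Jukes–Cantor distance correction used downstream.
- All alignment scores are small integers, so DP tracebacks compare
  exactly; NJ tie-breaks and the clamping rule make tree topologies a
  deterministic function of the distance matrix.
- Within-genus divergence 0.02 puts typical within-genus identity
  (~0.96) *below* the 0.97 clustering threshold, so default runs produce
  several OTUs per genus; monophyly validation then reunites them. This
  deliberately exercises the OTU → clade → taxon-set path rather than
  making clustering trivially congruent with the genera.
- The held-out split for classification testing takes alternating members
  of each validated taxon, and any evaluation sequence whose full-length
  string also occurs in training is excluded.
- Pipeline problem sizes in the package's tests are the default study
  conditions (200 sequences) for the classification benchmark and
  determinism checks, and smaller configurations (tens of sequences)
  where only wiring is under test.

## Known limitations

- The identity metric and greedy order are *a* deterministic
  concretization of common centroid-clustering behavior, not a
  reimplementation of any specific tool's internals; near-threshold
  cluster boundaries can differ from other implementations.
- Maximum-likelihood tree inference is out of scope; neighbor joining
  with bootstrap is used throughout.
- Chimera detection is not implemented; the pipeline assumes a
  pre-filtered input set.
- Coverage semantics are pair-amplicon based: a sequence counts as
  covered only if a valid amplicon forms, not if the two primers merely
  match somewhere.
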