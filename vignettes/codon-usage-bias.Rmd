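---
title: "Codon usage bias in plastid genomes: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias in plastid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcub)
```

## What the package computes

Synonymous codons are not used equally: mutation pressure (largely visible
as compositional drift at the third codon position) and translational
selection together shape per-gene codon usage. For plastid genomes the
standard analysis runs: extract a filtered coding-sequence (CDS) set from
the annotated circular genome; compute per-gene statistics — positional GC
content, relative synonymous codon usage (RSCU), observed and expected
effective number of codons (ENC), the codon adaptation index (CAI), and
parity-rule-2 (PR2) coordinates; read off the balance of mutation and
selection from four diagnostics (ENC-plot, ENC-ratio distribution, PR2
quadrants, neutrality regression); and finally call *optimal codons* by
contrasting RSCU between high- and low-expression gene libraries. `cpcub`
implements the full chain plus the quadripartite (LSC/SSC/IR) partition of
the plastome itself, and ships seeded simulators so every stage is
testable without downloads.

## Statistics and estimators

**RSCU.** For codon $j$ in a synonymous family of size $n$,
$\mathrm{RSCU}_j = x_j / (\frac{1}{n}\sum_k x_k)$. Families are amino
acids, with the three stop codons treated as one family; Leu, Ser and Arg
are single six-codon families. A family with zero total yields RSCU 0 for
all its codons and an `absent` flag, so downstream $\Delta$RSCU
arithmetic stays total while absent families can never be called optimal.

**Observed ENC.** The Wright-style estimator: per family with $n \ge 2$
codons counted, $\hat F = (n\sum \hat p^2 - 1)/(n-1)$; class means
$\bar F_2, \bar F_3, \bar F_4, \bar F_6$ over usable families
($\hat F > 0$); $ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 +
3/\bar F_6$, capped at 61. When the three-fold class (Ile) is unusable we
impute $\bar F_3 = (\bar F_2 + \bar F_4)/2$; an unusable six-fold class
takes $\bar F_6 = \bar F_4$. With no usable two-fold or four-fold family
the gene's ENC is undefined: the gene is flagged, kept in the table, and
excluded from species means and library construction. A gene using one
codon per amino acid scores exactly 20; uniform usage saturates at 61.

**Expected ENC and the ENC plot.** Under pure mutation pressure,
$ENC_{exp} = 2 + GC3 + 29/(GC3^2 + (1-GC3)^2)$. The abscissa of the ENC
plot is the *synonymous* third-position GC (`gc3s`): third positions of
Met, Trp and stop codons carry no synonymous signal, and including them
(they are fixed or nearly so) shifts the curve by 2–3 ENC units at
plastid-like GC3 — enough to invert the diagnostic. The metrics table
therefore carries both `gc3` (whole-sequence convention, used for
Table-style GC reporting, stop codon included by default with a flag to
drop it) and `gc3s` (used for `enc_exp` and the ENC plot). The ENC ratio
is $(ENC_{exp} - ENC_{obs})/ENC_{exp}$; values in $[-0.05, 0.05]$ mark
genes whose usage is explained by composition alone.

The closed form is itself an approximation: its per-class homozygosity
terms are not exact for the three-fold family or for the mixed third-base
structure of six-fold families. Genes simulated under exact mutation
pressure converge to roughly 0.7–0.9 ENC units *above* the curve at GC3
around 0.3. This is a property of the formula, not a bug; tests assert
distances against it with that headroom in mind.

**CAI.** Geometric mean of relative-adaptiveness weights
$w_j = \mathrm{RSCU}_j / \max_{k \in \mathrm{family}} \mathrm{RSCU}_k$
over counted codons, excluding stops and single-codon families. The
published analyses this package mirrors do not state their reference set,
so absolute CAI values are not comparable across tools; the default
reference here is the pooled counts of the strongest-bias (lowest-ENC)
10% of genes of the same species, and any external weight table can be
supplied. Codons unobserved in the reference have undefined weight and
are excluded from scoring rather than given an arbitrary floor.

**PR2.** Strand-symmetry coordinates
$x = G_3/(G_3+C_3)$, $y = A_3/(A_3+T_3)$ computed from third positions of
the five strictly four-fold families (Val, Pro, Thr, Ala, Gly). The
four-fold *subsets* of six-fold families are excluded — their first two
positions differ, so pooling them mixes amino-acid composition into a
parity statistic. Points exactly on a centre line are assigned to the
lowest adjacent quadrant index, a deterministic reporting convention;
analyses that need symmetry (for example uniformity tests) should drop
exact-0.5 coordinates first, since short genes with even third-base
totals land on the boundary with non-trivial probability.

**Neutrality regression.** Ordinary least squares of GC12 on GC3 across
genes, both as fractions. Slope near 1 means the first two codon
positions track the third (mutation dominance); slope near 0 means
selection holds protein-coding positions in place while the third
position drifts.

**Correlations.** Pearson $r$ with raw two-sided $p$ for all pairs among
GC1, GC2, GC3, ENC and CAI, starred at 0.05/0.01 without multiplicity
correction — matching the display convention of the correlation figures
this reproduces.

## Optimal codons

Genes with defined ENC are sorted ascending; the lowest-ENC 10% (strong
bias, conventionally the high-expression proxy) and the highest-ENC 10%
form the two libraries, each of size $\max(1, \lfloor 0.10 n \rfloor)$,
ties broken by gene name. $\Delta\mathrm{RSCU} =
\mathrm{RSCU}_{high} - \mathrm{RSCU}_{low}$ per codon; a codon is
*high-expression* when $\Delta \ge 0.08$ (inclusive), *high-frequency*
when whole-set RSCU $> 1$, and *optimal* when both hold. Thresholds are
applied at full precision by default; a table-reproduction mode rounds
both quantities to 2 decimals first so that decisions recomputed from a
published 2-decimal table match it exactly. Shared optimal codons across
species are the plain set intersection, reported with the third-base
(A/U vs G/C) ending composition.

Two caveats are deliberate. First, with ~50-gene plastid CDS sets the
libraries hold only ~5 genes each, and the sampling standard deviation of
RSCU in an unbiased family is of the same order as the 0.08 threshold —
single-species optimal-codon lists therefore carry a few noise
admissions, which is why per-species counts are unstable while the
cross-species intersection is reproducible. The package's recovery tests
use the same logic: three simulated replicate species are intersected,
which removes sampling noise while retaining every planted codon. Second,
the whole-set RSCU (not the high-library RSCU) feeds the RSCU $> 1$ test,
matching the layout of published per-codon tables.

## Quadripartite structure detection

The inverted-repeat pair is found by exact k-mer seeding ($k = 25$)
between the genome and its reverse complement, grouping seed hits by
diagonal, and extending the best runs maximally base-by-base (a mismatch
budget, default 0, is exposed; plastid IRs are near-identical so the
default is exact matching). Because a repeat can span the sequence
origin, circular genomes are scanned twice — as given and rotated by half
the genome length — and the longer pair wins; a repeat cannot span the
origin in both scans unless it exceeds half the genome. Equally-maximal
pairs tie-break to the smallest start coordinate. The longer single-copy
gap is labelled LSC, the shorter SSC; per-region GC is
$(G+C)/(A+C+G+T)$ with N excluded from the denominator. If no repeat
reaches `min_ir_len` (default 1000 bp, floor 100), the result is a
`NULL`-with-message "no structure" signal, distinct from an error.
Hyper-repetitive seeds (a k-mer occurring more than 8 times) are dropped
before pairing, so genomes that are almost entirely low-complexity
repeats are outside the detector's scope.

## CDS extraction filters

Each CDS feature is spliced per its (possibly multi-interval,
origin-wrapping, minus-strand) location. Retained sequences must have
length a multiple of 3 and $\ge 300$ nt, start ATG, end TAA/TAG/TGA, and
contain no internal stop. Codons containing N are dropped *before* the
length test; a CDS losing more than 5% of its codons is discarded so that
ambiguity cannot bias the statistics. Genes duplicated by the inverted
repeat are deduplicated on (name, sequence); same-name different-sequence
annotations are kept with suffixed names to avoid double-weighting pooled
counts. Coordinates are 0-based half-open internally and 1-based
inclusive in every report. Reports carry the source record's accession
id, never an assumed species name.

## The simulators, and what passing tests do not show

`simulate_cds_set()` emits genes that pass the extraction filters by
construction. In the mutation regime, synonymous codons are weighted so
each family's third-position GC equals the per-gene target GC3 exactly
(GC mass split over G/C-ending codons, AT mass over the rest); genes then
scatter around the expected-ENC curve. In the selection regime the base
distribution is uniform and is mixed with a point mass on a planted
preferred-codon set with per-gene weight $s_i = s \cdot e_i$,
$e_i \sim U(0,1)$ an expression level — this decouples ENC from GC3 and
creates exactly the high/low-expression contrast the optimal-codon
pipeline is built to detect. The mixed regime layers the point mass on
the GC3-weighted base. One root seed deterministically derives per-gene
child seeds (recorded in the returned ground truth), so identical
specifications are byte-identical.

The generator draws amino acids i.i.d. from a fixed plausible plastid
profile. It does not model amino-acid covariation along proteins, codon
pair effects, intron structure, GC skew between strands, or evolution
along a phylogeny; genomes from `simulate_quadripartite_genome()` have
exactly identical IR copies and junction bases adjusted to block chance
repeat extension. Tests passing on this synthetic material demonstrate
estimator and pipeline correctness under the stated models — not that
real plastomes satisfy those models.

Test and acceptance problem sizes are chosen to make the statistical
assertions well-powered while staying quick: 200 genes of 200–500 codons
for curve-tracking checks, 60-gene species in triplicate for
planted-codon recovery, 10 seeds × 100 genes for regime separation, and
15 kb planted genomes (scaling to 70 kb in the GC check) for structure
round-trips.

## Known limitations

* GenBank parsing covers the LOCUS/FEATURES/ORIGIN subset needed for
  plastome records (join/complement locations, gene/locus_tag/pseudo
  qualifiers); exotic location operators (`one-of`, remote references)
  are not supported.
* The IR detector reports a single maximal pair; plastomes with genuinely
  degenerate multiple IR pairs of identical length are resolved by the
  smallest-start tie-break, not enumerated.
* CAI values depend entirely on the reference set; compare CAI only
  within one reference choice.
* With mismatch budgets $> 0$ the detector extends greedily and does not
  chain split seed runs across long mismatch gaps.
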