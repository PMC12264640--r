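# cpcub — codon usage bias analysis for chloroplast genomes

`cpcub` is an R package for researchers in plant molecular evolution who
need a reproducible, tested pipeline for synonymous codon-usage analysis
of plastid (chloroplast) genomes: from an annotated circular genome to
the quadripartite structure table, the per-gene codon statistics, the
four standard bias diagnostics, and the optimal-codon call.

## What it computes

* **Quadripartite partition** — the maximal pair of inverted repeats
  (IRa/IRb) on the circular genome via exact k-mer seeding and maximal
  extension; the longer single-copy gap is LSC, the shorter SSC; per-
  region lengths and GC%.
* **Filtered CDS set** — strand-aware splicing of (possibly
  origin-wrapping, multi-exon) CDS features; filters: length ≥ 300 nt and
  ≡ 0 mod 3, ATG start, TAA/TAG/TGA stop, no internal stop, N-containing
  codons dropped, IR duplicates collapsed.
* **Per-gene statistics** — positional GC (GC1, GC2, GC3, GC12 =
  (GC1+GC2)/2), synonymous GC3s, RSCU
  (x_ij / mean of its family), observed ENC (Wright-style estimator:
  ENC = 2 + 9/F̄2 + 1/F̄3 + 5/F̄4 + 3/F̄6, range 20–61), expected ENC
  (ENCexp = 2 + GC3s + 29/[GC3s² + (1−GC3s)²]), ENC ratio
  ((ENCexp − ENCobs)/ENCexp), CAI (geometric mean of relative
  adaptiveness w = RSCU/RSCUmax), and PR2 coordinates
  (x = G3/(G3+C3), y = A3/(A3+T3) over strictly fourfold families).
* **Diagnostics** — Pearson correlation matrix of {GC1, GC2, GC3, ENC,
  CAI}; neutrality regression of GC12 on GC3; ENC-ratio histogram with
  the [−0.05, 0.05] central band; PR2 quadrant summary; plots for each.
* **Optimal codons** — high/low-expression libraries from the 10% ENC
  tails; ΔRSCU = RSCU(high) − RSCU(low); a codon is *optimal* when
  ΔRSCU ≥ 0.08 and whole-set RSCU > 1; cross-species shared sets by
  intersection, with A/U vs G/C ending composition.
* **Simulators** — seeded generators for CDS sets under mutation,
  selection, or mixed regimes (controllable GC3, planted preferred
  codons, per-gene selection strength) and for circular genomes with a
  planted LSC + IRa + SSC + IRb architecture, plus lossless
  FASTA/GenBank/TSV fixture writers.

## Worked example

```r
library(cpcub)

rec <- simulate_quadripartite_genome(lsc_len = 80000, ssc_len = 12000,
                                     ir_len = 20000,
                                     n_cds = c(lsc = 30, ssc = 6, ir = 4),
                                     seed = 42)
detect_quadripartite(rec)
#> <quadripartite> total 132000 bp | LSC 80000 bp (GC 37.35%) |
#>   SSC 12000 bp (GC 34.35%) | IR 20000 bp (GC 44.74%)

cds <- extract_cds(rec)          # 40 genes (IR copies deduplicated)
tab <- gene_metrics_table(cds)
round(attr(tab, "summary"), 3)
#>    gc1    gc2    gc3    enc    cai
#>  0.492  0.387  0.389 55.400  0.644

neutrality_fit(tab)
#> Neutrality fit (n = 40): GC12 = -0.1135 x GC3 + 0.4837 | R^2 = 0.03577, p = 0.242

h <- enc_ratio_histogram(tab)
c(h$band_count, h$n)             # 19 of 40 genes inside [-0.05, 0.05]
pr2_summary(tab)
#> PR2 quadrant counts: I=8 II=10 III=11 IV=11 | undefined=0 | n=40
```

The recovered partition equals the planted architecture exactly. The
mean ENC of 55.4 (> 45) marks weak overall bias; the near-zero
neutrality slope with R² = 0.036 says GC12 does not track GC3 — expected
here, since the simulated genes draw first/second positions from a fixed
amino-acid profile; about half the genes sit in the ENC-ratio central
band, i.e. their usage is explained by third-position composition.

For optimal codons across several species:

```r
sets <- lapply(1:3, function(k)
  simulate_cds_set(n_genes = 60, regime = "selection", s = 0.9,
                   preferred = to_dna(c("UUA", "GCU", "AAA")),
                   seed = 100 + k, label = paste0("sp", k)))
res <- run_optimal(sets, out_dir = "out")   # TSVs + shared-set JSON
as.character(res$shared)
```

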