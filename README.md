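# codonsel

Are synonymous mutations really neutral? A synonymous change can swap a
codon for a synonym that the cell's tRNA pool decodes faster or slower,
so translation-level selection can act on it even though the protein is
unchanged. `codonsel` is an R package for detecting that weak selection
from population data: it scores codon optimality from tRNA gene-copy
pools, classifies coding variants by the direction of their optimality
change, polarizes sites against two outgroups, and contrasts
fixation/polymorphism patterns and allele-frequency spectra between
mutation classes. It is aimed at molecular evolution and population
genetics work on any organism with a standard nuclear genetic code.

## The model in brief

Each sense codon $i$ gets a tRNA adaptation weight

$$W_i = \sum_j (1 - s_{ij})\,\mathrm{tGCN}_j$$

over its decoders in the pool: the Watson–Crick anticodon ($s = 0$) and
one wobble decoder fixed by the codon's third base, with eukaryotic
penalties $s_{G:U} = 0.7861$, $s_{I:C} = 0.4659$, $s_{I:A} = 0.9075$,
$s_{U:G} = 0.6295$ (I:U is free). Codons are ranked within each
amino-acid family (high/low optimality split: 32 high, 29 low under the
standard code), and every single-base synonymous codon pair is labelled
tAI-up or tAI-down by comparing $W$. A parallel frequency-based score
uses CAI weights $w$ from highly expressed genes (top half by RPKM).

Sites are called **polymorphic** (with a derived allele frequency, DAF)
or **fixed** by comparing the focal species with two agreeing outgroups,
under an allele-frequency band of [0.02, 0.98]; minor allele frequencies
(MAF) are computed without outgroup information. Selection on synonymous
changes then shows up as:

* a higher fixed:polymorphic ratio for tAI-up than tAI-down mutations
  (Fisher exact test on the 2×2 table);
* higher DAF/MAF for tAI-up than tAI-down (Wilcoxon rank-sum tests),
  with nonsense < nonsynonymous < synonymous as the sanity ordering;
* patterns that strengthen in highly expressed and high-GC genes,
  survive restriction to GC-conservative (A↔T, C↔G) changes — the
  control for GC-biased gene conversion — and show no nearest-neighbour
  clustering, plus a multiple regression of frequency on ΔCAI, ΔtAI and
  gene GC.

A seeded synthetic-data generator (`simulate_dataset()`) produces the
whole input stack — CDS FASTA, GtRNAdb-style tRNA pool, expression
table, aligned focal+outgroup triples, allele-frequency table — with
known ground truth, so the complete pipeline is testable end to end.

## Worked example

```r
library(codonsel)

## codon optimality from the bundled synthetic maize-like tRNA pool
pool <- synthetic_maize_pool()        # 52 anticodons, 1198 loci
tai  <- build_tai_table(pool)
head(tai[order(-tai$W), ], 5)
#>    codon aa       W rank class
#> 6    ACC  T 42.7502    1  high
#> 14   ATC  I 42.7502    1  high
#> 22   CCC  P 42.7502    1  high
#> 30   CTC  L 42.7502    1  high
#> 38   GCC  A 42.7502    1  high

## the classic 2x2: class counts in, ratios and Fisher p out
fixed_polymorphic_contrast(255236, 2220, 181820, 2645)
#>       fixed polymorphic
#> up   255236        2220
#> down 181820        2645
#> fixed:polymorphic ratios: up 115.0, down 68.7
#> odds ratio 1.673, Fisher two-sided p = 7.33e-71

## end-to-end on synthetic data with known ground truth
run <- run_pipeline(simulate_dataset(sim_config(seed = 1)))
run
#> codonsel pipeline run
#>   genes: 40  sites walked: 32463
#>   polymorphic: 990  fixed: 1350  excluded: 30123
#>   fixed:polymorphic ratio up 2.0 vs down 1.3 (p = 0.000116)
#>   median DAF: syn-up 0.541, syn-down 0.250
#>   site conservation: ok
```

The first block says C-ending codons top their families in this pool
(G/C-ending codons are the optima). The 2×2 block shows the fixation
excess of optimality-increasing synonymous mutations: they fixed 115
times per segregating site versus 68.7 for optimality-decreasing ones,
an association far beyond chance. The pipeline block shows the same
signature recovered from a fully synthetic dataset in which it was
planted: a higher up-class ratio and a higher up-class median DAF, with
every walked site accounted for (site conservation).

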