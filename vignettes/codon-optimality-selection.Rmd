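---
title: "Detecting weak selection on synonymous codon changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting weak selection on synonymous codon changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonsel)
```

## The question and the model

Synonymous mutations leave the protein untouched, but they exchange one
codon for another that the tRNA pool may decode faster or slower. If
decoding speed matters, mutations that move a codon towards a
better-supplied codon ("tAI-up") should behave differently in a population
from mutations that move it away ("tAI-down"): they should fix more often
relative to how often they segregate, and the ones still segregating
should sit at higher frequencies. `codonsel` implements that entire chain
of inference.

### Codon decoding capacity: tAI

The supply side is a tRNA pool: gene copy numbers (tGCN) per anticodon,
the standard genomic proxy for tRNA abundance. Each sense codon $i$ is
scored by an absolute weight

$$W_i = \sum_{j \in \text{decoders}(i)} (1 - s_{ij})\, \mathrm{tGCN}_j,$$

where the sum runs over the anticodons in the pool that can read the
codon: the Watson–Crick partner (the reverse complement of the codon) and
at most one wobble decoder determined by the codon's third base. The
penalties $s_{ij}$ discount non-canonical pairings; Watson–Crick and I:U
pairings cost nothing. The defaults are the eukaryote-calibrated
constants

| pairing (anticodon 34 : codon 3) | $s$ |
|---|---|
| G : U | 0.7861 |
| I : C | 0.4659 |
| I : A | 0.9075 |
| U : G | 0.6295 |

Inosine at anticodon position 34 is genomically encoded as A, so a single
A34 anticodon serves codons ending U (as I:U, free), C (I:C) and A (I:A).
Note the asymmetry of the two G·U geometries: the same chemical wobble is
penalized differently depending on which side contributes the G.

Because the downstream classification only ever compares codons *within*
one amino-acid family, the raw $W$ is used throughout. The conventional
normalization (divide by the maximum, replace zeros by the geometric
mean) is monotone within families, so it cannot change any
classification; `tai_normalize()` provides it as a reporting transform
only.

### Optimality classes and directed codon pairs

Within each amino-acid family, codons are ranked by $W$ (ties broken
alphabetically, a deterministic and documented rule). Families are split
half/half into high and low optimality codons; odd family sizes round
towards high (so Ile is 2 high / 1 low, and the single-codon families Met
and Trp are high). Under the standard code this split is a combinatorial
fact independent of the pool: 32 high and 29 low codons, always.

`enumerate_directed_pairs()` lists every ordered pair of sense codons
that encode the same amino acid and differ at one position — the complete
set of single-base synonymous mutations — and assigns each the direction
of its $W$ change. Exhaustive enumeration over the standard code yields
67 unordered (134 ordered) such pairs; a handful are ties under any given
pool and are excluded from the up/down sets. Published counts of
"tAI-changing pairs" in this literature sometimes differ (87 has been
reported); since the counting convention behind such numbers (ordered
vs unordered, with or without ties) is rarely stated, the package reports
its own enumeration and does not force agreement.

### Codon frequency optimality: CAI weights

The demand-side companion score is usage-based: over a reference set of
highly expressed genes, each sense codon gets
$w = \text{count} / \max(\text{count among its synonyms})$. Gene-level
CAI is the geometric mean of the $w$ of its codons. Expression is
measured by RPKM and "highly expressed" defaults to the top half of genes
by RPKM — the threshold is not canonical, so it is a parameter
(`top_fraction`). Codons from families never observed in the reference
set have missing (not zero) weights; codons with $w = 0$ are skipped in
the CAI geometric mean (with the skip count reported) rather than
collapsing the whole gene to zero.

### Polarization against two outgroups

To call a segregating allele ancestral or derived, each focal CDS site is
compared with the orthologous bases of two outgroup species in a
codon-aware three-way alignment. A site is usable only when the two
outgroups agree, neither is a gap or N, and neither outgroup site is
itself polymorphic. At a usable site:

* two retained alleles, one matching the shared outgroup base →
  **polymorphic**; ancestral = outgroup base, DAF = frequency of the
  other allele;
* one retained allele differing from the outgroup base → **fixed**;
* everything else → **excluded**, with a machine-readable reason
  (`outgroup_mismatch`, `outgroup_gap`, `outgroup_polymorphic`,
  `multiallelic`, `ancestral_not_segregating`, `invariant`).

Allele retention uses the frequency band [0.02, 0.98], the usual guard
against sequencing error in frequency estimates from read data. Both
bounds are inclusive — "between 0.02 and 0.98" is ambiguous, so the
choice is pinned by boundary unit tests. After dropping sub-band noise
alleles the two retained frequencies are renormalized to sum to one
(whether to renormalize is another genuinely open choice; renormalizing
keeps DAF + ancestral frequency = 1 exactly). Sites with more than two
band-passing alleles are excluded from DAF analyses but still yield a MAF
under the second-most-abundant-allele rule.

Fixed differences are called from the reference alignment alone at sites
without focal polymorphism data. With incomplete polymorphism discovery
this overestimates the absolute fixed:polymorphic ratios — only the
*comparison between classes* is interpretable, which is how every result
downstream is framed.

The MAF analysis deliberately ignores outgroups: every band-passing
bi-allelic site contributes its second-most-abundant allele frequency,
classified from the focal reference codon. This recovers the sites lost
to outgroup disagreement at the cost of not knowing the mutation's
direction in time.

### The evidential contrasts

* **Fixed:polymorphic 2×2** (up vs down × fixed vs polymorphic), with
  per-class ratios, the sample odds ratio, and a two-sided Fisher exact
  test. The Fisher p comes from `stats::fisher.test`; a test-side
  hypergeometric enumeration oracle pins its agreement on all small
  tables.
* **Spectrum comparisons** of DAF and MAF between classes (nonsense,
  nonsynonymous, synonymous up/down) with two-sided Wilcoxon rank-sum
  tests. Small samples take an exact path that enumerates all
  assignments of the observed (midranked) ranks to the two groups —
  written here because the standard exact algorithm abandons ties — and
  larger samples use the normal approximation with tie correction. The
  switch point is an enumeration budget (`choose(n1+n2, n1) <= 2e5`),
  i.e. roughly twenty observations combined.
* **Stratified contrasts** by expression or GC (top fraction vs rest),
  with the difference of median gaps, median(up) − median(down), as the
  effect-size contrast between strata.
* **GC-conservative subsets**: restricting to A↔T and C↔G changes
  removes any contribution of GC-biased gene conversion, which cannot
  distinguish alleles of equal GC content.
* **Nearest-neighbour classes**: each classified synonymous site is
  labelled by its own direction and its nearest neighbour's (ties broken
  towards the upstream site). If allele frequencies were set by local
  genomic processes (recombination-associated transmission bias), "up
  near up" and "up near down" spectra would differ; under per-site
  selection they should not.
* **Multiple regression** of DAF or MAF on ΔCAI, ΔtAI and gene GC
  (ordinary least squares over complete cases), separating the codon
  optimality signals from the GC composition of the host gene.

All tests are two-sided; no multiple-testing correction is applied by
default (a Benjamini–Hochberg flag exists in `spectrum_compare`), both
choices matching how results of this kind are conventionally reported.

## The synthetic-data generator

Real inputs to this analysis are expensive (RNA-seq read mapping, variant
calls, ortholog triples), so the package carries a generator that
emulates the entire input stack under known ground truth. Its defaults
*are* the validation conditions used by the test suite:

* 40 genes of 150–400 codons with per-gene GC targets in [0.35, 0.65]
  (CDSs sampled from an iid base model conditioned on sense codons:
  valid start, no internal stop);
* the bundled synthetic maize-like tRNA pool (52 anticodons, 1198 loci,
  inosine anticodons for nine families — constructed to match the
  published summary of a real grass pool, with synthetic copy numbers
  that make G/C-ending codons the within-family optima; it is labelled
  synthetic and is not the real complement);
* log-normal read counts; the top half by RPKM is the high-expression
  stratum;
* per-class DAF models: Beta(3,3) for syn-up, Beta(2,4) for syn-down
  (means 0.5 vs 1/3), Beta(1.5,5) for nonsynonymous and Beta(1,8) for
  nonsense — the deleterious classes pushed towards low frequencies, the
  ordering the selection hypothesis predicts; draws are resampled into
  the open frequency band;
* planted counts per class: 300/300/350/40 polymorphic and 600/400/350/0
  fixed (up/down/nonsynonymous/nonsense), i.e. a fixation excess in the
  up class; fixed nonsense defaults to zero because a fixed internal
  stop would invalidate the focal CDS;
* a stratum interaction multiplier (1.5) that widens the up/down Beta
  gap in high-expression genes;
* outgroup lineage divergence 0.03/site plus planted disagreement, gap
  and outgroup-polymorphism sites at low rates, all at positions
  disjoint from planted mutations.

Synonymous mutations are planted from the directed-pair table, so their
up/down labels are exact by construction, and the pipeline's round-trip
recovery of class, direction, status and DAF can be asserted at 100%.
Each divergence site mutates in exactly one outgroup lineage, so
divergence always shows up as an outgroup-mismatch exclusion and never
fabricates a spurious fixed call — a deliberate simplification that keeps
ground-truth reconciliation exact.

The DAF model is a Beta family rather than a population-genetic
(Wright–Fisher or coalescent) simulation. The claims under test are rank
and ratio statements about frequency spectra, which Beta shifts emulate
at desk scale; the generator therefore does *not* reproduce linkage,
demography, a realistic mutation spectrum, GC-biased transmission, or
site-frequency-spectrum shapes under drift. Passing the validation suite
shows the pipeline's bookkeeping and statistics are correct, not that any
particular genome is under selection.

## Numerical choices and degenerate inputs

* Ranks break ties alphabetically; pair direction ties are labelled
  `tie` and excluded from up/down sets (antisymmetry is property-tested).
* CDSs whose length is not a multiple of 3, or with internal stops, are
  skipped with a warning during usage counting; variants in codons
  containing ambiguous bases are rejected; variants in the terminal stop
  codon are excluded with a warning.
* A frequency vector summing to more than 1 (beyond 1e-6) is an error,
  not a silent renormalization.
* Zero polymorphic counts make a fixed:polymorphic ratio undefined
  (flagged, not infinite); constant or aliased regression predictors are
  flagged with a warning and reported as such.
* Replicate-based stochastic assertions (OLS 2-SE coverage, type-I error
  of the neutral configuration) are asserted with the binomial sampling
  tolerance implied by their replicate counts, fixed a priori: nominal
  2-SE coverage is 95.45%, so a hard "≥ 95% of 100" would fail a correct
  implementation about a third of the time.

## Problem sizes

The validation suite runs the full pipeline on the default 40-gene
dataset (~2,300 planted mutations, ~33,000 walked sites, seconds), the
oracle comparisons on exhaustive small-table/small-sample grids plus
10,000 random variants, and the replicate studies at 100 seeds × 2,000
draws per class (power), 1,000 seeds (type-I error) and 100 × 5,000
(regression recovery). These sizes were chosen so the complete suite
runs in about two and a half minutes on one CPU while leaving every
stochastic assertion comfortably powered.

## Known limitations

* tAI here uses gene copy number as the abundance proxy and the four
  stated wobble rules only; no species-specific modification chemistry
  (e.g. Ile AUA decoding by modified wobble bases) is modelled beyond
  them.
* The package consumes allele-count tables and aligned triples; read
  mapping, variant calling, ortholog inference and alignment are
  upstream tools' jobs, as is RNA secondary-structure prediction — a
  per-gene "structured fraction" column is accepted as an optional
  precomputed input for the correlation analyses.
* Fixed-site calls inherit the reference alignment's errors; only
  between-class comparisons of ratios are meaningful.
* MAF-based classification orients mutations from the focal reference
  allele, which is not an ancestral-state inference.
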