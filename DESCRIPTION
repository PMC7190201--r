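Package: codonsel
Title: Selection on Synonymous Codon Usage from tRNA Pools and Allele
    Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify weak selection on synonymous mutations in
    protein-coding genes. Builds per-codon tRNA adaptation index (tAI)
    weights from anticodon gene-copy pools with wobble penalties, derives
    codon adaptation index (CAI) weights from highly expressed genes,
    classifies single-base coding variants and the direction of their tAI
    and CAI change, polarizes sites against two outgroups to obtain derived
    allele frequencies, and contrasts fixed-to-polymorphic ratios and
    DAF/MAF spectra between mutation classes with Fisher and Wilcoxon
    tests, stratified analyses, GC-conservative (gene-conversion) controls,
    nearest-neighbour clustering checks and multiple regression. Includes a
    seeded synthetic-data generator that emulates the full input stack for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
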