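# shared toy fixtures, built in code at test time

toy_pool <- function() trna_pool(c(AGC = 2, GGC = 3))

maize_pool <- function() synthetic_maize_pool()

# a small config that keeps unit-test pipelines fast
small_config <- function(seed = 11L) {
  sim_config(seed = seed, n_genes = 10L,
             gene_length_codons = c(120L, 250L),
             n_poly = c(syn_up = 60L, syn_down = 60L,
                        nonsynonymous = 70L, nonsense = 10L),
             n_fixed = c(syn_up = 120L, syn_down = 80L,
                         nonsynonymous = 70L, nonsense = 0L))
}

# random pool over a random subset of possible anticodons
random_pool <- function(seed, n_anticodons = 45) {
  set.seed(seed)
  poss <- unique(vapply(sense_codons(), function(cd)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cd))),
    character(1)))
  acs <- sample(poss, n_anticodons)
  trna_pool(stats::setNames(sample(1:40, n_anticodons, replace = TRUE), acs))
}

# random valid CDS (start codon, sense body, one stop), length in codons
random_test_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  body <- sample(sense_codons(), n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}
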