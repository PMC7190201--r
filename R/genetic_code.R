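#' The standard nuclear genetic code
#'
#' Returns the standard genetic code as a named character vector mapping each
#' of the 64 codons (DNA alphabet, e.g. \code{"GCT"}) to a one-letter amino
#' acid symbol, with \code{"*"} for the three stop codons.
#'
#' @return Named character vector of length 64.
#' @examples
#' code <- standard_genetic_code()
#' code["ATG"]          # "M"
#' sum(code == "*")     # 3 stop codons
#' @export
standard_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  stopifnot(length(code) == 64L, sum(code == "*") == 3L)
  code
}

#' Sense codons of a genetic code
#'
#' @param code genetic code as returned by [standard_genetic_code()].
#' @return Character vector of the 61 sense codons (standard code).
#' @export
sense_codons <- function(code = standard_genetic_code()) {
  names(code)[code != "*"]
}

## reverse complement of codon/anticodon strings, DNA alphabet
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## normalize a nucleotide string to upper-case DNA alphabet (U -> T)
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

is_sense_codon <- function(codon, code = standard_genetic_code()) {
  codon %in% names(code) & code[codon] != "*"
}
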