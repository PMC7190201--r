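#' Construct a tRNA pool
#'
#' A tRNA pool maps anticodons (3-letter DNA strings, 5'->3', so the first
#' letter is position 34, the base that pairs with the codon's third
#' position) to tRNA gene copy numbers (tGCN). Gene copy number is the usual
#' genomic proxy for tRNA abundance.
#'
#' @param copies named non-negative integer vector, names are anticodons.
#'   RNA-alphabet names (with U) are normalized to DNA (T).
#' @param n_undetermined number of tRNA gene records whose anticodon could
#'   not be determined (e.g. "NNN"); carried as an attribute, not counted in
#'   the pool.
#' @return An object of class \code{trna_pool}: a named integer vector with
#'   attributes \code{n_undetermined} and \code{n_skipped}.
#' @examples
#' trna_pool(c(AGC = 2, GGC = 3))
#' @export
trna_pool <- function(copies = integer(0), n_undetermined = 0L) {
  if (length(copies)) {
    if (is.null(names(copies)) || any(!nzchar(names(copies))))
      stop("'copies' must be a named vector of anticodon counts")
    names(copies) <- normalize_dna(names(copies))
    if (any(nchar(names(copies)) != 3L) ||
        any(!grepl("^[ACGT]{3}$", names(copies))))
      stop("anticodons must be 3-letter strings over {A,C,G,T}")
    if (anyDuplicated(names(copies))) {
      copies <- tapply(copies, names(copies), sum)
      copies <- copies[order(names(copies))]
    }
    if (any(copies < 0)) stop("tGCN values must be non-negative")
  }
  pool <- as.integer(round(copies))
  names(pool) <- if (length(copies)) names(copies) else character(0)
  if (length(pool)) pool <- pool[order(names(pool))]
  structure(pool,
            n_undetermined = as.integer(n_undetermined),
            n_skipped = 0L,
            class = "trna_pool")
}

#' @export
print.trna_pool <- function(x, ...) {
  cat("tRNA pool:", length(x), "anticodons,", sum(x), "loci\n")
  if (attr(x, "n_undetermined") > 0L)
    cat("  (", attr(x, "n_undetermined"),
        "records with undetermined anticodon excluded )\n")
  print(unclass(structure(as.integer(x), names = names(x))))
  invisible(x)
}

#' Total tRNA loci in a pool
#' @param pool a [trna_pool()].
#' @return Integer, the sum of gene copy numbers.
#' @export
total_loci <- function(pool) sum(unclass(pool))

#' Parse a GtRNAdb-dialect tRNA FASTA into a tRNA pool
#'
#' GtRNAdb sequence headers embed the isotype and anticodon as
#' \code{...tRNA-<Isotype>-<Anticodon>-<locus>-<copy>...}; the anticodon
#' field is parsed from each record header and gene copies are counted per
#' anticodon. Records with an undetermined anticodon (containing N) are
#' tallied separately and excluded from the pool; records whose header
#' carries no recoverable anticodon are skipped with a warning.
#'
#' @param file path to a FASTA file of tRNA gene sequences.
#' @return A [trna_pool()]. Attribute \code{n_skipped} counts malformed
#'   headers.
#' @export
parse_trna_pool <- function(file) {
  seqs <- Biostrings::readBStringSet(file)
  if (length(seqs) == 0L) return(trna_pool())
  headers <- names(seqs)
  m <- regmatches(headers,
                  regexpr("tRNA-[A-Za-z]{1,4}-[ACGTUNacgtun]{3}", headers))
  found <- lengths(regmatches(headers,
            gregexpr("tRNA-[A-Za-z]{1,4}-[ACGTUNacgtun]{3}", headers))) > 0L
  n_skipped <- sum(!found)
  if (n_skipped > 0L)
    warning(n_skipped, " tRNA record(s) without a recoverable anticodon ",
            "were skipped")
  anticodons <- normalize_dna(sub("^tRNA-[A-Za-z]{1,4}-", "", m))
  undet <- grepl("N", anticodons)
  counts <- table(anticodons[!undet])
  pool <- trna_pool(stats::setNames(as.integer(counts), names(counts)),
                    n_undetermined = sum(undet))
  attr(pool, "n_skipped") <- as.integer(n_skipped)
  pool
}

#' Read a tRNA pool from a two-column TSV
#'
#' Plain-text alternative to the FASTA route: a header-less or headered TSV
#' with columns \code{anticodon} and \code{copies}.
#'
#' @param file path to the TSV.
#' @return A [trna_pool()].
#' @export
read_trna_pool_tsv <- function(file) {
  first <- readLines(file, n = 1L)
  header <- grepl("anticodon", first, ignore.case = TRUE)
  tab <- utils::read.delim(file, header = header,
                           col.names = c("anticodon", "copies"),
                           stringsAsFactors = FALSE)
  trna_pool(stats::setNames(tab$copies, tab$anticodon))
}

#' Write a tRNA pool as a GtRNAdb-dialect FASTA
#'
#' Emits one FASTA record per tRNA gene copy with a GtRNAdb-style header
#' (\code{<species>_tRNA-<Isotype>-<Anticodon>-<n>-1}). Sequences are
#' synthetic placeholder tRNA bodies carrying the anticodon at positions
#' 34-36; only the headers matter to [parse_trna_pool()]. Used by the
#' synthetic-data generator and test fixtures.
#'
#' @param pool a [trna_pool()].
#' @param file output path.
#' @param species species tag used as the header prefix.
#' @param code genetic code, used to derive the isotype from the anticodon.
#' @return Invisibly, the number of records written.
#' @export
write_gtrnadb_fasta <- function(pool, file, species = "Synthetica",
                                code = standard_genetic_code()) {
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
           Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
           L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
           S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
           `*` = "Sup")
  lines <- character(0)
  body5 <- paste(rep("GCGGAUUUAGCUCAGUUGGGAGAGCGCCAGACU", 1), collapse = "")
  body3 <- "AAUUCCCGGGUCGGCGGUUCGAUCCCGCCAAUCCGCCA"
  for (ac in names(pool)) {
    n <- unclass(pool)[[ac]]
    if (n <= 0L) next
    iso <- aa3[[code[[revcomp(ac)]]]]
    ac_rna <- chartr("T", "U", ac)
    seq <- paste0(substr(body5, 1, 33), ac_rna, body3)
    for (i in seq_len(n)) {
      lines <- c(lines,
                 sprintf(">%s_tRNA-%s-%s-%d-1 (synthetic) %d bp",
                         species, iso, ac, i, nchar(seq)),
                 seq)
    }
  }
  writeLines(lines, file)
  invisible(length(lines) %/% 2L)
}

#' The bundled synthetic maize-like tRNA pool
#'
#' A synthetic stand-in for a grass tRNA gene complement, constructed to
#' match the published summary of the maize pool: 52 distinct anticodons,
#' 1198 tRNA loci, inosine (A34) anticodons present for nine amino-acid
#' families, and a realized wobble census of 15 G:U, 13 U:G, 9 I:C and 9 I:A
#' anticodon:codon pairs. Copy numbers are synthetic and chosen so that
#' G/C-ending codons are generally the within-family optima, as reported for
#' maize. It is \emph{not} the real GtRNAdb complement.
#'
#' @return A [trna_pool()].
#' @export
synthetic_maize_pool <- function() {
  file <- system.file("extdata", "synthetic_maize_trna_pool.tsv",
                      package = "codonsel", mustWork = TRUE)
  read_trna_pool_tsv(file)
}
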