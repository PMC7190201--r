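#' Reads per kilobase per million mapped reads
#'
#' @param read_count mapped reads for the gene (vectorized).
#' @param cds_length_bp CDS length in base pairs, > 0.
#' @param total_mapped_reads library size, > 0.
#' @return RPKM = read_count / (cds_length_bp/1000) / (total_mapped_reads/1e6).
#' @export
compute_rpkm <- function(read_count, cds_length_bp, total_mapped_reads) {
  if (any(cds_length_bp <= 0)) stop("cds_length_bp must be positive")
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be positive")
  read_count / (cds_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Split genes into high- and low-expression sets
#'
#' Genes are sorted by RPKM descending, ties broken by gene id, and the top
#' \code{fraction} (by count, rounded up) forms the high set.
#'
#' @param genes data.frame with at least \code{gene_id} and \code{rpkm}.
#' @param fraction fraction in (0, 1) assigned to the high set; default 0.5.
#' @return list with data.frames \code{high} and \code{low}.
#' @export
select_high_expression <- function(genes, fraction = 0.5) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "rpkm") %in% names(genes)))
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  if (nrow(genes) == 0L)
    return(list(high = genes, low = genes))
  ord <- order(-genes$rpkm, genes$gene_id)
  n_high <- ceiling(nrow(genes) * fraction)
  list(high = genes[ord[seq_len(n_high)], , drop = FALSE],
       low  = genes[ord[-seq_len(n_high)], , drop = FALSE])
}

## split a CDS into codons, dropping a terminal stop codon if present.
## Returns NULL (with a warning) for CDSs that fail validation.
cds_codons <- function(seq, code = standard_genetic_code(), id = "<cds>",
                       warn = TRUE) {
  seq <- normalize_dna(seq)
  if (nchar(seq) %% 3 != 0) {
    if (warn) warning("CDS '", id, "' length not divisible by 3; skipped")
    return(NULL)
  }
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  n <- length(codons)
  if (n > 0 && codons[n] %in% names(code) && code[codons[n]] == "*")
    codons <- codons[-n]
  known <- codons %in% names(code)
  if (any(known & code[codons] == "*")) {
    if (warn) warning("CDS '", id, "' contains an internal stop; skipped")
    return(NULL)
  }
  codons
}

#' Codon usage table (w weights) from a gene set
#'
#' Accumulates codon counts over all genes (terminal stop codons and codons
#' containing ambiguous bases excluded; genes failing validation are skipped
#' with a warning) and computes, per sense codon, the frequency weight
#' \eqn{w = \mathrm{count} / \max(\mathrm{count})} within its synonymous
#' family. When computed over highly expressed genes these are the CAI
#' weights. An unobserved codon in an observed family has \eqn{w = 0}; a
#' family with no observations at all has \code{w = NA} (missing, not
#' zero).
#'
#' @param cds named character vector (or \code{DNAStringSet}) of CDS
#'   sequences.
#' @param code genetic code.
#' @return data.frame of class \code{codon_usage_table} with columns
#'   \code{codon}, \code{aa}, \code{count}, \code{w}.
#' @export
build_usage_table <- function(cds, code = standard_genetic_code()) {
  if (inherits(cds, "DNAStringSet")) cds <- as.character(cds)
  counts <- stats::setNames(integer(length(sense_codons(code))),
                            sense_codons(code))
  ids <- if (is.null(names(cds))) as.character(seq_along(cds)) else names(cds)
  for (i in seq_along(cds)) {
    codons <- cds_codons(cds[[i]], code, ids[i])
    if (is.null(codons)) next
    codons <- codons[grepl("^[ACGT]{3}$", codons)]
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  out <- data.frame(codon = names(counts), aa = unname(code[names(counts)]),
                    count = unname(counts), stringsAsFactors = FALSE)
  fam_max <- stats::ave(out$count, out$aa, FUN = max)
  out$w <- ifelse(fam_max > 0, out$count / fam_max, NA_real_)
  class(out) <- c("codon_usage_table", "data.frame")
  out
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of the usage weights w over the gene's sense codons.
#' Codons with missing or zero w are skipped (their count is reported via
#' the \code{n_skipped} attribute) rather than zeroing the whole gene.
#'
#' @param seq CDS sequence (character scalar).
#' @param usage a [build_usage_table()] result.
#' @param code genetic code.
#' @return CAI in (0, 1] with attributes \code{n_codons} (scored) and
#'   \code{n_skipped}. Errors if no codon is scorable.
#' @export
gene_cai <- function(seq, usage, code = standard_genetic_code()) {
  codons <- cds_codons(seq, code, warn = FALSE)
  if (is.null(codons)) stop("invalid CDS (length or internal stop)")
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  w <- usage$w[match(codons, usage$codon)]
  ok <- !is.na(w) & w > 0
  if (!any(ok)) stop("gene has no scorable codons")
  structure(exp(mean(log(w[ok]))),
            n_codons = sum(ok), n_skipped = sum(!ok))
}

#' GC content metrics of a CDS
#'
#' @param seq CDS sequence (character scalar), non-empty.
#' @return Named numeric: \code{GC} (fraction of G/C over all positions)
#'   and \code{GC3} (fraction of G/C at third codon positions).
#' @export
gc_metrics <- function(seq) {
  seq <- normalize_dna(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  gc <- mean(chars %in% c("G", "C"))
  third <- chars[seq(3, length(chars), 3)]
  gc3 <- if (length(third)) mean(third %in% c("G", "C")) else NA_real_
  c(GC = gc, GC3 = gc3)
}
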