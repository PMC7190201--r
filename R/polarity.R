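#' Allele-frequency band filter
#'
#' Keeps alleles with frequency inside the closed band \[low, high\]. An
#' allele above \code{high} makes the site monomorphic for that allele
#' (everything else is treated as sequencing noise); alleles below
#' \code{low} are dropped. A site is polymorphic iff at least two alleles
#' survive. Bounds are inclusive on both sides.
#'
#' @param freqs named numeric vector of allele frequencies in \[0, 1\],
#'   summing to at most 1 (small tolerance).
#' @param low,high band bounds; defaults 0.02 and 0.98.
#' @return Named numeric vector of retained allele frequencies (1 element
#'   for a monomorphic call).
#' @export
frequency_band_filter <- function(freqs, low = 0.02, high = 0.98) {
  stopifnot(!is.null(names(freqs)))
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  if (sum(freqs) > 1 + 1e-6) stop("allele frequencies sum to more than 1")
  freqs <- freqs[freqs > 0]
  if (any(freqs > high)) return(freqs[which.max(freqs)])
  freqs[freqs >= low]
}

#' Minor allele frequency
#'
#' Frequency of the second most abundant allele at a site, computed without
#' outgroup information. For bi-allelic sites frequencies are renormalized
#' to sum to one first, so the MAF never exceeds 0.5; for sites with more
#' than two alleles the raw frequency of the second most abundant allele is
#' returned.
#'
#' @param freqs named numeric vector with at least two positive entries.
#' @return MAF in (0, 0.5\] for bi-allelic sites.
#' @export
minor_allele_frequency <- function(freqs) {
  freqs <- freqs[freqs > 0]
  if (length(freqs) < 2L)
    stop("MAF undefined: site is monomorphic")
  if (length(freqs) == 2L) freqs <- freqs / sum(freqs)
  sort(freqs, decreasing = TRUE)[[2]]
}

.site_record <- function(status, reason = NA_character_,
                         ancestral = NA_character_,
                         derived = NA_character_,
                         daf = NA_real_, maf = NA_real_) {
  data.frame(status = status, reason = reason, ancestral = ancestral,
             derived = derived, daf = daf, maf = maf,
             stringsAsFactors = FALSE)
}

#' Polarize one CDS site against two outgroups
#'
#' Implements the two-outgroup criteria: a site is usable only if the two
#' outgroup bases agree, are not gaps or Ns, and neither outgroup site is
#' itself polymorphic. A usable site segregating two band-passing alleles,
#' one of which equals the shared outgroup base, is \emph{polymorphic}:
#' ancestral = outgroup base, derived = the other allele, DAF = derived
#' frequency after renormalizing the two retained alleles. A usable
#' monomorphic site whose base differs from the shared outgroup base is
#' \emph{fixed}. Everything else is excluded with a machine-readable
#' reason (\code{outgroup_gap}, \code{outgroup_mismatch},
#' \code{outgroup_polymorphic}, \code{no_retained_allele},
#' \code{multiallelic}, \code{ancestral_not_segregating},
#' \code{invariant}).
#'
#' @param freqs named numeric vector of focal allele frequencies. A
#'   monomorphic site can be given as a single frequency-1 allele.
#' @param out1,out2 outgroup bases in \{A,C,G,T,-,N\}.
#' @param out1_poly,out2_poly logical flags: the orthologous outgroup site
#'   is polymorphic in its own species.
#' @param band numeric length 2, the [frequency_band_filter()] bounds.
#' @return One-row data.frame: \code{status} (polymorphic | fixed |
#'   excluded), \code{reason}, \code{ancestral}, \code{derived}, \code{daf},
#'   \code{maf}.
#' @export
polarize_site <- function(freqs, out1, out2, out1_poly = FALSE,
                          out2_poly = FALSE, band = c(0.02, 0.98)) {
  out1 <- normalize_dna(out1); out2 <- normalize_dna(out2)
  stopifnot(out1 %in% c("A", "C", "G", "T", "-", "N"),
            out2 %in% c("A", "C", "G", "T", "-", "N"))
  if (out1 %in% c("-", "N") || out2 %in% c("-", "N"))
    return(.site_record("excluded", "outgroup_gap"))
  if (out1 != out2)
    return(.site_record("excluded", "outgroup_mismatch"))
  if (isTRUE(out1_poly) || isTRUE(out2_poly))
    return(.site_record("excluded", "outgroup_polymorphic"))
  retained <- frequency_band_filter(freqs, band[1], band[2])
  if (length(retained) == 0L)
    return(.site_record("excluded", "no_retained_allele"))
  if (length(retained) == 1L) {
    base <- names(retained)
    if (base == out1) return(.site_record("excluded", "invariant"))
    return(.site_record("fixed", ancestral = out1, derived = base))
  }
  if (length(retained) > 2L)
    return(.site_record("excluded", "multiallelic"))
  if (!out1 %in% names(retained))
    return(.site_record("excluded", "ancestral_not_segregating"))
  retained <- retained / sum(retained)
  derived <- setdiff(names(retained), out1)
  .site_record("polymorphic", ancestral = out1, derived = derived,
               daf = unname(retained[derived]),
               maf = min(retained))
}

#' Read a three-way codon-aware alignment (focal + two outgroups)
#'
#' Reads an aligned multi-FASTA with exactly three records whose ids are
#' tagged \code{focal}, \code{out1} and \code{out2} (as substrings of the
#' record names, in any order).
#'
#' @param file path to the aligned FASTA.
#' @param gene_id gene identifier; defaults to the file name.
#' @return An \code{aligned_triple}: list with \code{gene_id} and aligned
#'   sequences \code{focal}, \code{out1}, \code{out2} of equal length.
#' @export
read_aligned_triple <- function(file, gene_id = NULL) {
  seqs <- Biostrings::readBStringSet(file)
  if (length(seqs) != 3L)
    stop("aligned triple must contain exactly 3 records, found ",
         length(seqs))
  pick <- function(tag) {
    hit <- grep(tag, names(seqs))
    if (length(hit) != 1L)
      stop("alignment ids must tag exactly one record as '", tag, "'")
    as.character(seqs[[hit]])
  }
  aligned_triple(focal = pick("focal"), out1 = pick("out1"),
                 out2 = pick("out2"),
                 gene_id = gene_id %||% sub("\\.[^.]*$", "", basename(file)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an aligned triple
#'
#' @param focal,out1,out2 aligned sequences (equal length, gaps as "-").
#' @param gene_id gene identifier.
#' @return An object of class \code{aligned_triple}.
#' @export
aligned_triple <- function(focal, out1, out2, gene_id = "gene") {
  focal <- normalize_dna(focal); out1 <- normalize_dna(out1)
  out2 <- normalize_dna(out2)
  if (length(unique(nchar(c(focal, out1, out2)))) != 1L)
    stop("aligned sequences must have equal length")
  structure(list(gene_id = gene_id, focal = focal, out1 = out1,
                 out2 = out2),
            class = "aligned_triple")
}

#' Walk an aligned triple and call every focal CDS site
#'
#' Visits each focal CDS position once (gap columns in the focal sequence
#' carry no CDS position and are skipped), looks up the outgroup bases in
#' the same alignment column, and calls the site fixed, polymorphic or
#' excluded via [polarize_site()]. Positions present in the focal variant
#' table use the observed allele frequencies; all other positions are
#' treated as monomorphic for the focal reference base.
#'
#' @param triple an [aligned_triple()].
#' @param variants data.frame of focal polymorphism data with columns
#'   \code{cds_pos}, \code{freq_A}, \code{freq_C}, \code{freq_G},
#'   \code{freq_T} (and optionally \code{gene_id}, filtered to the triple's
#'   gene). May be NULL or empty.
#' @param outgroup_poly_pos integer vector of focal CDS positions whose
#'   orthologous outgroup site is polymorphic (mask).
#' @param band allele-frequency band bounds.
#' @return data.frame with one row per focal CDS position: \code{gene_id},
#'   \code{cds_pos}, \code{aligned_col}, \code{focal}, \code{out1},
#'   \code{out2}, \code{status}, \code{reason}, \code{ancestral},
#'   \code{derived}, \code{daf}, \code{maf}.
#' @export
walk_alignment <- function(triple, variants = NULL,
                           outgroup_poly_pos = integer(0),
                           band = c(0.02, 0.98)) {
  stopifnot(inherits(triple, "aligned_triple"))
  f <- strsplit(triple$focal, "")[[1]]
  o1 <- strsplit(triple$out1, "")[[1]]
  o2 <- strsplit(triple$out2, "")[[1]]
  keep <- f != "-"
  cols <- which(keep)
  n <- length(cols)
  if (!is.null(variants) && nrow(variants)) {
    if ("gene_id" %in% names(variants))
      variants <- variants[variants$gene_id == triple$gene_id, , drop = FALSE]
    if (any(variants$cds_pos < 1 | variants$cds_pos > n))
      stop("variant position outside focal CDS (column-map inconsistency)")
  }
  out <- data.frame(gene_id = triple$gene_id, cds_pos = seq_len(n),
                    aligned_col = cols, focal = f[cols], out1 = o1[cols],
                    out2 = o2[cols], stringsAsFactors = FALSE)
  var_at <- if (!is.null(variants) && nrow(variants))
    match(seq_len(n), variants$cds_pos) else rep(NA_integer_, n)
  poly_mask <- seq_len(n) %in% outgroup_poly_pos

  ## vectorized calls for the (vast majority of) monomorphic positions;
  ## polarize_site() is applied row-wise only where a variant is recorded
  status <- rep("excluded", n)
  reason <- rep(NA_character_, n)
  ancestral <- derived <- rep(NA_character_, n)
  daf <- maf <- rep(NA_real_, n)
  gap <- out$out1 %in% c("-", "N") | out$out2 %in% c("-", "N")
  mism <- !gap & out$out1 != out$out2
  opoly <- !gap & !mism & poly_mask
  focal_bad <- !out$focal %in% c("A", "C", "G", "T")
  usable <- !gap & !mism & !opoly & !focal_bad
  reason[gap] <- "outgroup_gap"
  reason[mism] <- "outgroup_mismatch"
  reason[opoly] <- "outgroup_polymorphic"
  reason[!gap & !mism & !opoly & focal_bad] <- "focal_ambiguous"
  mono <- usable & is.na(var_at)
  inv <- mono & out$focal == out$out1
  fix <- mono & out$focal != out$out1
  reason[inv] <- "invariant"
  status[fix] <- "fixed"; reason[fix] <- NA_character_
  ancestral[fix] <- out$out1[fix]; derived[fix] <- out$focal[fix]

  for (i in which(usable & !is.na(var_at))) {
    v <- variants[var_at[i], ]
    freqs <- c(A = v$freq_A, C = v$freq_C, G = v$freq_G, T = v$freq_T)
    r <- polarize_site(freqs, out$out1[i], out$out2[i], band = band)
    status[i] <- r$status; reason[i] <- r$reason
    ancestral[i] <- r$ancestral; derived[i] <- r$derived
    daf[i] <- r$daf; maf[i] <- r$maf
  }
  cbind(out, data.frame(status = status, reason = reason,
                        ancestral = ancestral, derived = derived,
                        daf = daf, maf = maf, stringsAsFactors = FALSE))
}
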