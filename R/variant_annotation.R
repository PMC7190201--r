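## Core classifier for a single-codon change. Both codons must be 3-letter
## DNA strings differing at exactly one position; ref must be a sense codon.
annotate_codon_change <- function(ref_codon, alt_codon, tai, usage = NULL,
                                  code = standard_genetic_code()) {
  diff <- which(strsplit(ref_codon, "")[[1]] != strsplit(alt_codon, "")[[1]])
  stopifnot(length(diff) == 1L)
  aa_ref <- code[[ref_codon]]
  aa_alt <- code[[alt_codon]]
  if (aa_ref == "*") stop("reference codon is a stop codon")
  cls <- if (aa_alt == "*") "nonsense"
         else if (aa_alt == aa_ref) "synonymous"
         else "nonsynonymous"
  tai_dir <- cai_dir <- "n/a"
  d_tai <- d_cai <- NA_real_
  if (cls == "synonymous") {
    W <- stats::setNames(tai$W, tai$codon)
    d_tai <- W[[alt_codon]] - W[[ref_codon]]
    tai_dir <- if (d_tai > 0) "up" else if (d_tai < 0) "down" else "tie"
    if (!is.null(usage)) {
      w <- stats::setNames(usage$w, usage$codon)
      d_cai <- w[[alt_codon]] - w[[ref_codon]]
      cai_dir <- if (is.na(d_cai)) "missing"
                 else if (d_cai > 0) "up"
                 else if (d_cai < 0) "down" else "tie"
    } else cai_dir <- "missing"
  }
  data.frame(ref_codon = ref_codon, alt_codon = alt_codon,
             codon_change_pos = diff, class = cls,
             tai_direction = tai_dir, cai_direction = cai_dir,
             delta_tai = d_tai, delta_cai = d_cai,
             stringsAsFactors = FALSE)
}

#' Annotate a single-base coding variant
#'
#' Classifies a single-base change in a CDS as synonymous, nonsynonymous or
#' nonsense, and, for synonymous changes, attaches the direction and
#' magnitude of the tAI change (from the codon tAI table) and of the CAI
#' weight change (from the codon usage table). Coordinates are 1-based on
#' the coding strand of the CDS.
#'
#' @param cds CDS sequence (character scalar).
#' @param position 1-based CDS position of the change.
#' @param ref_base,alt_base single bases; \code{cds[position]} must equal
#'   \code{ref_base}.
#' @param tai a [build_tai_table()] result.
#' @param usage optional [build_usage_table()] result.
#' @param gene_id identifier carried through to the output.
#' @param code genetic code.
#' @return One-row data.frame with gene id, coordinates (CDS position,
#'   codon index, position within codon), ref/alt codons, functional class,
#'   tAI/CAI directions and deltas.
#' @export
annotate_variant <- function(cds, position, ref_base, alt_base, tai,
                             usage = NULL, gene_id = NA_character_,
                             code = standard_genetic_code()) {
  cds <- normalize_dna(cds)
  ref_base <- normalize_dna(ref_base); alt_base <- normalize_dna(alt_base)
  if (position < 1 || position > nchar(cds))
    stop("position ", position, " outside CDS of length ", nchar(cds),
         if (!is.na(gene_id)) paste0(" (gene ", gene_id, ")"))
  if (substr(cds, position, position) != ref_base)
    stop("reference mismatch at ", gene_id, ":", position, " (CDS has '",
         substr(cds, position, position), "', variant says '", ref_base, "')")
  if (ref_base == alt_base) stop("ref and alt bases are identical")
  ci <- (position - 1) %/% 3 + 1
  cp <- (position - 1) %% 3 + 1
  ref_codon <- substr(cds, (ci - 1) * 3 + 1, ci * 3)
  if (!grepl("^[ACGT]{3}$", ref_codon))
    stop("codon containing position ", position, " has ambiguous bases")
  if (code[[ref_codon]] == "*") {
    warning("variant at ", gene_id, ":", position,
            " falls in a stop codon; excluded")
    return(NULL)
  }
  alt_codon <- ref_codon
  substr(alt_codon, cp, cp) <- alt_base
  ann <- annotate_codon_change(ref_codon, alt_codon, tai, usage, code)
  cbind(data.frame(gene_id = gene_id, cds_pos = position, codon_index = ci,
                   codon_pos = cp, ref = ref_base, alt = alt_base,
                   stringsAsFactors = FALSE),
        ann[, setdiff(names(ann), "codon_change_pos")])
}

#' Annotate a table of variants against a CDS set
#'
#' Applies [annotate_variant()] row-wise. Rows referencing unknown genes,
#' mismatching the reference, or falling in stop codons are rejected and
#' counted, not fatal.
#'
#' @param variants data.frame with columns \code{gene_id}, \code{cds_pos},
#'   \code{ref}, \code{alt}.
#' @param cds_set named character vector (or \code{DNAStringSet}) of CDSs.
#' @param tai a [build_tai_table()] result.
#' @param usage optional usage table.
#' @param code genetic code.
#' @return list with \code{annotations} (data.frame), \code{tally} (named
#'   integer by class), \code{rejected} (data.frame with a \code{reason}).
#' @export
batch_annotate <- function(variants, cds_set, tai, usage = NULL,
                           code = standard_genetic_code()) {
  if (inherits(cds_set, "DNAStringSet")) cds_set <- as.character(cds_set)
  need <- c("gene_id", "cds_pos", "ref", "alt")
  stopifnot(all(need %in% names(variants)))
  anns <- vector("list", nrow(variants))
  rej <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$gene_id %in% names(cds_set)) {
      rej[[i]] <- cbind(v[need], reason = "unknown_gene")
      next
    }
    res <- tryCatch(
      withCallingHandlers(
        annotate_variant(cds_set[[v$gene_id]], v$cds_pos, v$ref, v$alt,
                         tai, usage, gene_id = v$gene_id, code = code),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rej[[i]] <- cbind(v[need], reason = res)
    } else if (is.null(res)) {
      rej[[i]] <- cbind(v[need], reason = "stop_codon_site")
    } else anns[[i]] <- res
  }
  annotations <- do.call(rbind, anns[!vapply(anns, is.null, logical(1))])
  rejected <- do.call(rbind, rej[!vapply(rej, is.null, logical(1))])
  classes <- c("synonymous", "nonsynonymous", "nonsense")
  tally <- stats::setNames(integer(3), classes)
  if (!is.null(annotations)) {
    t0 <- table(factor(annotations$class, levels = classes))
    tally[] <- as.integer(t0)
  } else {
    annotations <- data.frame()
  }
  if (is.null(rejected)) rejected <- data.frame()
  list(annotations = annotations, tally = tally, rejected = rejected)
}
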