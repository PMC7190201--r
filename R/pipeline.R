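#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory holding \code{cds.fa}, \code{trna_pool.tsv} (or
#'   \code{trna.fa}), \code{expression.tsv}, \code{variants.tsv},
#'   \code{outgroup_poly.tsv} and \code{triples/}.
#' @return list of class \code{codonsel_dataset} (without ground truth
#'   unless \code{truth.tsv} is present).
#' @export
read_dataset <- function(dir) {
  fa <- Biostrings::readBStringSet(file.path(dir, "cds.fa"))
  cds <- stats::setNames(as.character(fa), names(fa))
  pool <- if (file.exists(file.path(dir, "trna_pool.tsv")))
    read_trna_pool_tsv(file.path(dir, "trna_pool.tsv"))
  else parse_trna_pool(file.path(dir, "trna.fa"))
  expr <- utils::read.delim(file.path(dir, "expression.tsv"),
                            stringsAsFactors = FALSE)
  variants <- utils::read.delim(file.path(dir, "variants.tsv"),
                                stringsAsFactors = FALSE)
  mask <- utils::read.delim(file.path(dir, "outgroup_poly.tsv"),
                            stringsAsFactors = FALSE)
  files <- list.files(file.path(dir, "triples"), full.names = TRUE)
  triples <- lapply(files, read_aligned_triple)
  names(triples) <- vapply(triples, `[[`, character(1), "gene_id")
  genes <- data.frame(gene_id = names(cds),
                      length_codons = nchar(cds) %/% 3L,
                      stringsAsFactors = FALSE)
  genes <- merge(genes, expr, by = "gene_id", sort = TRUE)
  truth <- if (file.exists(file.path(dir, "truth.tsv")))
    utils::read.delim(file.path(dir, "truth.tsv"),
                      stringsAsFactors = FALSE) else NULL
  structure(list(config = NULL, genes = genes, cds = cds,
                 triples = triples, variants = variants,
                 outgroup_poly = mask, truth = truth, pool = pool,
                 dir = dir),
            class = "codonsel_dataset")
}

## annotate polarized fixed/polymorphic sites: the reference codon is the
## focal codon with the site base replaced by the ancestral base, so fixed
## sites (whose focal base is the derived one) are handled uniformly
annotate_polarized <- function(sites, cds_set, tai, usage,
                               code = standard_genetic_code()) {
  sel <- sites$status %in% c("fixed", "polymorphic")
  s <- sites[sel, , drop = FALSE]
  n <- nrow(s)
  cols <- c("class", "tai_direction", "cai_direction")
  for (cl in cols) s[[cl]] <- NA_character_
  s$delta_tai <- s$delta_cai <- NA_real_
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    cds <- cds_set[[s$gene_id[i]]]
    pos <- s$cds_pos[i]
    ci <- (pos - 1) %/% 3 + 1
    cp <- (pos - 1) %% 3 + 1
    codon <- substr(cds, (ci - 1) * 3 + 1, ci * 3)
    ref_codon <- codon; substr(ref_codon, cp, cp) <- s$ancestral[i]
    alt_codon <- codon; substr(alt_codon, cp, cp) <- s$derived[i]
    if (!grepl("^[ACGT]{3}$", ref_codon) ||
        !grepl("^[ACGT]{3}$", alt_codon) ||
        code[[ref_codon]] == "*" || ref_codon == alt_codon) {
      drop[i] <- TRUE
      next
    }
    ann <- annotate_codon_change(ref_codon, alt_codon, tai, usage, code)
    s$class[i] <- ann$class
    s$tai_direction[i] <- ann$tai_direction
    s$cai_direction[i] <- ann$cai_direction
    s$delta_tai[i] <- ann$delta_tai
    s$delta_cai[i] <- ann$delta_cai
  }
  list(annotated = s[!drop, , drop = FALSE], n_dropped = sum(drop))
}

## MAF view: every band-passing bi-allelic site in the variant table,
## classified from the focal reference codon towards the alternate allele
## (no ancestral-state information used)
maf_view <- function(variants, cds_set, tai, usage, band = c(0.02, 0.98),
                     code = standard_genetic_code()) {
  if (is.null(variants) || !nrow(variants)) return(data.frame())
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    freqs <- c(A = v$freq_A, C = v$freq_C, G = v$freq_G, T = v$freq_T)
    kept <- frequency_band_filter(freqs, band[1], band[2])
    if (length(kept) != 2L) next
    cds <- cds_set[[v$gene_id]]
    ref <- substr(cds, v$cds_pos, v$cds_pos)
    if (!ref %in% names(kept)) next
    alt <- setdiff(names(kept), ref)
    ann <- tryCatch(
      annotate_variant(cds, v$cds_pos, ref, alt, tai, usage,
                       gene_id = v$gene_id, code = code),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(ann)) next
    ann$maf <- minor_allele_frequency(kept)
    k <- k + 1L
    rows[[k]] <- ann
  }
  if (!k) return(data.frame())
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Run the full selection-on-synonymous-mutations pipeline
#'
#' Orchestrates the stages end to end on a dataset (in-memory from
#' [simulate_dataset()] or loaded with [read_dataset()]): builds the codon
#' tAI table from the tRNA pool, computes RPKM and derives CAI weights from
#' the highly expressed half of the genes, polarizes every focal CDS site
#' against the two outgroups, annotates fixed and polymorphic changes with
#' class and tAI/CAI direction, and produces the selection contrasts
#' (fixed:polymorphic 2x2, DAF and MAF spectra, GC-conservative subsets,
#' nearest-neighbour classes, DAF/MAF regressions, stratified analyses).
#' A run manifest records parameters and per-stage record counts; site
#' conservation (sites walked = polymorphic + fixed + excluded) is checked.
#'
#' @param dataset a \code{codonsel_dataset}.
#' @param top_fraction fraction of genes forming the highly expressed set.
#' @param band allele-frequency band bounds.
#' @return list of class \code{codonsel_run}: \code{tai}, \code{pairs},
#'   \code{usage}, \code{genes}, \code{sites}, \code{annotated},
#'   \code{maf_sites}, \code{stats}, \code{manifest}.
#' @export
run_pipeline <- function(dataset, top_fraction = 0.5,
                         band = c(0.02, 0.98)) {
  stopifnot(inherits(dataset, "codonsel_dataset"))
  code <- standard_genetic_code()
  tai <- build_tai_table(dataset$pool)
  pairs <- enumerate_directed_pairs(tai)

  genes <- dataset$genes
  if (!"rpkm" %in% names(genes)) {
    stopifnot("read_count" %in% names(genes))
    genes$rpkm <- compute_rpkm(genes$read_count,
                               nchar(dataset$cds[genes$gene_id]),
                               sum(genes$read_count))
  }
  if (!"gc" %in% names(genes)) {
    m <- t(vapply(dataset$cds[genes$gene_id], gc_metrics, numeric(2)))
    genes$gc <- m[, "GC"]; genes$gc3 <- m[, "GC3"]
  }
  split2 <- select_high_expression(genes, top_fraction)
  usage <- build_usage_table(dataset$cds[split2$high$gene_id], code)
  genes$cai <- vapply(dataset$cds[genes$gene_id], function(s)
    tryCatch(as.numeric(gene_cai(s, usage, code)),
             error = function(e) NA_real_), numeric(1))

  sites <- do.call(rbind, lapply(dataset$triples, function(tr) {
    mask <- dataset$outgroup_poly
    mask_pos <- if (nrow(mask))
      mask$cds_pos[mask$gene_id == tr$gene_id] else integer(0)
    walk_alignment(tr, dataset$variants, outgroup_poly_pos = mask_pos,
                   band = band)
  }))
  rownames(sites) <- NULL

  ann <- annotate_polarized(sites, dataset$cds, tai, usage, code)
  annotated <- ann$annotated
  maf_sites <- maf_view(dataset$variants, dataset$cds, tai, usage, band,
                        code)

  gene_gc <- stats::setNames(genes$gc, genes$gene_id)
  annotated$gene_gc <- gene_gc[annotated$gene_id]
  if (nrow(maf_sites)) maf_sites$gene_gc <- gene_gc[maf_sites$gene_id]

  syn <- annotated[annotated$class == "synonymous", , drop = FALSE]
  poly <- annotated[annotated$status == "polymorphic", , drop = FALSE]
  poly_syn <- poly[poly$class == "synonymous", , drop = FALSE]

  class_freqs <- function(d, col) {
    list(syn_up = d[[col]][d$class == "synonymous" &
                             d$tai_direction == "up"],
         syn_down = d[[col]][d$class == "synonymous" &
                               d$tai_direction == "down"],
         nonsynonymous = d[[col]][d$class == "nonsynonymous"],
         nonsense = d[[col]][d$class == "nonsense"])
  }
  cnt <- function(dir, st) sum(syn$tai_direction == dir & syn$status == st)

  stats_out <- list()
  if (cnt("up", "polymorphic") > 0 && cnt("down", "polymorphic") > 0)
    stats_out$contingency <- fixed_polymorphic_contrast(
      cnt("up", "fixed"), cnt("up", "polymorphic"),
      cnt("down", "fixed"), cnt("down", "polymorphic"))
  stats_out$daf_spectrum <- spectrum_compare(class_freqs(poly, "daf"),
                                             metric = "DAF")
  if (nrow(maf_sites))
    stats_out$maf_spectrum <- spectrum_compare(
      class_freqs(maf_sites, "maf"), metric = "MAF")
  if (nrow(poly_syn) > 1) {
    stats_out$gbgc <- gbgc_control_subsets(poly_syn)
    stats_out$neighbors <- nearest_neighbor_classes(poly_syn)
  }
  reg_in <- poly_syn[poly_syn$tai_direction %in% c("up", "down", "tie"), ]
  if (nrow(reg_in) >= 10)
    stats_out$daf_regression <- regress_frequency(reg_in, "daf")
  if (nrow(maf_sites)) {
    reg_maf <- maf_sites[maf_sites$class == "synonymous", , drop = FALSE]
    if (nrow(reg_maf) >= 10)
      stats_out$maf_regression <- regress_frequency(reg_maf, "maf")
  }
  if (nrow(poly_syn) > 1) {
    stats_out$stratified_rpkm <- stratified_contrast(
      poly_syn, genes, "rpkm", top_fraction)
    if (length(unique(genes$gc)) > 1)
      stats_out$stratified_gc <- stratified_contrast(
        poly_syn, genes, "gc", top_fraction)
  }

  reason_tab <- table(sites$reason[sites$status == "excluded"])
  manifest <- list(
    parameters = list(top_fraction = top_fraction, band = band),
    inputs = if (!is.null(dataset$dir))
      list(dir = dataset$dir,
           digests = tryCatch(
             tools::md5sum(list.files(dataset$dir, recursive = TRUE,
                                      full.names = TRUE)),
             error = function(e) NULL))
    else list(source = "in-memory dataset",
              seed = dataset$config$seed),
    counts = list(
      genes = nrow(genes),
      sites_walked = nrow(sites),
      polymorphic = sum(sites$status == "polymorphic"),
      fixed = sum(sites$status == "fixed"),
      excluded = sum(sites$status == "excluded"),
      excluded_by_reason = as.list(reason_tab),
      variants_in = if (is.null(dataset$variants)) 0L
                    else nrow(dataset$variants),
      annotated = nrow(annotated),
      annotation_dropped = ann$n_dropped,
      maf_sites = nrow(maf_sites),
      by_class = as.list(table(annotated$class))),
    conservation_ok =
      nrow(sites) == sum(sites$status == "polymorphic") +
                     sum(sites$status == "fixed") +
                     sum(sites$status == "excluded"))
  structure(list(tai = tai, pairs = pairs, usage = usage, genes = genes,
                 sites = sites, annotated = annotated,
                 maf_sites = maf_sites, stats = stats_out,
                 manifest = manifest),
            class = "codonsel_run")
}

#' @export
print.codonsel_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("codonsel pipeline run\n")
  cat("  genes:", cts$genes, " sites walked:", cts$sites_walked, "\n")
  cat("  polymorphic:", cts$polymorphic, " fixed:", cts$fixed,
      " excluded:", cts$excluded, "\n")
  if (!is.null(x$stats$contingency)) {
    cat(sprintf("  fixed:polymorphic ratio up %.1f vs down %.1f (p = %.3g)\n",
                x$stats$contingency$ratio_up,
                x$stats$contingency$ratio_down,
                x$stats$contingency$p_value))
  }
  if (!is.null(x$stats$daf_spectrum)) {
    s <- x$stats$daf_spectrum$summary
    cat(sprintf("  median DAF: syn-up %.3f, syn-down %.3f\n",
                s$median[s$class == "syn_up"],
                s$median[s$class == "syn_down"]))
  }
  cat("  site conservation:",
      if (x$manifest$conservation_ok) "ok" else "VIOLATED", "\n")
  invisible(x)
}
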