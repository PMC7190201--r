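#' Configuration for the synthetic dataset generator
#'
#' Bundles every knob of the generator: gene count and length range, GC
#' targets, the tRNA pool, the expression model, per-class Beta models for
#' derived allele frequencies, per-class planted polymorphic/fixed counts,
#' outgroup divergence and artefact rates, and the stratum interaction
#' multiplier. The defaults define the study conditions used throughout the
#' package's validation: tAI-up synonymous DAFs from Beta(3, 3) versus
#' tAI-down from Beta(2, 4) (means 0.5 vs 1/3), deleterious classes shifted
#' lower still, and a higher fixed:polymorphic ratio for the up class.
#'
#' @param seed integer seed; the same seed reproduces every output byte.
#' @param n_genes number of genes.
#' @param gene_length_codons integer length-2 range of gene lengths in
#'   codons (start and stop included).
#' @param gc_range per-gene GC target range (uniform draw).
#' @param pool a [trna_pool()]; default the bundled synthetic maize-like
#'   pool.
#' @param expression_meanlog,expression_sdlog log-normal read-count model.
#' @param daf_beta named list of Beta(alpha, beta) parameter pairs for
#'   classes \code{syn_up}, \code{syn_down}, \code{nonsynonymous},
#'   \code{nonsense}.
#' @param n_poly,n_fixed named integer vectors of planted polymorphic and
#'   fixed mutation counts per class (dataset totals, spread over genes
#'   proportionally to length).
#' @param outgroup_divergence per-site substitution rate applied to each
#'   outgroup lineage at non-planted sites.
#' @param disagreement_rate,outgroup_gap_rate,outgroup_poly_rate per-site
#'   rates of planted outgroup disagreement, alignment gap, and outgroup
#'   polymorphism-mask sites.
#' @param band allele-frequency band used both to clip planted DAFs and
#'   downstream as the polymorphism filter.
#' @param expr_gap_multiplier in high-expression genes the syn-up Beta
#'   alpha and the syn-down Beta beta are multiplied by this factor,
#'   widening the up/down gap (stronger selection in highly expressed
#'   genes); 1 disables the interaction.
#' @param gc_gap_multiplier same interaction keyed on gene GC target.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 40L,
                       gene_length_codons = c(150L, 400L),
                       gc_range = c(0.35, 0.65),
                       pool = NULL,
                       expression_meanlog = 4,
                       expression_sdlog = 1.5,
                       daf_beta = list(syn_up = c(3, 3),
                                       syn_down = c(2, 4),
                                       nonsynonymous = c(1.5, 5),
                                       nonsense = c(1, 8)),
                       n_poly = c(syn_up = 300L, syn_down = 300L,
                                  nonsynonymous = 350L, nonsense = 40L),
                       n_fixed = c(syn_up = 600L, syn_down = 400L,
                                   nonsynonymous = 350L, nonsense = 0L),
                       outgroup_divergence = 0.03,
                       disagreement_rate = 0.005,
                       outgroup_gap_rate = 0.002,
                       outgroup_poly_rate = 0.002,
                       band = c(0.02, 0.98),
                       expr_gap_multiplier = 1.5,
                       gc_gap_multiplier = 1) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              gene_length_codons = as.integer(gene_length_codons),
              gc_range = gc_range, pool = pool,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              daf_beta = daf_beta, n_poly = n_poly, n_fixed = n_fixed,
              outgroup_divergence = outgroup_divergence,
              disagreement_rate = disagreement_rate,
              outgroup_gap_rate = outgroup_gap_rate,
              outgroup_poly_rate = outgroup_poly_rate,
              band = band,
              expr_gap_multiplier = expr_gap_multiplier,
              gc_gap_multiplier = gc_gap_multiplier)
  rates <- c(outgroup_divergence, disagreement_rate, outgroup_gap_rate,
             outgroup_poly_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(unlist(daf_beta) <= 0)) stop("Beta parameters must be positive")
  if (n_genes < 1L) stop("need at least one gene")
  if (gene_length_codons[1] < 10L) stop("genes must be at least 10 codons")
  classes <- c("syn_up", "syn_down", "nonsynonymous", "nonsense")
  if (!all(classes %in% names(daf_beta)) ||
      !all(classes %in% names(n_poly)) || !all(classes %in% names(n_fixed)))
    stop("daf_beta, n_poly and n_fixed must name the four classes")
  class(cfg) <- "sim_config"
  cfg
}

#' Draw derived allele frequencies from a class's Beta model
#'
#' The per-class DAF model of the generator: a Beta(alpha, beta) draw,
#' resampled until it falls inside the polymorphism frequency band, with
#' the stratum interaction multiplier applied for synonymous classes in
#' high-expression / high-GC genes. Exposed so replicate studies can run
#' the spectrum statistics directly on generator draws.
#'
#' @param n number of draws.
#' @param class one of \code{syn_up}, \code{syn_down},
#'   \code{nonsynonymous}, \code{nonsense}.
#' @param config a [sim_config()].
#' @param high_expr,high_gc stratum flags of the host gene.
#' @return Numeric vector of DAFs inside the band.
#' @export
sample_daf <- function(n, class, config, high_expr = FALSE,
                       high_gc = FALSE) {
  ab <- config$daf_beta[[class]]
  if (class %in% c("syn_up", "syn_down")) {
    m <- (if (high_expr) config$expr_gap_multiplier else 1) *
         (if (high_gc) config$gc_gap_multiplier else 1)
    if (class == "syn_up") ab[1] <- ab[1] * m else ab[2] <- ab[2] * m
  }
  d <- stats::rbeta(n, ab[1], ab[2])
  lo <- config$band[1]; hi <- config$band[2]
  bad <- d < lo | d > hi
  while (any(bad)) {
    d[bad] <- stats::rbeta(sum(bad), ab[1], ab[2])
    bad <- d < lo | d > hi
  }
  d
}

## single-base mutation options per sense codon: for each (from, to) neighbor
## the class key used by the planting plan
mutation_options <- function(tai, code = standard_genetic_code()) {
  W <- stats::setNames(tai$W, tai$codon)
  bases <- c("A", "C", "G", "T")
  rows <- list(); k <- 0L
  for (cd in tai$codon) {
    for (p in 1:3) for (b in bases) {
      if (substr(cd, p, p) == b) next
      alt <- cd; substr(alt, p, p) <- b
      aa_alt <- code[[alt]]
      key <- if (aa_alt == "*") "nonsense"
             else if (aa_alt != code[[cd]]) "nonsynonymous"
             else if (W[[alt]] > W[[cd]]) "syn_up"
             else if (W[[alt]] < W[[cd]]) "syn_down" else "syn_tie"
      k <- k + 1L
      rows[[k]] <- data.frame(from = cd, to = alt, position = p, key = key,
                              stringsAsFactors = FALSE)
    }
  }
  opts <- do.call(rbind, rows)
  split(opts, opts$from)
}

#' Plant classified mutations into one CDS
#'
#' Chooses codons of the CDS (never the start or stop codon, one mutation
#' per codon) whose single-base neighbourhoods realize the requested plan
#' of mutation classes, so that the planted tAI direction of every
#' synonymous mutation is exact by construction (it comes from the same
#' directed-pair logic the annotator uses).
#'
#' @param cds CDS sequence (character scalar).
#' @param options per-codon mutation options from the internal option
#'   builder; pass \code{NULL} to build from \code{tai}.
#' @param plan named integer vector of requested counts over keys
#'   \code{syn_up}, \code{syn_down}, \code{nonsynonymous}, \code{nonsense}.
#' @param tai codon tAI table (used when \code{options} is NULL).
#' @return data.frame with one row per planted mutation: \code{codon_index},
#'   \code{codon_pos}, \code{cds_pos}, \code{ref_codon}, \code{alt_codon},
#'   \code{ref}, \code{alt}, \code{key}. Errors listing the shortfall when
#'   the CDS cannot host the plan.
#' @export
plant_variants <- function(cds, plan, tai = NULL, options = NULL) {
  if (is.null(options)) options <- mutation_options(tai)
  plan <- plan[plan > 0]
  if (!length(plan))
    return(data.frame(codon_index = integer(0), codon_pos = integer(0),
                      cds_pos = integer(0), ref_codon = character(0),
                      alt_codon = character(0), ref = character(0),
                      alt = character(0), key = character(0)))
  codons <- cds_codons(cds, warn = FALSE)
  if (is.null(codons)) stop("invalid CDS")
  need <- as.list(plan)
  cand <- sample(2:length(codons))   # spare the start codon
  rows <- list(); k <- 0L
  for (ci in cand) {
    if (!any(unlist(need) > 0)) break
    opt <- options[[codons[ci]]]
    if (is.null(opt)) next
    avail <- intersect(names(need)[unlist(need) > 0], unique(opt$key))
    if (!length(avail)) next
    key <- avail[[1]]
    pick <- opt[opt$key == key, , drop = FALSE]
    pick <- pick[sample(nrow(pick), 1L), ]
    k <- k + 1L
    cds_pos <- (ci - 1L) * 3L + pick$position
    rows[[k]] <- data.frame(codon_index = ci, codon_pos = pick$position,
                            cds_pos = cds_pos, ref_codon = pick$from,
                            alt_codon = pick$to,
                            ref = substr(pick$from, pick$position,
                                         pick$position),
                            alt = substr(pick$to, pick$position,
                                         pick$position),
                            key = key, stringsAsFactors = FALSE)
    need[[key]] <- need[[key]] - 1L
  }
  short <- unlist(need)[unlist(need) > 0]
  if (length(short))
    stop("insufficient eligible codons; shortfall: ",
         paste(names(short), short, sep = "=", collapse = ", "))
  out <- do.call(rbind, rows)
  out[order(out$cds_pos), , drop = FALSE]
}

## random CDS with a GC target: iid base model conditioned on sense codons
random_cds <- function(n_codons, gc_target,
                       code = standard_genetic_code()) {
  sense <- sense_codons(code)
  gcn <- vapply(strsplit(sense, ""), function(ch)
    sum(ch %in% c("G", "C")), numeric(1))
  p <- (gc_target / 2)^gcn * ((1 - gc_target) / 2)^(3 - gcn)
  body <- sample(sense, n_codons - 2L, replace = TRUE, prob = p / sum(p))
  stopc <- sample(c("TAA", "TAG", "TGA"), 1L)
  paste0("ATG", paste(body, collapse = ""), stopc)
}

#' Generate a complete synthetic dataset
#'
#' Produces every input the pipeline consumes - CDS set, tRNA pool,
#' expression table, aligned focal+outgroup triples, allele-frequency
#' table, outgroup polymorphism mask - together with a GroundTruth table
#' recording each planted mutation's class, direction, status and DAF.
#' Synonymous mutations are planted from the directed-pair table, so their
#' up/down labels are exact by construction; DAFs are drawn from the class
#' Beta models; fixed differences are written into the focal sequence with
#' both outgroups keeping the ancestral base; outgroup disagreement, gap
#' and polymorphism-mask sites are planted at the configured rates at
#' positions disjoint from the planted mutations.
#'
#' @param config a [sim_config()].
#' @return list of class \code{codonsel_dataset} with elements
#'   \code{config}, \code{genes}, \code{cds}, \code{ancestral},
#'   \code{triples}, \code{variants}, \code{outgroup_poly}, \code{truth},
#'   \code{pool}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pool <- config$pool
  if (is.null(pool)) pool <- synthetic_maize_pool()
  tai <- build_tai_table(pool)
  opts <- mutation_options(tai)

  n <- config$n_genes
  lens <- sample(seq(config$gene_length_codons[1],
                     config$gene_length_codons[2]), n, replace = TRUE)
  gct <- stats::runif(n, config$gc_range[1], config$gc_range[2])
  ids <- sprintf("gene%03d", seq_len(n))
  reads <- pmax(1, round(stats::rlnorm(n, config$expression_meanlog,
                                       config$expression_sdlog)))
  rpkm <- compute_rpkm(reads, lens * 3L, sum(reads))
  high_expr <- ids %in%
    select_high_expression(data.frame(gene_id = ids, rpkm = rpkm))$high$gene_id
  high_gc <- gct > stats::median(gct)

  classes <- c("syn_up", "syn_down", "nonsynonymous", "nonsense")
  spread <- function(tot) {
    m <- vapply(classes, function(cl)
      as.integer(stats::rmultinom(1, tot[[cl]], prob = lens)), integer(n))
    rownames(m) <- ids
    m
  }
  poly_plan <- spread(config$n_poly)
  fixed_plan <- spread(config$n_fixed)

  cds <- ancestral <- stats::setNames(character(n), ids)
  triples <- vector("list", n); names(triples) <- ids
  var_rows <- truth_rows <- mask_rows <- list()
  gc_real <- gc3_real <- numeric(n)

  for (i in seq_len(n)) {
    anc <- random_cds(lens[i], gct[i])
    plan <- poly_plan[i, ] + fixed_plan[i, ]
    planted <- plant_variants(anc, plan, options = opts)
    ## decide which planted rows are fixed vs polymorphic, per class
    planted$status <- NA_character_
    for (cl in classes) {
      rows_cl <- which(planted$key == cl)
      rows_cl <- rows_cl[sample.int(length(rows_cl))]
      nf <- fixed_plan[i, cl]
      planted$status[rows_cl] <- rep(c("fixed", "polymorphic"),
                                     c(nf, length(rows_cl) - nf))
    }
    foc <- anc
    fx <- planted[planted$status == "fixed", , drop = FALSE]
    for (j in seq_len(nrow(fx)))
      substr(foc, fx$cds_pos[j], fx$cds_pos[j]) <- fx$alt[j]
    po <- planted[planted$status == "polymorphic", , drop = FALSE]
    po$daf <- rep(NA_real_, nrow(po))
    for (cl in classes) {
      sel <- po$key == cl
      if (any(sel))
        po$daf[sel] <- sample_daf(sum(sel), cl, config,
                                  high_expr = high_expr[i],
                                  high_gc = high_gc[i])
    }
    if (nrow(po)) {
      freqs <- matrix(0, nrow(po), 4,
                      dimnames = list(NULL, c("A", "C", "G", "T")))
      for (j in seq_len(nrow(po))) {
        freqs[j, po$alt[j]] <- po$daf[j]
        freqs[j, po$ref[j]] <- 1 - po$daf[j]
      }
      var_rows[[i]] <- data.frame(gene_id = ids[i], cds_pos = po$cds_pos,
                                  freq_A = freqs[, "A"],
                                  freq_C = freqs[, "C"],
                                  freq_G = freqs[, "G"],
                                  freq_T = freqs[, "T"],
                                  stringsAsFactors = FALSE)
    }

    ## outgroups: ancestral plus lineage-specific divergence, then planted
    ## disagreement / gap / mask sites, all disjoint from planted mutations
    L <- nchar(anc)
    o1 <- o2 <- anc
    free <- setdiff(seq_len(L), planted$cds_pos)
    free <- free[sample.int(length(free))]
    take <- function(rate) {
      k <- min(length(free), stats::rbinom(1, L, rate))
      taken <- free[seq_len(k)]
      if (k > 0L) free <<- free[-seq_len(k)]
      taken
    }
    mutate_at <- function(seq, pos) {
      for (p in pos) {
        b <- substr(seq, p, p)
        substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }
      seq
    }
    div <- take(config$outgroup_divergence)
    to1 <- div[sample(c(TRUE, FALSE), length(div), replace = TRUE)]
    o1 <- mutate_at(o1, to1)
    o2 <- mutate_at(o2, setdiff(div, to1))
    disag <- take(config$disagreement_rate)
    o1 <- mutate_at(o1, disag)          # out1 differs from ancestral...
    for (p in disag) {                  # ...and out2 differs from out1
      b1 <- substr(o1, p, p)
      substr(o2, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b1), 1L)
    }
    gaps <- take(config$outgroup_gap_rate)
    for (p in gaps) substr(o1, p, p) <- "-"
    mask <- take(config$outgroup_poly_rate)
    if (length(mask))
      mask_rows[[i]] <- data.frame(gene_id = ids[i], cds_pos = sort(mask))

    cds[i] <- foc; ancestral[i] <- anc
    triples[[i]] <- aligned_triple(foc, o1, o2, gene_id = ids[i])
    m <- gc_metrics(foc)
    gc_real[i] <- m[["GC"]]; gc3_real[i] <- m[["GC3"]]

    tr <- rbind(
      if (nrow(fx)) data.frame(gene_id = ids[i], cds_pos = fx$cds_pos,
                               class = fx$key, status = "fixed",
                               daf = NA_real_, ancestral = fx$ref,
                               derived = fx$alt, ref_codon = fx$ref_codon,
                               alt_codon = fx$alt_codon,
                               stringsAsFactors = FALSE),
      if (nrow(po)) data.frame(gene_id = ids[i], cds_pos = po$cds_pos,
                               class = po$key, status = "polymorphic",
                               daf = po$daf, ancestral = po$ref,
                               derived = po$alt, ref_codon = po$ref_codon,
                               alt_codon = po$alt_codon,
                               stringsAsFactors = FALSE))
    extra <- rbind(
      if (length(disag)) data.frame(gene_id = ids[i], cds_pos = disag,
                                    kind = "disagreement"),
      if (length(gaps)) data.frame(gene_id = ids[i], cds_pos = gaps,
                                   kind = "gap"),
      if (length(mask)) data.frame(gene_id = ids[i], cds_pos = mask,
                                   kind = "outgroup_poly"),
      if (length(div)) data.frame(gene_id = ids[i], cds_pos = div,
                                  kind = "divergence"))
    truth_rows[[i]] <- list(mut = tr, extra = extra)
  }

  truth <- do.call(rbind, lapply(truth_rows, `[[`, "mut"))
  planted_extra <- do.call(rbind, lapply(truth_rows, `[[`, "extra"))
  rownames(truth) <- rownames(planted_extra) <- NULL
  genes <- data.frame(gene_id = ids, length_codons = lens,
                      gc_target = gct, gc = gc_real, gc3 = gc3_real,
                      read_count = reads, rpkm = rpkm,
                      high_expr = high_expr, high_gc = high_gc,
                      stringsAsFactors = FALSE)
  structure(list(config = config, genes = genes, cds = cds,
                 ancestral = ancestral, triples = triples,
                 variants = do.call(rbind, var_rows),
                 outgroup_poly = if (length(mask_rows))
                   do.call(rbind, mask_rows)
                 else data.frame(gene_id = character(0),
                                 cds_pos = integer(0)),
                 truth = truth, planted_extra = planted_extra,
                 pool = pool),
            class = "codonsel_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits exactly the formats the pipeline consumes: \code{cds.fa},
#' \code{trna.fa} (GtRNAdb dialect) and \code{trna_pool.tsv},
#' \code{expression.tsv}, \code{variants.tsv}, \code{outgroup_poly.tsv},
#' one aligned triple FASTA per gene under \code{triples/}, and
#' \code{truth.tsv}.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "triples"), recursive = TRUE,
             showWarnings = FALSE)
  wfa <- function(seqs, file) {
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), file)
  }
  wfa(dataset$cds, file.path(dir, "cds.fa"))
  write_gtrnadb_fasta(dataset$pool, file.path(dir, "trna.fa"))
  utils::write.table(
    data.frame(anticodon = names(dataset$pool),
               copies = as.integer(dataset$pool)),
    file.path(dir, "trna_pool.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(dataset$genes[, c("gene_id", "read_count")],
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$outgroup_poly,
                     file.path(dir, "outgroup_poly.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(dataset$triples)) {
    tr <- dataset$triples[[id]]
    wfa(stats::setNames(c(tr$focal, tr$out1, tr$out2),
                        paste0(id, c("_focal", "_out1", "_out2"))),
        file.path(dir, "triples", paste0(id, ".fa")))
  }
  invisible(dir)
}
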