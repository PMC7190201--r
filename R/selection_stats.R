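#' Fixed-to-polymorphic contrast between two mutation classes
#'
#' McDonald-Kreitman-style 2x2 contrast of fixed vs polymorphic counts for
#' two classes (conventionally the tAI-up and tAI-down synonymous classes).
#' Reports per-class fixed:polymorphic ratios, the sample odds ratio and a
#' two-sided Fisher exact p-value.
#'
#' @param fixed_up,poly_up,fixed_down,poly_down non-negative integer counts.
#' @return list of class \code{contingency_result}: \code{table} (2x2),
#'   \code{ratio_up}, \code{ratio_down} (NA and flagged when the polymorphic
#'   count is zero), \code{odds_ratio}, \code{p_value}.
#' @examples
#' fixed_polymorphic_contrast(255236, 2220, 181820, 2645)
#' @export
fixed_polymorphic_contrast <- function(fixed_up, poly_up, fixed_down,
                                       poly_down) {
  counts <- c(fixed_up, poly_up, fixed_down, poly_down)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(c("up", "down"),
                                c("fixed", "polymorphic")))
  ratio <- function(f, p) if (p > 0) f / p else NA_real_
  res <- list(table = tab,
              ratio_up = ratio(fixed_up, poly_up),
              ratio_down = ratio(fixed_down, poly_down),
              odds_ratio = (fixed_up * poly_down) /
                           (fixed_down * poly_up),
              p_value = stats::fisher.test(tab)$p.value,
              zero_polymorphic = poly_up == 0 || poly_down == 0)
  class(res) <- "contingency_result"
  res
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("fixed:polymorphic ratios: up %.1f, down %.1f\n",
              x$ratio_up, x$ratio_down))
  cat(sprintf("odds ratio %.3f, Fisher two-sided p = %.3g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test with a small-sample exact path
#'
#' For small samples the null distribution of the rank-sum statistic is
#' obtained by exhaustive enumeration of all assignments of the observed
#' (possibly tied, midranked) ranks to the two groups, so the exact p-value
#' is valid under ties; larger samples use the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y numeric vectors.
#' @param exact_limit maximum number of group assignments
#'   (\code{choose(n1+n2, n1)}) for which the exact path is used.
#' @return list: \code{statistic} (Mann-Whitney U of \code{x}), \code{p_value},
#'   \code{method} ("exact" or "normal").
#' @export
rank_sum_test <- function(x, y, exact_limit = 2e5) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= exact_limit) {
    idx <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    u_all <- sums - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u + eps), mean(u_all >= u - eps)))
    list(statistic = u, p_value = p, method = "exact")
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    list(statistic = u, p_value = p, method = "normal")
  }
}

#' Compare allele-frequency spectra between mutation classes
#'
#' Summarizes per-class DAF or MAF vectors (n, median) and runs two-sided
#' Wilcoxon rank-sum tests for each requested pair of classes (all pairs of
#' non-empty classes by default). Contrasts involving an empty class are
#' skipped and reported.
#'
#' @param freq_by_class named list of numeric vectors (one per class, e.g.
#'   \code{syn_up}, \code{syn_down}, \code{nonsynonymous}, \code{nonsense}).
#' @param metric label carried through ("DAF" or "MAF").
#' @param contrasts optional 2-column character matrix of class pairs.
#' @param p_adjust multiple-testing correction method passed to
#'   [stats::p.adjust()]; default "none" (a "BH" flag is available).
#' @return list of class \code{spectrum_summary}: \code{metric},
#'   \code{summary} (data.frame class/n/median), \code{tests} (data.frame
#'   class1/class2/p_value/method), \code{skipped}.
#' @export
spectrum_compare <- function(freq_by_class, metric = c("DAF", "MAF"),
                             contrasts = NULL, p_adjust = "none") {
  metric <- match.arg(metric)
  stopifnot(is.list(freq_by_class), !is.null(names(freq_by_class)))
  cls <- names(freq_by_class)
  n <- vapply(freq_by_class, length, integer(1))
  summ <- data.frame(class = cls, n = unname(n),
                     median = vapply(freq_by_class, function(v)
                       if (length(v)) stats::median(v) else NA_real_,
                       numeric(1)),
                     stringsAsFactors = FALSE)
  if (is.null(contrasts)) {
    if (length(cls) >= 2) contrasts <- t(utils::combn(cls, 2))
    else contrasts <- matrix(character(0), ncol = 2)
  }
  tests <- data.frame(class1 = character(0), class2 = character(0),
                      p_value = numeric(0), method = character(0),
                      stringsAsFactors = FALSE)
  skipped <- character(0)
  for (i in seq_len(nrow(contrasts))) {
    a <- contrasts[i, 1]; b <- contrasts[i, 2]
    if (n[[a]] == 0 || n[[b]] == 0) {
      skipped <- c(skipped, paste(a, "vs", b))
      next
    }
    rs <- rank_sum_test(freq_by_class[[a]], freq_by_class[[b]])
    tests <- rbind(tests, data.frame(class1 = a, class2 = b,
                                     p_value = rs$p_value,
                                     method = rs$method,
                                     stringsAsFactors = FALSE))
  }
  if (nrow(tests)) tests$p_adjusted <- stats::p.adjust(tests$p_value,
                                                       method = p_adjust)
  structure(list(metric = metric, summary = summ, tests = tests,
                 skipped = skipped),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(x$metric, "spectrum summary\n")
  print(x$summary, row.names = FALSE)
  if (nrow(x$tests)) print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Stratified spectrum and fixed:polymorphic contrasts
#'
#' Splits genes into two strata (top fraction vs rest) by a per-gene value
#' (RPKM or GC content), recomputes the syn-up vs syn-down spectrum
#' comparison and, when fixed/polymorphic status is present, the 2x2
#' contrast within each stratum, and reports the difference of median gaps
#' (median(up) - median(down)) between strata as the effect-size contrast.
#'
#' @param sites data.frame of synonymous sites with columns \code{gene_id},
#'   \code{tai_direction} ("up"/"down"), a frequency column named by
#'   \code{value_col}, and optionally \code{status}.
#' @param gene_meta data.frame with \code{gene_id} and the stratifier column.
#' @param stratifier name of the stratifying column in \code{gene_meta}.
#' @param fraction top fraction forming the "high" stratum.
#' @param value_col frequency column to compare; default \code{"daf"}.
#' @return list with per-stratum results (\code{high}, \code{low}), each
#'   holding \code{spectrum} and (optionally) \code{contingency}, plus
#'   \code{gap_high}, \code{gap_low} and \code{gap_difference}.
#' @export
stratified_contrast <- function(sites, gene_meta, stratifier,
                                fraction = 0.5, value_col = "daf") {
  stopifnot(stratifier %in% names(gene_meta),
            all(c("gene_id", "tai_direction", value_col) %in% names(sites)))
  vals <- gene_meta[[stratifier]]
  if (length(unique(vals)) < 2L) stop("degenerate stratifier: '",
                                      stratifier, "' is constant")
  if (!all(sites$gene_id %in% gene_meta$gene_id))
    stop("every site's gene must appear in gene_meta")
  fake <- data.frame(gene_id = gene_meta$gene_id, rpkm = vals)
  split2 <- select_high_expression(fake, fraction)
  strata <- list(high = split2$high$gene_id, low = split2$low$gene_id)
  one <- function(gids) {
    s <- sites[sites$gene_id %in% gids, , drop = FALSE]
    keep <- if ("status" %in% names(s))
      is.na(s$status) | s$status == "polymorphic"
    else rep(TRUE, nrow(s))
    up <- s[[value_col]][s$tai_direction == "up" & keep]
    down <- s[[value_col]][s$tai_direction == "down" & keep]
    spec <- spectrum_compare(list(syn_up = up[!is.na(up)],
                                  syn_down = down[!is.na(down)]))
    res <- list(spectrum = spec, n_sites = nrow(s))
    if ("status" %in% names(s)) {
      cnt <- function(dir, st) sum(s$tai_direction == dir & s$status == st,
                                   na.rm = TRUE)
      if (cnt("up", "polymorphic") > 0 && cnt("down", "polymorphic") > 0)
        res$contingency <- fixed_polymorphic_contrast(
          cnt("up", "fixed"), cnt("up", "polymorphic"),
          cnt("down", "fixed"), cnt("down", "polymorphic"))
    }
    res
  }
  res <- lapply(strata, one)
  gap <- function(r) {
    m <- r$spectrum$summary
    m$median[m$class == "syn_up"] - m$median[m$class == "syn_down"]
  }
  list(high = res$high, low = res$low,
       gap_high = gap(res$high), gap_low = gap(res$low),
       gap_difference = gap(res$high) - gap(res$low))
}

#' GC-conservative (gene-conversion control) spectrum subsets
#'
#' GC-biased gene conversion can mimic selection by favouring G/C alleles,
#' but it cannot act on A<->T or C<->G changes. This restricts the syn-up
#' vs syn-down comparison to those GC-conservative allele pairs.
#'
#' @param sites data.frame with \code{ancestral}, \code{derived},
#'   \code{tai_direction} and the frequency column \code{value_col}.
#' @param value_col frequency column; default \code{"daf"}.
#' @return list with elements \code{AT} and \code{CG}, each a
#'   [spectrum_compare()] result over \code{syn_up}/\code{syn_down}, plus
#'   subset sizes.
#' @export
gbgc_control_subsets <- function(sites, value_col = "daf") {
  stopifnot(all(c("ancestral", "derived", "tai_direction", value_col)
                %in% names(sites)))
  pairset <- function(b1, b2)
    (sites$ancestral == b1 & sites$derived == b2) |
    (sites$ancestral == b2 & sites$derived == b1)
  one <- function(sel) {
    s <- sites[sel & !is.na(sites[[value_col]]), , drop = FALSE]
    spectrum_compare(list(syn_up = s[[value_col]][s$tai_direction == "up"],
                          syn_down = s[[value_col]][s$tai_direction == "down"]))
  }
  list(AT = one(pairset("A", "T")), CG = one(pairset("C", "G")),
       n_AT = sum(pairset("A", "T")), n_CG = sum(pairset("C", "G")))
}

#' Nearest-neighbour clustering classes for up/down mutations
#'
#' For every classified synonymous site in a gene with at least two such
#' sites, finds the nearest other site by absolute CDS distance (ties
#' broken towards the upstream site) and labels the site by its own
#' direction and its neighbour's (\code{up_near_up}, \code{up_near_down},
#' \code{down_near_up}, \code{down_near_down}). If allele frequencies are
#' shaped by recombination-linked processes rather than per-site selection,
#' the "near up" and "near down" variants of a class should differ; under
#' per-site selection they should not.
#'
#' @param sites data.frame with \code{gene_id}, \code{cds_pos},
#'   \code{tai_direction} ("up"/"down") and the frequency column
#'   \code{value_col}.
#' @param value_col frequency column; default \code{"daf"}.
#' @return list: \code{labels} (sites with \code{neighbor_dir},
#'   \code{nn_distance}, \code{nn_class}), \code{per_gene} (median
#'   nearest-neighbour distance), \code{tests} (Wilcoxon up_near_up vs
#'   up_near_down and down_near_up vs down_near_down),
#'   \code{n_skipped_genes}.
#' @export
nearest_neighbor_classes <- function(sites, value_col = "daf") {
  stopifnot(all(c("gene_id", "cds_pos", "tai_direction", value_col)
                %in% names(sites)))
  sites <- sites[sites$tai_direction %in% c("up", "down"), , drop = FALSE]
  by_gene <- split(sites, sites$gene_id)
  skipped <- sum(vapply(by_gene, nrow, integer(1)) < 2L)
  lab <- lapply(by_gene, function(g) {
    if (nrow(g) < 2L) return(NULL)
    g <- g[order(g$cds_pos), , drop = FALSE]
    nn_dir <- character(nrow(g)); nn_dist <- integer(nrow(g))
    for (i in seq_len(nrow(g))) {
      d <- abs(g$cds_pos - g$cds_pos[i])
      d[i] <- NA
      j <- which(d == min(d, na.rm = TRUE))
      j <- j[which.min(g$cds_pos[j])]   # tie towards the upstream site
      nn_dir[i] <- g$tai_direction[j]
      nn_dist[i] <- d[j]
    }
    g$neighbor_dir <- nn_dir
    g$nn_distance <- nn_dist
    g$nn_class <- paste0(g$tai_direction, "_near_", nn_dir)
    g
  })
  labels <- do.call(rbind, lab[!vapply(lab, is.null, logical(1))])
  if (is.null(labels))
    return(list(labels = data.frame(), per_gene = data.frame(),
                tests = data.frame(), n_skipped_genes = skipped))
  rownames(labels) <- NULL
  per_gene <- stats::aggregate(nn_distance ~ gene_id, data = labels,
                               FUN = stats::median)
  names(per_gene)[2] <- "median_nn_distance"
  pair_test <- function(c1, c2) {
    v1 <- labels[[value_col]][labels$nn_class == c1]
    v2 <- labels[[value_col]][labels$nn_class == c2]
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    if (!length(v1) || !length(v2))
      return(data.frame(class1 = c1, class2 = c2, p_value = NA_real_,
                        n1 = length(v1), n2 = length(v2)))
    data.frame(class1 = c1, class2 = c2,
               p_value = rank_sum_test(v1, v2)$p_value,
               n1 = length(v1), n2 = length(v2))
  }
  tests <- rbind(pair_test("up_near_up", "up_near_down"),
                 pair_test("down_near_up", "down_near_down"))
  list(labels = labels, per_gene = per_gene, tests = tests,
       n_skipped_genes = skipped)
}

#' Regress allele frequency on CAI change, tAI change and gene GC
#'
#' Ordinary least squares fit of DAF or MAF on the CAI weight change, the
#' tAI weight change and the host gene's GC fraction, over complete-case
#' synonymous sites, quantifying the relative contribution of each factor
#' to the frequency spectrum.
#'
#' @param data data.frame with the response column (\code{daf} or
#'   \code{maf}) and predictors \code{delta_cai}, \code{delta_tai},
#'   \code{gene_gc}.
#' @param response "daf" or "maf".
#' @return list of class \code{regression_result}: \code{coefficients}
#'   (data.frame term/estimate/se), \code{n}, \code{flagged} (names of
#'   constant or aliased predictors), \code{fit} (the \code{lm} object).
#' @export
regress_frequency <- function(data, response = c("daf", "maf")) {
  response <- match.arg(response)
  preds <- c("delta_cai", "delta_tai", "gene_gc")
  stopifnot(all(c(response, preds) %in% names(data)))
  d <- data[stats::complete.cases(data[, c(response, preds)]), , drop = FALSE]
  if (nrow(d) < length(preds) + 2L) stop("too few complete cases")
  flagged <- preds[vapply(preds, function(p) length(unique(d[[p]])) < 2L,
                          logical(1))]
  fit <- stats::lm(stats::reformulate(preds, response), data = d)
  if (any(is.na(stats::coef(fit))))
    flagged <- union(flagged,
                     names(stats::coef(fit))[is.na(stats::coef(fit))])
  if (length(flagged))
    warning("constant or aliased predictor(s): ",
            paste(flagged, collapse = ", "))
  cf <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      se = cf[, 2], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, n = nrow(d), flagged = flagged,
                 fit = fit),
            class = "regression_result")
}

#' Spearman correlation with tie-corrected p-value
#'
#' Thin wrapper used for the gene-level GC ~ tAI, GC ~ structured-fraction
#' and tAI ~ structured-fraction relations.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param method correlation method; only "spearman" is offered.
#' @return list: \code{rho}, \code{p_value}, \code{n}.
#' @export
correlate <- function(x, y, method = "spearman") {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
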