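#' Wobble pairing penalties
#'
#' Selective-constraint values \eqn{s_{ij}} for the non-Watson-Crick
#' anticodon:codon pairings at the wobble position (anticodon position 34 vs
#' codon position 3). Watson-Crick and I:U pairings carry \eqn{s = 0}. The
#' defaults are the eukaryote-calibrated values used for plant tAI:
#' \eqn{s_{G:U} = 0.7861}, \eqn{s_{I:C} = 0.4659}, \eqn{s_{I:A} = 0.9075},
#' \eqn{s_{U:G} = 0.6295}. Each penalty discounts the contribution of that
#' decoder: a pairing with penalty \eqn{s} contributes \eqn{(1-s)} per tRNA
#' gene copy.
#'
#' @param s_GU,s_IC,s_IA,s_UG penalties in \[0, 1\]. Names follow the
#'   anticodon:codon convention (e.g. \code{s_GU} is anticodon G34 reading a
#'   codon ending U).
#' @return An object of class \code{wobble_penalties}.
#' @export
wobble_penalties <- function(s_GU = 0.7861, s_IC = 0.4659,
                             s_IA = 0.9075, s_UG = 0.6295) {
  s <- c(s_GU = s_GU, s_IC = s_IC, s_IA = s_IA, s_UG = s_UG)
  if (any(s < 0 | s > 1)) stop("wobble penalties must lie in [0, 1]")
  structure(as.list(s), class = "wobble_penalties")
}

## third codon base -> (anticodon-34 base of the wobble decoder, penalty name,
## pairing label). The Watson-Crick decoder is always the reverse complement
## of the codon and carries s = 0 (this also covers I:U, read by the same
## A34-encoded anticodon).
.wobble_rule <- list(
  T = c(ac34 = "G", s = "s_GU", pairing = "G:U"),
  C = c(ac34 = "A", s = "s_IC", pairing = "I:C"),
  A = c(ac34 = "A", s = "s_IA", pairing = "I:A"),
  G = c(ac34 = "T", s = "s_UG", pairing = "U:G")
)

#' Decoders of a sense codon in a tRNA pool
#'
#' For a sense codon, lists the anticodons in the pool that can decode it:
#' the Watson-Crick anticodon (reverse complement of the codon, \eqn{s = 0})
#' and the single wobble decoder determined by the codon's third base
#' (codon3 U: anticodon G34, penalty \code{s_GU}; codon3 C: A34 read as
#' inosine, \code{s_IC}; codon3 A: A34 as inosine, \code{s_IA}; codon3 G:
#' U34, \code{s_UG}). An anticodon is reported only if present in the pool.
#'
#' @param codon a sense codon (DNA alphabet).
#' @param pool a [trna_pool()].
#' @param s a [wobble_penalties()] object.
#' @param code genetic code.
#' @return data.frame with columns \code{anticodon}, \code{pairing},
#'   \code{s}, \code{tgcn}; zero rows if no decoder is present.
#' @examples
#' pool <- trna_pool(c(AGC = 2, GGC = 3))
#' decoding_pairs("GCT", pool)   # AGC (WC) and GGC (G:U)
#' @export
decoding_pairs <- function(codon, pool, s = wobble_penalties(),
                           code = standard_genetic_code()) {
  codon <- normalize_dna(codon)
  stopifnot(length(codon) == 1L)
  if (!codon %in% names(code)) stop("not a codon: ", codon)
  if (code[[codon]] == "*")
    stop("stop codon '", codon, "' has no decoding request")
  wc <- revcomp(codon)
  rule <- .wobble_rule[[substr(codon, 3, 3)]]
  wob <- paste0(rule[["ac34"]], substr(wc, 2, 3))
  out <- data.frame(anticodon = c(wc, wob),
                    pairing = c("WC", rule[["pairing"]]),
                    s = c(0, s[[rule[["s"]]]]),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$anticodon), , drop = FALSE]
  out <- out[out$anticodon %in% names(pool), , drop = FALSE]
  out$tgcn <- as.integer(unclass(pool)[out$anticodon])
  rownames(out) <- NULL
  out
}

#' Absolute tAI weight of a codon
#'
#' \eqn{W = \sum_j (1 - s_{ij})\, \mathrm{tGCN}_j} over the codon's decoders
#' present in the pool. \eqn{W = 0} when no decoder exists.
#'
#' @inheritParams decoding_pairs
#' @return Non-negative numeric weight.
#' @examples
#' pool <- trna_pool(c(AGC = 2, GGC = 3))
#' codon_weight("GCT", pool)  # 2*1 + 3*(1 - 0.7861) = 2.6417
#' @export
codon_weight <- function(codon, pool, s = wobble_penalties(),
                         code = standard_genetic_code()) {
  dp <- decoding_pairs(codon, pool, s, code)
  if (nrow(dp) == 0L) return(0)
  sum((1 - dp$s) * dp$tgcn)
}

#' Per-codon tAI table with within-amino-acid optimality classes
#'
#' Computes the absolute weight W for all 61 sense codons, ranks codons
#' within each amino-acid family by W (descending; ties broken by
#' alphabetical codon order), and splits each family into high/low
#' optimality classes: half and half for even family sizes, odd sizes
#' rounded towards high (Ile 2 high / 1 low; Met and Trp high). Under the
#' standard code this always yields 32 high and 29 low codons.
#'
#' @inheritParams decoding_pairs
#' @return data.frame of class \code{codon_tai_table} with columns
#'   \code{codon}, \code{aa}, \code{W}, \code{rank}, \code{class}.
#' @export
build_tai_table <- function(pool, s = wobble_penalties(),
                            code = standard_genetic_code()) {
  codons <- sense_codons(code)
  W <- vapply(codons, codon_weight, numeric(1), pool = pool, s = s,
              code = code)
  tab <- data.frame(codon = codons, aa = unname(code[codons]), W = unname(W),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aa, -tab$W, tab$codon), ]
  tab$rank <- stats::ave(seq_len(nrow(tab)), tab$aa,
                         FUN = seq_along)
  n_high <- stats::ave(tab$rank, tab$aa,
                       FUN = function(r) ceiling(length(r) / 2))
  tab$class <- ifelse(tab$rank <= n_high, "high", "low")
  tab <- tab[order(tab$codon), ]
  rownames(tab) <- NULL
  class(tab) <- c("codon_tai_table", "data.frame")
  tab
}

#' Normalized tAI weights (reporting transform)
#'
#' The conventional tAI normalization: divide W by the maximum over sense
#' codons, then replace zero weights by the geometric mean of the non-zero
#' normalized weights. This cannot change within-family order, so it is
#' offered only as a reporting transform; classification uses raw W.
#'
#' @param tai a [build_tai_table()] result.
#' @return The table with an added \code{w_norm} column.
#' @export
tai_normalize <- function(tai) {
  w <- tai$W / max(tai$W)
  gm <- exp(mean(log(w[w > 0])))
  w[w == 0] <- gm
  tai$w_norm <- w
  tai
}

#' Enumerate directed single-base synonymous codon pairs
#'
#' All ordered (from, to) pairs of sense codons that encode the same amino
#' acid and differ at exactly one position, with the tAI direction obtained
#' by comparing W: \code{tai_up} iff W(to) > W(from), \code{tai_down} iff
#' smaller, \code{tie} if equal. A single-base synonymous mutation
#' from -> to therefore carries the pair's direction.
#'
#' @param tai a [build_tai_table()] result.
#' @param code genetic code.
#' @return data.frame with columns \code{from}, \code{to}, \code{aa},
#'   \code{position} (1-3), \code{direction}, \code{delta_W}.
#' @export
enumerate_directed_pairs <- function(tai, code = standard_genetic_code()) {
  codons <- tai$codon
  W <- stats::setNames(tai$W, tai$codon)
  aa <- stats::setNames(tai$aa, tai$codon)
  bases <- c("A", "C", "G", "T")
  out <- vector("list", length(codons) * 9L)
  k <- 0L
  for (cd in codons) {
    for (p in 1:3) {
      for (b in bases) {
        if (substr(cd, p, p) == b) next
        alt <- cd
        substr(alt, p, p) <- b
        if (!alt %in% codons || aa[[alt]] != aa[[cd]]) next
        k <- k + 1L
        dw <- W[[alt]] - W[[cd]]
        out[[k]] <- data.frame(
          from = cd, to = alt, aa = aa[[cd]], position = p,
          direction = if (dw > 0) "tai_up" else if (dw < 0) "tai_down"
                      else "tie",
          delta_W = dw, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Census of realized wobble anticodon:codon pairs
#'
#' Counts, for each wobble pairing geometry, how many sense codons have
#' their wobble decoder present in the pool, and reports pool anticodons
#' that decode no sense codon.
#'
#' @inheritParams build_tai_table
#' @return list with \code{counts} (named integer: \code{G:U}, \code{I:C},
#'   \code{I:A}, \code{U:G}) and \code{unused_anticodons}.
#' @export
wobble_pair_census <- function(pool, code = standard_genetic_code()) {
  counts <- c("G:U" = 0L, "I:C" = 0L, "I:A" = 0L, "U:G" = 0L)
  used <- character(0)
  for (cd in sense_codons(code)) {
    dp <- decoding_pairs(cd, pool, code = code)
    used <- c(used, dp$anticodon)
    wob <- dp$pairing[dp$pairing != "WC"]
    if (length(wob)) counts[wob] <- counts[wob] + 1L
  }
  list(counts = counts,
       unused_anticodons = setdiff(names(pool), unique(used)))
}
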