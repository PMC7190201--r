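test_that("GtRNAdb-dialect parsing counts anticodons and flags bad records", {
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  pool <- parse_trna_pool(empty)
  expect_equal(length(pool), 0L)
  expect_equal(total_loci(pool), 0L)

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(
    ">Zm_tRNA-Ala-AGC-1-1 (chr1:1-73) 73 bp", "GCGGAUUU",
    ">Zm_tRNA-Ala-AGC-2-1 (chr2:1-73) 73 bp", "GCGGAUUU",
    ">Zm_tRNA-Gly-GGC-1-1 (chr3:1-73) 73 bp", "GCGGAUUU",
    ">Zm_tRNA-Und-NNN-1-1 (chr4:1-73) 73 bp", "GCGGAUUU",
    ">some_totally_malformed_header", "GCGGAUUU"), fa)
  expect_warning(pool <- parse_trna_pool(fa), "skipped")
  expect_equal(as.integer(pool[c("AGC", "GGC")]), c(2L, 1L))
  expect_equal(length(pool), 2L)
  expect_equal(attr(pool, "n_undetermined"), 1L)
  expect_equal(attr(pool, "n_skipped"), 1L)
})

test_that("a written GtRNAdb FASTA round-trips through the parser", {
  fa <- withr::local_tempfile(fileext = ".fa")
  write_gtrnadb_fasta(maize_pool(), fa, species = "SynZm")
  pool <- parse_trna_pool(fa)
  expect_equal(length(pool), 52L)
  expect_equal(total_loci(pool), 1198L)
  expect_equal(as.integer(pool), as.integer(maize_pool()))
})

test_that("decoding pairs follow the wobble geometry and pool membership", {
  pool <- toy_pool()
  dp <- decoding_pairs("GCT", pool)
  expect_equal(dp$anticodon, c("AGC", "GGC"))
  expect_equal(dp$s, c(0, 0.7861))
  dp2 <- decoding_pairs("GCC", pool)
  expect_equal(dp2$anticodon[order(dp2$s)], c("GGC", "AGC"))
  expect_equal(sort(dp2$s), c(0, 0.4659))
  expect_equal(nrow(decoding_pairs("GCT", trna_pool())), 0L)
  expect_error(decoding_pairs("TAA", pool), "stop codon")
})

test_that("codon weights match hand arithmetic and degenerate cases", {
  pool <- toy_pool()
  expect_equal(codon_weight("GCT", pool), 2 * 1 + 3 * (1 - 0.7861))
  expect_equal(codon_weight("GCT", pool), 2.6417)
  expect_equal(codon_weight("GCC", pool), 3 * 1 + 2 * (1 - 0.4659))
  expect_equal(codon_weight("GCC", pool), 4.0682)
  expect_equal(codon_weight("TTT", trna_pool()), 0)
  expect_error(codon_weight("TGA", pool), "stop")
})

test_that("tAI table splits 61 sense codons into 32 high and 29 low", {
  for (pool in list(maize_pool(), toy_pool(), random_pool(5), trna_pool())) {
    tab <- build_tai_table(pool)
    expect_equal(nrow(tab), 61L)
    expect_equal(sum(tab$class == "high"), 32L)
    expect_equal(sum(tab$class == "low"), 29L)
    # ranks are a permutation within every family
    for (fam in split(tab, tab$aa))
      expect_setequal(fam$rank, seq_len(nrow(fam)))
  }
  # Ile rounds towards high; Met and Trp are high
  tab <- build_tai_table(maize_pool())
  ile <- tab[tab$aa == "I", ]
  expect_equal(sum(ile$class == "high"), 2L)
  expect_equal(tab$class[tab$aa == "M"], "high")
  expect_equal(tab$class[tab$aa == "W"], "high")
})

test_that("ranks, classes and pair directions are tGCN-scale invariant", {
  pool <- maize_pool()
  scaled <- trna_pool(stats::setNames(as.integer(pool) * 10L, names(pool)))
  t1 <- build_tai_table(pool); t2 <- build_tai_table(scaled)
  expect_equal(t1$rank, t2$rank)
  expect_equal(t1$class, t2$class)
  expect_equal(enumerate_directed_pairs(t1)$direction,
               enumerate_directed_pairs(t2)$direction)
  expect_equal(t2$W, t1$W * 10)
})

test_that("within-family order follows W (toy pool: GCC above GCT)", {
  tab <- build_tai_table(toy_pool())
  expect_lt(tab$rank[tab$codon == "GCC"], tab$rank[tab$codon == "GCT"])
})

test_that("directed pair enumeration matches a brute-force oracle", {
  # independent oracle: loop the genetic code directly
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  n_ordered <- 0L
  for (cd in sense) for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (substr(cd, p, p) == b) next
    alt <- cd; substr(alt, p, p) <- b
    if (code[[alt]] != "*" && code[[alt]] == code[[cd]])
      n_ordered <- n_ordered + 1L
  }
  pairs <- enumerate_directed_pairs(build_tai_table(maize_pool()))
  expect_equal(nrow(pairs), n_ordered)
  expect_equal(nrow(pairs), 134L)  # 67 unordered single-base synonymous pairs
  # every from/to differs at exactly the stated position, same amino acid
  for (i in sample(nrow(pairs), 20)) {
    d <- which(strsplit(pairs$from[i], "")[[1]] !=
                 strsplit(pairs$to[i], "")[[1]])
    expect_equal(d, pairs$position[i])
  }
})

test_that("pair directions are antisymmetric and ties symmetric", {
  pairs <- enumerate_directed_pairs(build_tai_table(maize_pool()))
  key <- paste(pairs$from, pairs$to)
  rev_dir <- pairs$direction[match(paste(pairs$to, pairs$from), key)]
  expect_equal(rev_dir[pairs$direction == "tai_up"],
               rep("tai_down", sum(pairs$direction == "tai_up")))
  expect_equal(rev_dir[pairs$direction == "tie"],
               rep("tie", sum(pairs$direction == "tie")))
  # with the maize-like pool the GCG -> GCC Ala change increases tAI
  expect_equal(pairs$direction[pairs$from == "GCG" & pairs$to == "GCC"],
               "tai_up")
})

test_that("wobble census equals a brute-force count over the pool", {
  wob34 <- c(T = "G", C = "A", A = "A", G = "T")
  lab <- c(T = "G:U", C = "I:C", A = "I:A", G = "U:G")
  for (pool in list(maize_pool(), random_pool(3), toy_pool())) {
    expected <- c("G:U" = 0L, "I:C" = 0L, "I:A" = 0L, "U:G" = 0L)
    for (cd in sense_codons()) {
      wc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cd)))
      third <- substr(cd, 3, 3)
      wa <- paste0(wob34[[third]], substr(wc, 2, 3))
      if (wa %in% names(pool))
        expected[lab[[third]]] <- expected[lab[[third]]] + 1L
    }
    expect_equal(wobble_pair_census(pool)$counts, expected)
  }
})

test_that("normalized tAI preserves within-family order", {
  tab <- tai_normalize(build_tai_table(maize_pool()))
  expect_true(all(tab$w_norm > 0 & tab$w_norm <= 1))
  for (fam in split(tab, tab$aa))
    expect_equal(order(-fam$W, fam$codon), order(-fam$w_norm, fam$codon))
})
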