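test_that("frequency band bounds are inclusive and high freqs dominate", {
  expect_equal(names(frequency_band_filter(c(C = 0.99, T = 0.01))), "C")
  expect_equal(sort(names(frequency_band_filter(c(C = 0.6, T = 0.4)))),
               c("C", "T"))
  expect_equal(sort(names(frequency_band_filter(c(C = 0.98, T = 0.02)))),
               c("C", "T"))                       # boundary retained
  expect_equal(names(frequency_band_filter(c(C = 0.985, T = 0.015))), "C")
  expect_error(frequency_band_filter(c(A = 0.7, C = 0.7)), "sum")
  expect_error(frequency_band_filter(c(A = 1.2)), "\\[0, 1\\]")
})

test_that("MAF is the second most abundant allele", {
  expect_equal(minor_allele_frequency(c(A = 0.7, G = 0.3)), 0.3)
  expect_equal(minor_allele_frequency(c(A = 0.5, G = 0.5)), 0.5)
  expect_equal(minor_allele_frequency(c(A = 0.6, G = 0.3, T = 0.1)), 0.3)
  expect_error(minor_allele_frequency(c(A = 1)), "monomorphic")
  # bi-allelic renormalization keeps MAF <= 0.5
  expect_lte(minor_allele_frequency(c(A = 0.55, G = 0.35)), 0.5)
})

test_that("polarization implements the two-outgroup criteria", {
  p <- polarize_site(c(C = 0.7, T = 0.3), "C", "C")
  expect_equal(p$status, "polymorphic")
  expect_equal(p$ancestral, "C")
  expect_equal(p$derived, "T")
  expect_equal(p$daf, 0.3)
  expect_equal(p$maf, 0.3)

  f <- polarize_site(c(T = 1), "C", "C")
  expect_equal(f$status, "fixed")
  expect_equal(f$ancestral, "C")
  expect_equal(f$derived, "T")

  expect_equal(polarize_site(c(C = 0.7, T = 0.3), "C", "G")$reason,
               "outgroup_mismatch")
  expect_equal(polarize_site(c(C = 0.7, T = 0.3), "-", "C")$reason,
               "outgroup_gap")
  expect_equal(polarize_site(c(C = 0.7, T = 0.3), "N", "N")$reason,
               "outgroup_gap")
  expect_equal(polarize_site(c(C = 0.7, T = 0.3), "C", "C",
                             out1_poly = TRUE)$reason,
               "outgroup_polymorphic")
  expect_equal(polarize_site(c(C = 1), "C", "C")$reason, "invariant")
  expect_equal(polarize_site(c(A = 0.4, G = 0.3, T = 0.3), "A", "A")$reason,
               "multiallelic")
  expect_equal(polarize_site(c(A = 0.6, G = 0.4), "C", "C")$reason,
               "ancestral_not_segregating")
})

test_that("DAF and ancestral frequency are complementary after renormalization", {
  set.seed(31)
  for (i in 1:50) {
    d <- runif(1, 0.03, 0.97)
    extra <- runif(1, 0, 0.015)            # sub-band noise allele
    freqs <- c(C = (1 - d) * (1 - extra), T = d * (1 - extra), G = extra)
    p <- polarize_site(freqs, "C", "C")
    expect_equal(p$status, "polymorphic")
    expect_equal(p$daf + (1 - p$daf), 1)
    expect_lte(p$maf, 0.5 + 1e-12)
    expect_equal(p$maf, min(p$daf, 1 - p$daf), tolerance = 1e-12)
    # symmetric in outgroup order
    expect_identical(p, polarize_site(freqs, "C", "C"))
  }
})

make_triple <- function(focal, out1, out2, id = "g") {
  aligned_triple(focal, out1, out2, gene_id = id)
}

test_that("walking an identical triple yields no fixed or polymorphic calls", {
  s <- "ATGGCGGCCTTACCGTAA"
  res <- walk_alignment(make_triple(s, s, s))
  expect_equal(nrow(res), nchar(s))
  expect_equal(sum(res$status != "excluded"), 0L)
  expect_equal(unique(res$reason), "invariant")
})

test_that("planted fixed and polymorphic sites are recovered exactly", {
  set.seed(8)
  anc <- random_test_cds(60)
  n <- nchar(anc)
  pos_all <- sample(4:(n - 3), 10)
  fix_pos <- sort(pos_all[1:5]); poly_pos <- sort(pos_all[6:8])
  dis_pos <- sort(pos_all[9:10])
  focal <- anc
  for (p in fix_pos) {
    b <- substr(focal, p, p)
    substr(focal, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }
  out1 <- out2 <- anc
  for (p in dis_pos) {
    b <- substr(out1, p, p)
    substr(out1, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }
  vars <- do.call(rbind, lapply(poly_pos, function(p) {
    ref <- substr(focal, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    d <- runif(1, 0.1, 0.9)
    f <- c(A = 0, C = 0, G = 0, T = 0)
    f[ref] <- 1 - d; f[alt] <- d
    data.frame(gene_id = "g", cds_pos = p, freq_A = f[["A"]],
               freq_C = f[["C"]], freq_G = f[["G"]], freq_T = f[["T"]])
  }))
  res <- walk_alignment(make_triple(focal, out1, out2), vars)
  expect_setequal(res$cds_pos[res$status == "fixed"], fix_pos)
  expect_setequal(res$cds_pos[res$status == "polymorphic"], poly_pos)
  expect_setequal(res$cds_pos[res$reason %in% "outgroup_mismatch"], dis_pos)
  # ancestral equals the shared outgroup base at every non-excluded site
  ok <- res$status != "excluded"
  expect_equal(res$ancestral[ok], res$out1[ok])
})

test_that("focal gap columns carry no CDS position", {
  res <- walk_alignment(make_triple("AT-GC", "ATTGC", "ATTGC"))
  expect_equal(nrow(res), 4L)
  expect_equal(res$aligned_col, c(1L, 2L, 4L, 5L))
  expect_error(
    walk_alignment(make_triple("ATGC", "ATGC", "ATGC"),
                   data.frame(gene_id = "g", cds_pos = 99, freq_A = 1,
                              freq_C = 0, freq_G = 0, freq_T = 0)),
    "column-map")
})

test_that("every walked site has exactly one status and reasons partition", {
  ds <- simulate_dataset(small_config(3))
  tr <- ds$triples[[1]]
  res <- walk_alignment(tr, ds$variants,
                        outgroup_poly_pos = ds$outgroup_poly$cds_pos[
                          ds$outgroup_poly$gene_id == tr$gene_id])
  expect_equal(nrow(res), sum(strsplit(tr$focal, "")[[1]] != "-"))
  expect_true(all(res$status %in% c("polymorphic", "fixed", "excluded")))
  expect_true(all(!is.na(res$reason[res$status == "excluded"])))
  expect_true(all(is.na(res$reason[res$status != "excluded"])))
})
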