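# independent two-sided Fisher oracle: enumerate the hypergeometric support
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("fixed:polymorphic contrast reports ratios, OR and Fisher p", {
  r <- fixed_polymorphic_contrast(10, 10, 10, 10)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  r2 <- fixed_polymorphic_contrast(8, 0, 3, 5)
  expect_true(r2$zero_polymorphic)
  expect_true(is.na(r2$ratio_up))
  expect_error(fixed_polymorphic_contrast(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  set.seed(17)
  for (i in 1:60) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    r <- fixed_polymorphic_contrast(tab[1, 1], tab[1, 2], tab[2, 1],
                                    tab[2, 2])
    expect_equal(r$p_value,
                 fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
})

# independent exact Wilcoxon oracle: enumerate all label assignments
wilcox_perm_oracle <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  sums <- apply(combs, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(sums <= obs + 1e-9), mean(sums >= obs - 1e-9)))
}

test_that("exact rank-sum p equals full label-permutation enumeration", {
  set.seed(23)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:5, n1, replace = TRUE) / 5   # heavy ties on purpose
    y <- sample(0:5, n2, replace = TRUE) / 5
    got <- rank_sum_test(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, wilcox_perm_oracle(x, y), tolerance = 1e-12)
  }
  # no-ties exact path also agrees with R's exact Wilcoxon distribution
  for (i in 1:10) {
    x <- runif(5); y <- runif(6)
    expect_equal(rank_sum_test(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("spectrum comparison summarizes classes and skips empty ones", {
  v <- runif(30)
  s <- spectrum_compare(list(a = v, b = v), metric = "DAF")
  expect_equal(s$tests$p_value, 1)
  expect_equal(s$summary$median[1], s$summary$median[2])

  s2 <- spectrum_compare(list(a = v, b = numeric(0)))
  expect_equal(nrow(s2$tests), 0L)
  expect_equal(s2$skipped, "a vs b")
})

test_that("a Beta selection shift is detected at study scale", {
  set.seed(2026)
  up <- rbeta(2000, 3, 3)
  down <- rbeta(2000, 2, 4)
  s <- spectrum_compare(list(syn_up = up, syn_down = down))
  expect_gt(s$summary$median[s$summary$class == "syn_up"],
            s$summary$median[s$summary$class == "syn_down"])
  expect_lt(s$tests$p_value, 0.05)
})

test_that("stratified contrasts recover a planted stratum interaction", {
  set.seed(5)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      rpkm = c(rep(100, 10), rep(1, 10)),
                      gc = runif(20))
  mk <- function(gids, n, a_up, b_down) {
    do.call(rbind, lapply(gids, function(g)
      data.frame(gene_id = g,
                 tai_direction = rep(c("up", "down"), each = n),
                 daf = c(rbeta(n, a_up, 3), rbeta(n, 2, b_down)))))
  }
  sites <- rbind(mk(genes$gene_id[1:10], 50, 4.5, 6),   # wide gap stratum
                 mk(genes$gene_id[11:20], 50, 3, 3))    # no gap stratum
  r <- stratified_contrast(sites, genes, "rpkm")
  expect_gt(r$gap_high, r$gap_low)
  expect_gt(r$gap_difference, 0)

  same <- rbind(mk(genes$gene_id[1:10], 30, 3, 4),
                mk(genes$gene_id[11:20], 30, 3, 4))
  expect_error(stratified_contrast(same, transform(genes, rpkm = 1), "rpkm"),
               "degenerate")
})

test_that("GC-conservative subsets are defined by the allele pair", {
  sites <- data.frame(
    ancestral = c("A", "T", "C", "G", "A", "C"),
    derived   = c("T", "A", "G", "C", "G", "T"),
    tai_direction = c("up", "down", "up", "down", "up", "down"),
    daf = c(0.4, 0.3, 0.5, 0.2, 0.6, 0.1))
  g <- gbgc_control_subsets(sites)
  expect_equal(g$n_AT, 2L)   # A->T and T->A only
  expect_equal(g$n_CG, 2L)   # C->G and G->C only
  set.seed(9)
  big <- data.frame(
    ancestral = rep(c("A", "T"), each = 300),
    derived = rep(c("T", "A"), each = 300),
    tai_direction = rep(c("up", "down"), 300),
    daf = NA_real_)
  big$daf[big$tai_direction == "up"] <- rbeta(300, 3, 3)
  big$daf[big$tai_direction == "down"] <- rbeta(300, 2, 4)
  g2 <- gbgc_control_subsets(big)
  su <- g2$AT$summary
  expect_gt(su$median[su$class == "syn_up"],
            su$median[su$class == "syn_down"])
  expect_lt(g2$AT$tests$p_value, 0.05)
})

test_that("nearest-neighbour labels and distances match the toy layout", {
  sites <- data.frame(gene_id = "g", cds_pos = c(10L, 100L, 110L),
                      tai_direction = c("up", "down", "up"),
                      daf = c(0.5, 0.4, 0.3))
  r <- nearest_neighbor_classes(sites)
  lab <- r$labels[order(r$labels$cds_pos), ]
  expect_equal(lab$nn_class,
               c("up_near_down", "down_near_up", "up_near_down"))
  expect_equal(lab$nn_distance, c(90L, 10L, 10L))
  expect_equal(r$per_gene$median_nn_distance, 10)

  single <- data.frame(gene_id = c("g1", "g2", "g2"),
                       cds_pos = c(5L, 7L, 20L),
                       tai_direction = c("up", "up", "down"),
                       daf = c(0.1, 0.2, 0.3))
  r2 <- nearest_neighbor_classes(single)
  expect_equal(r2$n_skipped_genes, 1L)
  expect_true(all(r2$labels$gene_id == "g2"))
})

test_that("distance ties break towards the upstream site", {
  sites <- data.frame(gene_id = "g", cds_pos = c(10L, 20L, 30L),
                      tai_direction = c("up", "down", "up"),
                      daf = c(0.5, 0.4, 0.3))
  r <- nearest_neighbor_classes(sites)
  mid <- r$labels[r$labels$cds_pos == 20L, ]
  expect_equal(mid$nn_class, "down_near_up")
  expect_equal(mid$nn_distance, 10L)     # picked position 10, the upstream tie
})

test_that("regression recovers exact coefficients in the noise-free case", {
  set.seed(4)
  d <- data.frame(delta_cai = runif(200, -1, 1),
                  delta_tai = runif(200, -1, 1),
                  gene_gc = runif(200))
  d$daf <- 0.2 + 0.5 * d$delta_cai + 0.3 * d$delta_tai + 0 * d$gene_gc
  r <- suppressWarnings(regress_frequency(d, "daf"))  # lm's perfect-fit note
  est <- stats::setNames(r$coefficients$estimate, r$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(est["delta_cai"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(est["delta_tai"]), 0.3, tolerance = 1e-10)
  expect_equal(unname(est["gene_gc"]), 0, tolerance = 1e-8)
  expect_equal(r$n, 200L)
})

test_that("constant predictors are flagged, not fatal", {
  d <- data.frame(delta_cai = runif(50), delta_tai = runif(50),
                  gene_gc = 0.5)
  d$daf <- 0.1 + 0.4 * d$delta_cai
  expect_warning(r <- regress_frequency(d, "daf"), "constant or aliased")
  expect_true("gene_gc" %in% r$flagged)
})

test_that("Spearman correlation matches the definitional rank formula", {
  x <- c(1, 3, 5, 7, 11)
  expect_equal(correlate(x, x * 2 + 1)$rho, 1)
  expect_equal(correlate(x, rev(x))$rho, -1)
  set.seed(6)
  a <- runif(15); b <- runif(15)          # continuous, no ties
  dsq <- sum((rank(a) - rank(b))^2)
  n <- length(a)
  expect_equal(correlate(a, b)$rho, 1 - 6 * dsq / (n * (n^2 - 1)),
               tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "constant")
})
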