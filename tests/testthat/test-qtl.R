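test_that("haplotype clustering recovers clean groups and flags degenerate input", {
  set.seed(71)
  K <- 5
  proto <- matrix(rbinom(K * 40, 1, 0.5), K)
  hap <- proto[rep(1:K, each = 8), ]
  bp <- seq(1e4, by = 2e4, length.out = 40)
  cl <- cluster_haplotypes(hap, bp, anchors = 20L, K = 5, window_bp = 2e6)[[1]]
  expect_equal(length(unique(cl$cluster)), 5L)
  tab <- table(cl$cluster, rep(1:K, each = 8))
  expect_true(all(apply(tab > 0, 1, sum) == 1))   # exact group recovery
  ## identical haplotypes: one cluster, flagged
  cl1 <- cluster_haplotypes(hap[rep(1, 12), ], bp, 20L, K = 5, window_bp = 2e6)[[1]]
  expect_equal(unique(cl1$cluster), 1L)
  expect_true(cl1$flagged)
})

sim_scan_setup <- function(n_sires = 80, n_pos = 12, K = 10, seed = 72) {
  set.seed(seed)
  fam <- rep(seq_len(n_sires / 2), each = 2)
  A <- diag(n_sires)
  for (f in unique(fam)) {
    rows <- which(fam == f)
    A[rows[1], rows[2]] <- A[rows[2], rows[1]] <- 0.25
  }
  clusters <- lapply(seq_len(n_pos), function(j)
    sample.int(K, 2 * n_sires, replace = TRUE))
  positions <- data.frame(chrom = 1, bp = seq_len(n_pos) * 1e6)
  list(fam = fam, A = A, clusters = clusters, positions = positions)
}

test_that("the scan statistic is invariant to cluster relabeling", {
  s <- sim_scan_setup()
  pheno <- data.frame(sire = paste0("s", 1:80), y = rnorm(80), n_sons = 10L)
  sc1 <- mixed_scan(pheno, s$clusters, s$positions, s$A)
  relab <- lapply(s$clusters, function(cl) {
    perm <- sample(max(cl))
    perm[cl]
  })
  sc2 <- mixed_scan(pheno, relab, s$positions, s$A)
  expect_equal(sc1$scan$lrt, sc2$scan$lrt, tolerance = 1e-8)
})

test_that("a single cluster reduces the scan to the null model", {
  s <- sim_scan_setup(n_pos = 4)
  one <- lapply(s$clusters, function(cl) rep(1L, length(cl)))
  pheno <- data.frame(sire = paste0("s", 1:80), y = rnorm(80), n_sons = 10L)
  sc <- mixed_scan(pheno, one, s$positions, diag(80))
  expect_true(all(abs(sc$scan$lrt) < 1e-6))
})

test_that("permutation thresholds order correctly and bound the null maxima", {
  s <- sim_scan_setup(n_pos = 8)
  set.seed(73)
  pheno <- data.frame(sire = paste0("s", 1:80), y = rnorm(80), n_sons = 10L)
  sc <- mixed_scan(pheno, s$clusters, s$positions, s$A)
  sc <- permutation_thresholds(sc, pheno, s$clusters, s$A, s$fam,
                               n_perm = 200, seed = 5)
  expect_lte(sc$thresholds[["suggestive"]], sc$thresholds[["significant"]])
  expect_gte(mean(sc$perm_max <= sc$thresholds[["significant"]]), 0.95)
  ## thresholds monotone in the requested percentile by construction
  expect_equal(unname(quantile(sc$perm_max, 0.95)),
               sc$thresholds[["significant"]])
})

test_that("a strong cluster effect is detected and localized", {
  set.seed(74)
  s <- sim_scan_setup(n_sires = 100, n_pos = 10, K = 8)
  causal <- 6L
  carrier <- (s$clusters[[causal]][seq(1, 200, 2)] <= 2) |
             (s$clusters[[causal]][seq(2, 200, 2)] <= 2)
  ## neighbouring position in LD with the causal clusters
  s$clusters[[causal + 1L]] <- s$clusters[[causal]]
  y <- 0.8 * carrier + rnorm(100, 0, 0.5)
  pheno <- data.frame(sire = paste0("s", 1:100), y = y, n_sons = 10L)
  sc <- mixed_scan(pheno, s$clusters, s$positions, s$A)
  sc <- permutation_thresholds(sc, pheno, s$clusters, s$A, s$fam,
                               n_perm = 200, seed = 6)
  pk <- which.max(sc$scan$lrt)
  expect_true(pk %in% c(causal, causal + 1L))
  expect_gt(max(sc$scan$lrt), sc$thresholds[["significant"]])
})

test_that("the cis dosage ANOVA is calibrated under exchangeable phenotypes", {
  set.seed(75)
  n_sires <- 60; m <- 12
  ps <- replicate(300, {
    pair <- t(replicate(n_sires, sample.int(10, 2)))
    y <- matrix(rnorm(n_sires * m), n_sires)   # iid: no sire structure
    a <- bovrec:::cis_anova(pair, rowSums(y), sum(y^2), rep(m, n_sires))
    a$p
  })
  ks <- ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})
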