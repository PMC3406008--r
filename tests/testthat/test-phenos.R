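test_that("GHU is the fraction of crossover mass in hot windows", {
  ev <- data.frame(sire = c("s1", "s1", "s2"), son = c("a", "b", "c"),
                   chrom = 1, left_bp = c(1e5, 5e5, 1e5),
                   right_bp = c(2e5, 6e5, 2e5))
  ## no hot windows: GHU 0
  none <- ghu_phenotype(ev, data.frame(chrom = integer(0), start = numeric(0),
                                       end = numeric(0)))
  expect_true(all(none$ghu == 0))
  ## all intervals inside hot windows: GHU 1
  hot <- data.frame(chrom = 1, start = 1, end = 1e6)
  all1 <- ghu_phenotype(ev, hot)
  expect_equal(all1$ghu, c(1, 1), tolerance = 1e-9)
  ## half-overlap arithmetic
  half <- ghu_phenotype(data.frame(sire = "s", son = "x", chrom = 1,
                                   left_bp = 1e5, right_bp = 3e5),
                        data.frame(chrom = 1, start = 2e5 + 1, end = 4e5))
  expect_equal(half$ghu, 0.5, tolerance = 1e-9)
})

test_that("repeatability is rank correlation over shared sires", {
  a <- data.frame(sire = paste0("s", 1:40), y = rnorm(40))
  expect_equal(repeatability(a, a)$rho, 1)
  set.seed(51)
  n <- 400
  a2 <- data.frame(sire = paste0("s", 1:n), y = rnorm(n))
  b2 <- data.frame(sire = paste0("s", 1:n), y = rnorm(n))
  expect_lt(abs(repeatability(a2, b2)$rho), 2 / sqrt(n))
})

test_that("split-half repeatability matches the simulated sire variance share", {
  ## sire variance : within-measurement noise tuned for expected rho ~ 0.58
  set.seed(52)
  n <- 120
  u <- rnorm(n)
  frac <- 0.58
  a <- data.frame(sire = paste0("s", 1:n),
                  y = sqrt(frac) * u + sqrt(1 - frac) * rnorm(n))
  b <- data.frame(sire = paste0("s", 1:n),
                  y = sqrt(frac) * u + sqrt(1 - frac) * rnorm(n))
  r <- repeatability(a, b)
  expect_gt(r$rho, 0.45); expect_lt(r$rho, 0.70)
})

test_that("kinship from the pedigree follows the tabular method", {
  ped <- data.frame(id = c("gi", "a", "b", "x", "y"),
                    gen = c("GI", "GII", "GII", "GIII", "GIII"),
                    sire = c(NA, "gi", "gi", "a", "a"))
  A <- kinship_matrix(ped)
  expect_equal(unname(diag(A)), rep(1, 5))
  expect_equal(A["a", "b"], 0.25)      # paternal half sibs
  expect_equal(A["x", "a"], 0.5)       # sire-son
  expect_equal(A["x", "y"], 0.25)
  expect_equal(A["x", "b"], 0.125)     # nephew via half-sib sires
})

test_that("REML matches the closed-form ANOVA solution on balanced data", {
  set.seed(53)
  k <- 30; m <- 2
  y <- rnorm(m * k, rep(rnorm(m, 0, 1.5), each = k), 1)
  sire <- rep(c("s1", "s2"), each = k)
  msb <- k * sum((tapply(y, sire, mean) - mean(y))^2) / (m - 1)
  msw <- sum((y - ave(y, sire))^2) / (m * k - m)
  ped <- data.frame(id = c("s1", "s2"), gen = "GII", sire = NA_character_)
  fit <- heritability(data.frame(sire = sire, y = y), ped, model = "gamete")
  sire_var <- fit$sigma2[["additive"]] + fit$sigma2[["permanent"]]
  expect_lt(abs(sire_var - (msb - msw) / k), 1e-6)
  expect_lt(abs(fit$sigma2[["residual"]] - msw), 1e-6)
})

test_that("pure-noise phenotypes give near-zero heritability", {
  ## noise means per-gamete measurement error: sire means vary as 1/n_sons
  cfg <- sim_config(n_grandsires = 250, seed = 54)
  ped <- simulate_pedigree(cfg)
  sires <- ped$id[ped$gen == "GII"]
  n_sons <- as.integer(table(ped$sire[ped$gen == "GIII"])[sires])
  set.seed(55)
  pheno <- data.frame(sire = sires, y = rnorm(length(sires)) / sqrt(n_sons),
                      n_sons = n_sons)
  fit <- heritability(pheno, ped, model = "sire_mean")
  expect_lt(fit$h2, 0.05)
})

test_that("sire-mean and gamete models agree on shared synthetic data", {
  ## family sizes vary so the sire-mean model can separate additive variance
  ## from the 1/n_sons residual trend
  set.seed(56)
  cfg <- sim_config(n_grandsires = 220, sons_per_GI_mean = 2,
                    sons_per_GII_mean = 3, seed = 56)
  ped <- simulate_pedigree(cfg)
  sires <- ped$id[ped$gen == "GII"][1:400]
  n_s <- length(sires)
  m_s <- sample(2:6, n_s, replace = TRUE)
  A <- kinship_matrix(ped, sires)
  a <- as.numeric(t(chol(A)) %*% rnorm(n_s)) * sqrt(0.3)
  y_g <- rep(a, m_s) + rnorm(sum(m_s), 0, sqrt(0.7))
  f2 <- heritability(data.frame(sire = rep(sires, m_s), y = y_g), ped,
                     model = "gamete")
  means <- tapply(y_g, factor(rep(sires, m_s), levels = sires), mean)
  f1 <- heritability(data.frame(sire = sires, y = as.numeric(means),
                                n_sons = m_s), ped, model = "sire_mean")
  expect_lt(abs(f1$h2 - f2$h2), 0.05)
  expect_lt(abs(f2$h2 - 0.3), 0.1)
})

test_that("family-size bias calibration shrinks with family size under error", {
  cfg <- sim_config(n_grandsires = 10, sons_per_GI_mean = 1,
                    sons_per_GII_mean = 45, n_chrom = 1,
                    chrom_lengths_bp = 2e7, chrom_lengths_cM = 30,
                    n_snps_per_chrom = 700, genotype_error_rate = 0.015,
                    hot_fraction = 0, n_anc = 20,
                    family_size_dispersion = c(5, 80), seed = 58)
  d <- simulate_dataset(cfg)
  expect_error(family_size_correction(d$geno, d$pedigree, d$map,
                                      min_family_size = 100),
               "families")
  ct <- family_size_correction(d$geno, d$pedigree, d$map, max_n = 8L,
                               n_rep = 12L, min_family_size = 30L,
                               n_families = 10L, seed = 2)
  expect_true(is.na(ct$delta[1]))           # phase undefined with one son
  expect_gt(ct$delta[3], ct$delta[8])       # bias shrinks with family size
  expect_gt(ct$delta[3], 0)                 # small families mis-estimate GRR
  expect_lt(abs(ct$delta[8]), abs(ct$delta[3]))
  ## corrected GRR subtracts the bias for small families only
  det <- detect_crossovers(d$geno, d$pedigree, d$map)
  g <- grr_phenotype(det, correction = ct)
  expect_equal(g$grr, g$grr_raw)            # all calibration families are large
})
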