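make_family <- function(h1, n_sons_per_hap = 3L) {
  ## sire heterozygous everywhere; sons homozygous (dam matches paternal allele)
  h2 <- 1L - h1
  M <- length(h1)
  sire <- rep(1L, M)
  sons <- rbind(matrix(rep(2L * h1, n_sons_per_hap), ncol = M, byrow = TRUE),
                matrix(rep(2L * h2, n_sons_per_hap), ncol = M, byrow = TRUE))
  rownames(sons) <- paste0("son", seq_len(nrow(sons)))
  list(sire = sire, sons = sons, pos = seq(1e5, by = 1e5, length.out = M))
}

test_that("phasing requires two sons and recovers haplotypes without recombination", {
  h1 <- rep(c(0L, 1L), 10)
  f <- make_family(h1)
  expect_error(phase_sire(f$sire, f$sons[1, , drop = FALSE], f$pos), "2 genotyped sons")
  ph <- phase_sire(f$sire, f$sons, f$pos)
  agree <- mean(ph$hap1 == h1)
  expect_true(agree == 1 || agree == 0)   # up to a global flip
  expect_true(all(ph$conf == 1))
  ## no heterozygous site: empty phase
  ph0 <- phase_sire(rep(0L, 20), f$sons, f$pos)
  expect_length(ph0$sites, 0L)
})

test_that("origin assignment labels transmitted haplotypes and flags inconsistencies", {
  h1 <- rep(c(0L, 1L), 10)
  f <- make_family(h1)
  ph <- phase_sire(f$sire, f$sons, f$pos)
  tr <- assign_origin(f$sons[1, ], f$sire, ph, f$pos)
  expect_true(length(unique(tr$label[!is.na(tr$label)])) == 1L)
  ## single recombinant son: two homogeneous label blocks
  rec <- c(2L * h1[1:10], 2L * (1 - h1)[11:20])
  tr2 <- assign_origin(rec, f$sire, ph, f$pos)
  r <- rle(tr2$label[!is.na(tr2$label)])
  expect_equal(length(r$lengths), 2L)
  ev <- call_crossovers(tr2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$left_bp, f$pos[10])
  expect_equal(ev$right_bp, f$pos[11])
  ## all sites dam-ambiguous (son heterozygous everywhere): empty track
  tr3 <- assign_origin(rep(1L, 20), f$sire, ph, f$pos)
  expect_true(all(is.na(tr3$label)))
  expect_equal(nrow(call_crossovers(tr3)), 0L)
  ## Mendelian inconsistency at a sire-homozygous site is counted
  sire_hom <- rep(0L, 20)
  tr4 <- assign_origin(rep(2L, 20), sire_hom, phase_sire(sire_hom, f$sons, f$pos), f$pos)
  expect_equal(tr4$n_mendel_err, 20L)
})

test_that("phase links are >=99.5% correct on error-free simulated families", {
  d <- dense_sim()
  tot <- 0; bad <- 0
  for (ci in 1:2) for (s in d$det$sires) {
    ph <- d$det$phases[[paste(s, ci)]]
    true1 <- d$haplotypes[[ci]][paste0(s, ".1"), ph$sites]
    ok <- !is.na(ph$hap1)
    agr <- mean(ph$hap1[ok] == true1[ok])
    bad <- bad + round((1 - max(agr, 1 - agr)) * sum(ok))
    tot <- tot + sum(ok)
  }
  expect_gt(1 - bad / tot, 0.995)
})

test_that("detected events equal label switches before cleanup", {
  d <- small_sim()
  det0 <- detect_crossovers(d$geno, d$pedigree, d$map, clean = FALSE)
  switches <- sum(vapply(det0$tracks, function(tr) {
    lab <- tr$label[!is.na(tr$label)]
    if (length(lab) < 2L) 0L else sum(diff(lab) != 0L)
  }, 1L))
  expect_equal(nrow(det0$events), switches)
})

test_that("double-crossover filter applies the three-informative-marker rule", {
  base <- data.frame(sire = "s", son = "x", chrom = 1,
                     left_idx = c(10L, 14L), right_idx = c(11L, 15L),
                     left_bp = c(1e6, 2e6), right_bp = c(1.1e6, 2.1e6),
                     left_rank = c(10L, 14L), right_rank = c(11L, 15L))
  ## inner resolved sites: 14 - 11 + 1 = 4 -> kept
  keep <- clean_crossovers(base, c(s = 50), 3e7)
  expect_equal(nrow(keep$events), 2L)
  ## shift second event closer: inner = 2 -> both removed
  base2 <- base
  base2$left_rank[2] <- 12L
  drop <- clean_crossovers(base2, c(s = 50), 3e7)
  expect_equal(nrow(drop$events), 0L)
  expect_true(all(drop$removed$reason == "double_co"))
  ## boundary: inner exactly 3 -> retained
  base3 <- base
  base3$left_rank[2] <- 13L
  expect_equal(nrow(clean_crossovers(base3, c(s = 50), 3e7)$events), 2L)
})

test_that("an injected sire phase flip is removed by the 2-Mb window filter", {
  d <- small_sim()
  det <- d$det
  s <- names(which.max(det$n_sons))
  ci <- 1
  ph <- det$phases[[paste(s, ci)]]
  flip_bp <- 2e7
  m <- d$map[d$map$chrom == ci, ]
  flip <- m$bp[ph$sites] >= flip_bp
  ph$hap1[flip] <- 1L - ph$hap1[flip]
  sons <- d$pedigree$id[!is.na(d$pedigree$sire) & d$pedigree$sire == s &
                          d$pedigree$gen == "GIII"]
  evs <- list()
  for (son in sons) {
    tr <- assign_origin(d$geno[[ci]][son, ], d$geno[[ci]][s, ], ph, m$bp)
    e <- call_crossovers(tr)
    if (nrow(e)) { e$sire <- s; e$son <- son; e$chrom <- ci
      evs[[length(evs) + 1L]] <- e }
  }
  ev <- do.call(rbind, evs)
  mid <- (ev$left_bp + ev$right_bp) / 2
  expect_gt(sum(abs(mid - flip_bp) < 1e6), 0.7 * length(sons))  # flip artifact
  cl <- clean_crossovers(ev, det$n_sons, 4e7)
  kept_mid <- (cl$events$left_bp + cl$events$right_bp) / 2
  expect_equal(sum(abs(kept_mid - flip_bp) < 5e5), 0L)
  expect_true("sire_window" %in% cl$removed$reason)
})

test_that("cleanup removes more events when genotyping error increases", {
  mk <- function(err) {
    cfg <- sim_config(n_grandsires = 5, sons_per_GI_mean = 2,
                      sons_per_GII_mean = 12, n_chrom = 1,
                      chrom_lengths_bp = 2e7, chrom_lengths_cM = 20,
                      n_snps_per_chrom = 700, genotype_error_rate = err,
                      hot_fraction = 0, seed = 55)
    d <- simulate_dataset(cfg)
    detect_crossovers(d$geno, d$pedigree, d$map)
  }
  expect_gt(nrow(mk(0.02)$removed), nrow(mk(0)$removed))
})
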