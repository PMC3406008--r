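test_that("overlap weighting distributes each crossover's unit mass", {
  w <- genome_windows(c(3e5), 60000)
  expect_equal(nrow(w), 5L)
  ## interval wholly inside one window: full unit mass
  ev <- data.frame(chrom = 1, left_bp = 70000, right_bp = 90000)
  rr <- window_rr(ev, w, 10)$raw_rr
  expect_equal(rr[2], 1 / 10)
  expect_equal(sum(rr) * 10, 1)
  ## 100-kb interval overlapping a window by 30 kb contributes 0.3/T
  ev2 <- data.frame(chrom = 1, left_bp = 90000, right_bp = 190000)
  rr2 <- window_rr(ev2, w, 10)$raw_rr
  expect_equal(rr2[2], 0.3 / 10)
  expect_equal(rr2[3], 0.6 / 10)
  expect_equal(rr2[4], 0.1 / 10)
})

test_that("conservation: window masses sum to the crossover count", {
  d <- small_sim()
  w <- genome_windows(c(4e7, 3e7), 60000)
  rr <- window_rr(d$det$events, w, d$det$n_gametes)
  expect_equal(sum(rr$raw_rr) * d$det$n_gametes, nrow(d$det$events),
               tolerance = 1e-8)
})

test_that("study-scale geometry reproduces the ~0.00062 mean window rate", {
  ## 25.7 CO per gamete over a 2.512-Gb genome in 60-kb windows
  set.seed(41)
  lens <- round(seq(161e6, 42e6, length.out = 29) /
                  sum(seq(161e6, 42e6, length.out = 29)) * 2.512e9)
  w <- genome_windows(lens, 60000)
  T <- 40
  n_co <- rpois(29 * T, 25.7 * lens / sum(lens))
  ev <- do.call(rbind, lapply(seq_along(n_co), function(k) {
    ci <- (k - 1) %% 29 + 1
    if (n_co[k] == 0) return(NULL)
    mid <- runif(n_co[k], 1e5, lens[ci] - 1e5)
    data.frame(chrom = ci, left_bp = mid - 5e4, right_bp = mid + 5e4)
  }))
  rr <- window_rr(ev, w, T)
  expect_equal(mean(rr$raw_rr), 0.00062, tolerance = 0.03)
})

test_that("window classification flags by +-2.5 SD and is symmetric", {
  r <- data.frame(chrom = 1, width = 6e4, raw_rr = runif(100, 0, 1e-3),
                  z = rep(0, 100))
  cl <- classify_windows(r)
  expect_equal(sum(cl$rates$flag != "regular"), 0L)
  expect_equal(cl$summary$frac_genome_hot, 0)
  r$z <- rnorm(100, 0, 2)
  a <- classify_windows(r)
  r2 <- r; r2$z <- -r$z
  b <- classify_windows(r2)
  expect_equal(sum(a$rates$flag == "hot"), sum(b$rates$flag == "cold"))
  expect_equal(sum(a$rates$flag == "cold"), sum(b$rates$flag == "hot"))
})

test_that("jungles and deserts are maximal gap-tolerant runs", {
  r <- data.frame(chrom = 1, start = (0:3) * 6e4 + 1, end = (1:4) * 6e4,
                  flag = c("hot", "hot", "regular", "hot"))
  j1 <- jungles_deserts(r, max_gap = 1)
  expect_equal(nrow(j1), 1L)
  expect_equal(j1$n_windows, 4L)
  j0 <- jungles_deserts(r, max_gap = 0)
  expect_equal(nrow(j0), 2L)
  expect_equal(nrow(jungles_deserts(transform(r, flag = "regular"))), 0L)
})

test_that("an elevated window is detected as hot against the uniform null", {
  cfg <- sim_config(n_grandsires = 5, sons_per_GI_mean = 2,
                    sons_per_GII_mean = 28, n_chrom = 1,
                    chrom_lengths_bp = 2e7, chrom_lengths_cM = 30,
                    n_snps_per_chrom = 900, genotype_error_rate = 0,
                    hot_fraction = 0.034, hot_intensity = 6,
                    window_bp = 6e5, n_anc = 20,
                    family_size_dispersion = c(5, 40), seed = 61)
  d <- simulate_dataset(cfg)
  det <- detect_crossovers(d$geno, d$pedigree, d$map)
  expect_warning(
    wr <- normalize_rr(det, d$geno, d$pedigree, d$map, chrom_lengths_bp = 2e7,
                       n_sim = 25, window_bp = 6e5, seed = 4),
    "n_sim")
  hot_true <- d$truth$hot_windows[d$truth$hot_windows$hot, ]
  zin <- wr$z[wr$start %in% hot_true$start]
  expect_gt(max(zin), 2.5)
  expect_true(any(wr$flag[wr$start %in% hot_true$start] == "hot"))
  ## BED and crossover TSV writers round-trip through plain text
  bed <- withr::local_tempfile(fileext = ".bed")
  write_windows_bed(wr, bed)
  back <- read.table(bed, sep = "\t")
  expect_equal(nrow(back), nrow(wr))
  expect_equal(back$V2, wr$start - 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_co_tsv(det$events, tsv)
  ev2 <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(ev2), nrow(det$events))
  expect_equal(ev2$left_bp, det$events$left_bp)
})
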