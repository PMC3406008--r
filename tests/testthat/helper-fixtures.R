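# fixtures are built lazily once per test run and shared across files

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## small error-free two-chromosome dataset with moderate families
small_sim <- function() fixture("small", function() {
  cfg <- sim_config(n_grandsires = 6, sons_per_GI_mean = 2,
                    sons_per_GII_mean = 14, n_chrom = 2,
                    chrom_lengths_bp = c(4e7, 3e7), chrom_lengths_cM = c(40, 30),
                    n_snps_per_chrom = 1500, genotype_error_rate = 0,
                    hot_fraction = 0, n_anc = 20,
                    family_size_dispersion = c(5, 20), seed = 101)
  d <- simulate_dataset(cfg)
  d$det <- detect_crossovers(d$geno, d$pedigree, d$map)
  d
})

## dense-marker large-family dataset: the high-sensitivity detection regime
## (~100-son families, where the sire-window artifact filter essentially
## never fires on chance coincidences)
dense_sim <- function() fixture("dense", function() {
  cfg <- sim_config(n_grandsires = 3, sons_per_GI_mean = 2,
                    sons_per_GII_mean = 100, n_chrom = 2,
                    chrom_lengths_bp = c(6e7, 5e7), chrom_lengths_cM = c(60, 50),
                    n_snps_per_chrom = 4000, genotype_error_rate = 0,
                    hot_fraction = 0, n_anc = 30,
                    family_size_dispersion = c(5, 150), seed = 202)
  d <- simulate_dataset(cfg)
  d$det <- detect_crossovers(d$geno, d$pedigree, d$map)
  d
})

## sensitivity of detection against the generator's truth records
co_sensitivity <- function(d, det = d$det) {
  tc <- d$truth$crossovers
  hit <- 0L
  for (i in seq_len(nrow(tc))) {
    e <- det$events[det$events$son == tc$son[i] & det$events$chrom == tc$chrom[i], ]
    if (any(e$left_bp <= tc$bp[i] & e$right_bp >= tc$bp[i])) hit <- hit + 1L
  }
  hit / nrow(tc)
}

## interference observation list from simulated chain segments (truth-level)
chain_obs <- function(nu, length_cM, n, seed = 1) {
  set.seed(seed)
  cs <- bovrec:::chain_segments(nu, length_cM, n)
  first_of <- cumsum(c(0L, cs$counts))
  obs <- list(counts = tabulate(cs$counts + 1L, nbins = max(cs$counts, 3L) + 1L))
  obs$sco <- cs$within[first_of[which(cs$counts == 1L)] + 1L]
  i2 <- first_of[which(cs$counts == 2L)]
  obs$dco <- cs$within[i2 + 2L] - cs$within[i2 + 1L]
  i3 <- first_of[which(cs$counts == 3L)]
  obs$tco <- c(cs$within[i3 + 2L] - cs$within[i3 + 1L],
               cs$within[i3 + 3L] - cs$within[i3 + 2L])
  obs
}

## phenotype data.frame aligned with a detection's sire order
aligned_pheno <- function(det, ph) {
  pd <- ph[match(det$sires, ph$sire), ]
  pd$n_sons <- as.integer(det$n_sons)
  pd
}
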