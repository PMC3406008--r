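#' Configuration for the synthetic half-sib recombination dataset
#'
#' Bundles and validates all knobs of the generator.  Defaults emulate the
#' cattle-style study design: 429 grandsire (GI) families with on average 1.84
#' genotyped GII sons each, 12.85 genotyped GIII sons per GII sire, 29
#' acrocentric autosomes totalling ~2.51 Gb and ~25.7 Morgans (~1 cM/Mb),
#' ~50K SNPs, gamma-renewal chiasma placement with shape \code{nu} = 2.6, 13%
#' of 60-kb windows hot with intensity tuned so ~34% of crossovers fall in
#' them, and a small per-call genotyping error rate.
#'
#' @param n_grandsires number of GI founders.
#' @param sons_per_GI_mean,sons_per_GII_mean mean family sizes (zero-truncated
#'   negative binomial; see \code{\link{simulate_pedigree}}).
#' @param n_chrom number of autosomes.
#' @param chrom_lengths_bp,chrom_lengths_cM physical and genetic lengths; must
#'   have length \code{n_chrom}.
#' @param n_snps_per_chrom markers per chromosome.
#' @param nu gamma shape (>= 1) of the chiasma renewal process.
#' @param obligate_chiasma if TRUE, meioses with zero chiasmata on a
#'   chromosome are redrawn (at least one chiasma per bivalent).
#' @param hot_fraction fraction of 60-kb windows designated hot (in [0, 1)).
#' @param hot_intensity per-bp recombination-rate multiplier of hot windows.
#'   The default 3.45 makes the expected fraction of crossovers in hot windows
#'   0.13 * 3.45 / (0.13 * 3.45 + 0.87) = 0.34 at \code{hot_fraction} 0.13.
#' @param genotype_error_rate per-genotype-call error probability (one allele
#'   of the call flipped).
#' @param qtl_spec list of QTL, each a list with fields \code{type} (one of
#'   "GRR", "GHU", "cisLRR"), \code{chrom}, \code{bp} (snapped to the nearest
#'   marker), \code{effect} (multiplier applied to carrier sires), optional
#'   \code{freq} (carrier-allele frequency in the ancestral pool, default
#'   0.25) and, for cisLRR, optional \code{width_bp} (default 8e5).
#' @param n_anc size of the ancestral haplotype pool from which all founder
#'   and dam haplotypes are drawn as mosaics.
#' @param anc_segment_bp mean ancestral mosaic segment length (exponential).
#' @param family_size_dispersion negative-binomial size parameters
#'   (GII, GIII) controlling family-size spread.
#' @param window_bp window width used for the hot/cold rate structure.
#' @param seed integer seed; every stochastic step of the generator derives
#'   its stream from it.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_grandsires = 429,
                       sons_per_GI_mean = 1.84,
                       sons_per_GII_mean = 12.85,
                       n_chrom = 29,
                       chrom_lengths_bp = NULL,
                       chrom_lengths_cM = NULL,
                       n_snps_per_chrom = 1750,
                       nu = 2.6,
                       obligate_chiasma = FALSE,
                       hot_fraction = 0.13,
                       hot_intensity = 3.45,
                       genotype_error_rate = 0.002,
                       qtl_spec = list(),
                       n_anc = 20,
                       anc_segment_bp = 2.5e6,
                       family_size_dispersion = c(2, 0.9),
                       window_bp = 60000,
                       seed = 1L) {
  if (is.null(chrom_lengths_bp)) {
    ## bovine-like declining autosome sizes, total ~2.512 Gb
    raw <- seq(161e6, 42e6, length.out = n_chrom)
    chrom_lengths_bp <- round(raw / sum(raw) * 2.512e9)
  }
  if (is.null(chrom_lengths_cM)) {
    ## ~25.7 M male map, allocated proportionally to physical length
    chrom_lengths_cM <- 2570 * chrom_lengths_bp / sum(chrom_lengths_bp)
  }
  cfg <- list(n_grandsires = n_grandsires,
              sons_per_GI_mean = sons_per_GI_mean,
              sons_per_GII_mean = sons_per_GII_mean,
              n_chrom = n_chrom,
              chrom_lengths_bp = chrom_lengths_bp,
              chrom_lengths_cM = chrom_lengths_cM,
              n_snps_per_chrom = n_snps_per_chrom,
              nu = nu,
              obligate_chiasma = isTRUE(obligate_chiasma),
              hot_fraction = hot_fraction,
              hot_intensity = hot_intensity,
              genotype_error_rate = genotype_error_rate,
              qtl_spec = qtl_spec,
              n_anc = n_anc,
              anc_segment_bp = anc_segment_bp,
              family_size_dispersion = family_size_dispersion,
              window_bp = window_bp,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_grandsires < 1) stop("n_grandsires must be >= 1", call. = FALSE)
    if (sons_per_GI_mean <= 0 || sons_per_GII_mean <= 0)
      stop("family-size means must be > 0", call. = FALSE)
    if (length(chrom_lengths_bp) != n_chrom || length(chrom_lengths_cM) != n_chrom)
      stop("chromosome length vectors must have length n_chrom", call. = FALSE)
    if (any(chrom_lengths_bp <= 0) || any(chrom_lengths_cM <= 0))
      stop("chromosome lengths must be positive", call. = FALSE)
    if (nu < 1) stop("nu must be >= 1", call. = FALSE)
    if (hot_fraction < 0 || hot_fraction >= 1)
      stop("hot_fraction must be in [0, 1)", call. = FALSE)
    if (genotype_error_rate < 0 || genotype_error_rate > 1)
      stop("genotype_error_rate must be a probability", call. = FALSE)
    for (q in qtl_spec) {
      if (!q$type %in% c("GRR", "GHU", "cisLRR"))
        stop("qtl_spec type must be GRR, GHU or cisLRR", call. = FALSE)
      if (is.null(q$chrom) || q$chrom < 1 || q$chrom > n_chrom)
        stop("qtl_spec chromosome outside the simulated genome", call. = FALSE)
      if (is.null(q$bp) || q$bp < 1 || q$bp > chrom_lengths_bp[q$chrom])
        stop("qtl_spec position outside the chromosome", call. = FALSE)
      if (is.null(q$effect) || q$effect <= 0)
        stop("qtl_spec effect must be a positive multiplier", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic half-sib recombination design\n")
  cat(sprintf("  %d GI families; mean %.2f GII sons, %.2f GIII sons\n",
              x$n_grandsires, x$sons_per_GI_mean, x$sons_per_GII_mean))
  cat(sprintf("  %d chromosomes, %.2f Gb, %.1f M; %d SNPs/chrom\n",
              x$n_chrom, sum(x$chrom_lengths_bp) / 1e9,
              sum(x$chrom_lengths_cM) / 100, x$n_snps_per_chrom))
  cat(sprintf("  nu = %.2f, hot fraction %.2f (x%.2f), error rate %.4f, %d QTL\n",
              x$nu, x$hot_fraction, x$hot_intensity,
              x$genotype_error_rate, length(x$qtl_spec)))
  invisible(x)
}
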