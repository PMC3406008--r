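#' Simulate Mendelian transmission of a gamete given crossover positions
#'
#' Builds the transmitted allele sequence by alternating between the parent's
#' two haplotypes exactly at the crossover positions.  The starting haplotype
#' is drawn with probability 0.5 unless given.
#'
#' @param parent_haplotypes 2 x M integer matrix of phased parental alleles.
#' @param positions_bp marker positions (bp), increasing.
#' @param co_bp sorted crossover positions in bp (may be empty).
#' @param start optional starting haplotype (1 or 2).
#' @return integer vector of M transmitted alleles.
#' @export
simulate_gamete <- function(parent_haplotypes, positions_bp, co_bp,
                            start = NULL) {
  stopifnot(is.matrix(parent_haplotypes), nrow(parent_haplotypes) == 2L,
            ncol(parent_haplotypes) == length(positions_bp))
  if (length(co_bp) && is.unsorted(co_bp))
    stop("crossover positions must be sorted", call. = FALSE)
  if (length(co_bp) && min(co_bp) < 0)
    stop("crossover positions outside the marker map", call. = FALSE)
  if (is.null(start)) start <- sample.int(2L, 1L)
  n_before <- findInterval(positions_bp, co_bp)
  hap <- (start - 1L + n_before) %% 2L + 1L
  parent_haplotypes[cbind(hap, seq_along(positions_bp))]
}

## ---------------------------------------------------------------------------
## genome scaffold: windows, hot structure, markers, ancestral haplotype pool

build_genome <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "genome"))
  chroms <- vector("list", cfg$n_chrom)
  for (c in seq_len(cfg$n_chrom)) {
    L_bp <- cfg$chrom_lengths_bp[c]
    L_cM <- cfg$chrom_lengths_cM[c]
    bnd <- unique(c(seq(0, L_bp, by = cfg$window_bp), L_bp))
    n_win <- length(bnd) - 1L
    w <- diff(bnd)
    hot <- rep(FALSE, n_win)
    n_hot <- floor(cfg$hot_fraction * n_win)
    if (n_hot > 0) hot[sample.int(n_win, n_hot)] <- TRUE
    dens <- ifelse(hot, cfg$hot_intensity, 1)
    pos <- sort(sample.int(L_bp - 1L, cfg$n_snps_per_chrom))
    pool <- matrix(stats::rbinom(cfg$n_anc * cfg$n_snps_per_chrom, 1L, 0.5),
                   nrow = cfg$n_anc)
    chroms[[c]] <- list(chrom = c, L_bp = L_bp, L_cM = L_cM,
                        win_bnd = bnd, win_width = w, hot = hot,
                        base_dens = dens, pos = pos, pool = pool)
  }
  ## snap QTL to nearest marker and fix ancestral carrier alleles at that site
  qtl <- list()
  for (k in seq_along(cfg$qtl_spec)) {
    q <- cfg$qtl_spec[[k]]
    g <- chroms[[q$chrom]]
    mk <- which.min(abs(g$pos - q$bp))
    freq <- q$freq %||% 0.25
    n_car <- max(1L, round(freq * cfg$n_anc))
    carrier_anc <- sample.int(cfg$n_anc, n_car)
    al <- integer(cfg$n_anc); al[carrier_anc] <- 1L
    chroms[[q$chrom]]$pool[, mk] <- al
    q$marker <- mk
    q$bp <- g$pos[mk]
    q$freq <- freq
    q$width_bp <- q$width_bp %||% 8e5
    qtl[[k]] <- q
  }
  list(chroms = chroms, qtl = qtl)
}

## anchors of the population-average genetic map for one chromosome
base_anchors <- function(g) {
  cM <- g$L_cM * cumsum(g$base_dens * g$win_width) / sum(g$base_dens * g$win_width)
  list(bp = g$win_bnd, cM = c(0, cM))
}

## mosaic of the ancestral pool; exponential segment lengths
mosaic_haplotype <- function(g, seg_mean_bp) {
  n_seg_max <- ceiling(g$L_bp / seg_mean_bp * 2) + 10
  brk <- cumsum(stats::rexp(n_seg_max, 1 / seg_mean_bp))
  brk <- brk[brk < g$L_bp]
  anc <- sample.int(nrow(g$pool), length(brk) + 1L, replace = TRUE)
  idx <- findInterval(g$pos, brk) + 1L
  g$pool[cbind(anc[idx], seq_along(g$pos))]
}

## sire-specific per-window recombination density given QTL multipliers
sire_density <- function(g, ghu_mult, cis_mult, cis_win) {
  dens <- g$base_dens
  if (ghu_mult != 1) {
    dens[g$hot] <- dens[g$hot] * ghu_mult
    dens <- dens * (g$L_cM / sum(dens * g$win_width)) *
      (sum(g$base_dens * g$win_width) / g$L_cM)  # renormalize to L_cM
  }
  if (cis_mult != 1 && length(cis_win)) dens[cis_win] <- dens[cis_win] * cis_mult
  dens
}

## one meiosis: chiasma chain on the sire-specific map, thinning, bp mapping
sim_meiosis <- function(g, dens, grr_mult, nu, obligate) {
  cm_tot <- sum(dens * g$win_width) / sum(g$base_dens * g$win_width) * g$L_cM
  L <- cm_tot * grr_mult
  repeat {
    ch <- simulate_chiasma_chain(nu, L, burn_cM = 600)
    if (!obligate || length(ch) >= 1L) break
  }
  co <- thin_to_crossovers(ch)
  anchors <- list(bp = g$win_bnd,
                  cM = c(0, cumsum(dens * g$win_width) / sum(dens * g$win_width) * cm_tot))
  co_scaled <- co / grr_mult       # back to the sire map scale [0, cm_tot]
  bp <- if (length(co)) cm_to_bp(co_scaled, anchors$bp, anchors$cM) else numeric(0)
  list(n_chiasma = length(ch), co_bp = bp)
}

#' Simulate a complete synthetic half-sib recombination dataset
#'
#' End-to-end generator: pedigree, marker map with hot/cold rate structure,
#' phased founder genomes drawn as mosaics of a shared ancestral haplotype
#' pool, meioses with gamma-renewal (interfering) chiasma placement, QTL
#' effects on carrier GII sires, unphased genotypes with genotyping error, and
#' full truth records for evaluation.
#'
#' QTL act on GII sires carrying at least one copy of the causal allele:
#' a GRR QTL multiplies the sire's chiasma density genome-wide, a GHU QTL
#' rescales the intensity of hot windows (renormalized so the sire's map
#' length is unchanged), and a cisLRR QTL multiplies the local rate in one
#' window (not renormalized).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return an object of class \code{recomb_sim}: list with \code{config},
#'   \code{pedigree}, \code{map} (chrom, id, bp, cM), \code{geno} (one
#'   integer matrix per chromosome, individuals x markers, 0/1/2), and
#'   \code{truth} (crossovers, meioses, hot windows, sire effects, QTL).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- simulate_pedigree(cfg)
  gen <- build_genome(cfg)
  chroms <- gen$chroms
  set.seed(derive_seed(cfg$seed, "haplotypes"))

  gi <- ped$id[ped$gen == "GI"]
  gii <- ped$id[ped$gen == "GII"]
  giii <- ped$id[ped$gen == "GIII"]
  ids <- c(gi, gii, giii)
  sire_of <- stats::setNames(ped$sire, ped$id)

  ## per chromosome: haplotype matrices (2 rows per individual)
  hap <- lapply(chroms, function(g)
    matrix(NA_integer_, nrow = 2L * length(ids), ncol = length(g$pos),
           dimnames = list(paste(rep(ids, each = 2), 1:2, sep = "."), NULL)))
  hrow <- function(id, k) match(id, ids) * 2L - 2L + k

  for (ci in seq_along(chroms)) {
    g <- chroms[[ci]]
    for (s in gi) {
      hap[[ci]][hrow(s, 1L), ] <- mosaic_haplotype(g, cfg$anc_segment_bp)
      hap[[ci]][hrow(s, 2L), ] <- mosaic_haplotype(g, cfg$anc_segment_bp)
    }
  }

  ## GII: paternal gamete from GI meiosis (population map, no QTL), dam mosaic
  set.seed(derive_seed(cfg$seed, "gii"))
  for (ci in seq_along(chroms)) {
    g <- chroms[[ci]]
    for (s in gii) {
      f <- sire_of[[s]]
      mei <- sim_meiosis(g, g$base_dens, 1, cfg$nu, cfg$obligate_chiasma)
      ph <- rbind(hap[[ci]][hrow(f, 1L), ], hap[[ci]][hrow(f, 2L), ])
      hap[[ci]][hrow(s, 1L), ] <- simulate_gamete(ph, g$pos, mei$co_bp)
      hap[[ci]][hrow(s, 2L), ] <- mosaic_haplotype(g, cfg$anc_segment_bp)
    }
  }

  ## carrier status and per-sire multipliers
  eff <- data.frame(sire = gii, grr_mult = 1, ghu_mult = 1, cis_mult = 1,
                    stringsAsFactors = FALSE)
  carrier_tab <- list()
  for (k in seq_along(gen$qtl)) {
    q <- gen$qtl[[k]]
    a1 <- hap[[q$chrom]][vapply(gii, hrow, 1L, k = 1L), q$marker]
    a2 <- hap[[q$chrom]][vapply(gii, hrow, 1L, k = 2L), q$marker]
    carrier <- (a1 + a2) >= 1L
    if (q$type == "GRR") eff$grr_mult[carrier] <- eff$grr_mult[carrier] * q$effect
    if (q$type == "GHU") eff$ghu_mult[carrier] <- eff$ghu_mult[carrier] * q$effect
    if (q$type == "cisLRR") eff$cis_mult[carrier] <- eff$cis_mult[carrier] * q$effect
    carrier_tab[[k]] <- data.frame(qtl = k, type = q$type, sire = gii,
                                   carrier = carrier, stringsAsFactors = FALSE)
  }

  ## GIII: paternal gamete from GII meiosis with QTL multipliers + dam mosaic
  set.seed(derive_seed(cfg$seed, "giii"))
  co_list <- list(); mei_list <- list()
  cis_by_chrom <- lapply(seq_along(chroms), function(ci) {
    hits <- integer(0)
    for (q in gen$qtl) if (q$type == "cisLRR" && q$chrom == ci) {
      g <- chroms[[ci]]
      lo <- q$bp - q$width_bp / 2; hi <- q$bp + q$width_bp / 2
      hits <- union(hits, which(g$win_bnd[-length(g$win_bnd)] < hi & g$win_bnd[-1] > lo))
    }
    hits
  })
  for (ci in seq_along(chroms)) {
    g <- chroms[[ci]]
    anch <- base_anchors(g)
    dens_cache <- list()
    for (s in gii) {
      e <- eff[eff$sire == s, ]
      key <- sprintf("%.6g_%.6g", e$ghu_mult, e$cis_mult)
      if (is.null(dens_cache[[key]]))
        dens_cache[[key]] <- sire_density(g, e$ghu_mult, e$cis_mult, cis_by_chrom[[ci]])
      dens <- dens_cache[[key]]
      sons <- ped$id[!is.na(ped$sire) & ped$sire == s & ped$gen == "GIII"]
      ph <- rbind(hap[[ci]][hrow(s, 1L), ], hap[[ci]][hrow(s, 2L), ])
      for (son in sons) {
        mei <- sim_meiosis(g, dens, e$grr_mult, cfg$nu, cfg$obligate_chiasma)
        hap[[ci]][hrow(son, 1L), ] <- simulate_gamete(ph, g$pos, mei$co_bp)
        hap[[ci]][hrow(son, 2L), ] <- mosaic_haplotype(g, cfg$anc_segment_bp)
        n_co <- length(mei$co_bp)
        mei_list[[length(mei_list) + 1L]] <-
          data.frame(sire = s, son = son, chrom = ci,
                     n_chiasma = mei$n_chiasma, n_co = n_co,
                     stringsAsFactors = FALSE)
        if (n_co)
          co_list[[length(co_list) + 1L]] <-
            data.frame(sire = s, son = son, chrom = ci, bp = mei$co_bp,
                       cM = bp_to_cm(mei$co_bp, anch$bp, anch$cM),
                       stringsAsFactors = FALSE)
      }
    }
  }

  ## genotypes with error
  set.seed(derive_seed(cfg$seed, "errors"))
  geno <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    h <- hap[[ci]]
    gmat <- h[seq(1, nrow(h), 2), , drop = FALSE] + h[seq(2, nrow(h), 2), , drop = FALSE]
    rownames(gmat) <- ids
    if (cfg$genotype_error_rate > 0) {
      err <- which(stats::runif(length(gmat)) < cfg$genotype_error_rate)
      if (length(err)) {
        old <- gmat[err]
        gmat[err] <- ifelse(old == 1L, ifelse(stats::runif(length(err)) < 0.5, 0L, 2L),
                            1L)  # flip one allele of the call
      }
    }
    storage.mode(gmat) <- "integer"
    geno[[ci]] <- gmat
  }

  map <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    g <- chroms[[ci]]
    anch <- base_anchors(g)
    data.frame(chrom = ci, id = sprintf("snp%d_%d", ci, seq_along(g$pos)),
               bp = g$pos, cM = bp_to_cm(g$pos, anch$bp, anch$cM),
               stringsAsFactors = FALSE)
  }))
  hot_windows <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    g <- chroms[[ci]]
    data.frame(chrom = ci, start = g$win_bnd[-length(g$win_bnd)] + 1,
               end = g$win_bnd[-1], hot = g$hot, stringsAsFactors = FALSE)
  }))
  qtl_truth <- if (length(gen$qtl))
    do.call(rbind, lapply(gen$qtl, function(q)
      data.frame(type = q$type, chrom = q$chrom, bp = q$bp, effect = q$effect,
                 freq = q$freq, stringsAsFactors = FALSE)))
  else NULL

  out <- list(config = cfg, pedigree = ped, map = map, geno = geno,
              haplotypes = hap, ids = ids,
              truth = list(
                crossovers = if (length(co_list)) do.call(rbind, co_list) else
                  data.frame(sire = character(), son = character(),
                             chrom = integer(), bp = numeric(), cM = numeric()),
                meioses = do.call(rbind, mei_list),
                hot_windows = hot_windows,
                sire_effects = merge_carriers(eff, carrier_tab),
                qtl = qtl_truth))
  class(out) <- "recomb_sim"
  out
}

merge_carriers <- function(eff, carrier_tab) {
  for (k in seq_along(carrier_tab)) {
    ct <- carrier_tab[[k]]
    eff[[paste0("carrier_", tolower(ct$type[1]), k)]] <- ct$carrier
  }
  eff
}

#' @export
print.recomb_sim <- function(x, ...) {
  ped <- x$pedigree
  cat("Synthetic half-sib recombination dataset\n")
  cat(sprintf("  %d GI / %d GII / %d GIII individuals; %d chromosomes, %d SNPs\n",
              sum(ped$gen == "GI"), sum(ped$gen == "GII"), sum(ped$gen == "GIII"),
              length(x$geno), nrow(x$map)))
  cat(sprintf("  %d true crossovers in %d gametes (%.2f per gamete genome-wide)\n",
              nrow(x$truth$crossovers),
              sum(ped$gen == "GIII"),
              nrow(x$truth$crossovers) / max(1, sum(ped$gen == "GIII"))))
  invisible(x)
}
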