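#' Tile the genome into windows
#'
#' Windows tile each chromosome from position 1 in steps of
#' \code{window_bp}; the final partial window is kept with its true width.
#' Coordinates are half-open \code{[start-1, end)} in 0-based terms, reported
#' 1-based inclusive.
#'
#' @param chrom_lengths_bp named or unnamed vector of chromosome lengths.
#' @param window_bp window width (default 60 kb).
#' @return data.frame \code{chrom}, \code{start}, \code{end}, \code{width}.
#' @export
genome_windows <- function(chrom_lengths_bp, window_bp = 60000) {
  chroms <- seq_along(chrom_lengths_bp)
  do.call(rbind, lapply(chroms, function(ci) {
    L <- chrom_lengths_bp[ci]
    s <- seq(0, L - 1, by = window_bp)
    e <- pmin(s + window_bp, L)
    data.frame(chrom = ci, start = s + 1, end = e, width = e - s)
  }))
}

#' Overlap-weighted window recombination rates
#'
#' The raw rate of a window is \eqn{(1/T) \sum_i o_i / x_i} over crossovers
#' whose bounding marker interval (size \eqn{x_i} bp) overlaps the window by
#' \eqn{o_i} bp: each crossover distributes one unit of mass across the
#' windows its interval spans, so the rate is a per-gamete recombination
#' probability.
#'
#' @param events crossover data.frame (\code{chrom}, \code{left_bp},
#'   \code{right_bp}).
#' @param windows from \code{\link{genome_windows}}.
#' @param n_gametes total number of analyzed gametes T.
#' @return \code{windows} with an added \code{raw_rr} column.
#' @export
window_rr <- function(events, windows, n_gametes) {
  stopifnot(n_gametes > 0)
  rr <- numeric(nrow(windows))
  off <- c(0, cumsum(tapply(windows$chrom, windows$chrom, length)))
  names(off) <- NULL
  chroms <- sort(unique(windows$chrom))
  for (k in seq_along(chroms)) {
    ci <- chroms[k]
    w <- windows[windows$chrom == ci, ]
    ev <- events[events$chrom == ci, ]
    if (!nrow(ev)) next
    wbp <- w$end[1] - w$start[1] + 1   # nominal width
    nwin <- nrow(w)
    x <- ev$right_bp - ev$left_bp
    x[x <= 0] <- 1
    j1 <- pmax(0L, pmin(floor(ev$left_bp / wbp), nwin - 1L))
    j2 <- pmax(0L, pmin(ceiling(ev$right_bp / wbp) - 1L, nwin - 1L))
    n_span <- j2 - j1 + 1L
    ei <- rep.int(seq_len(nrow(ev)), n_span)
    wi <- unlist(lapply(seq_len(nrow(ev)), function(i) j1[i]:j2[i])) + 1L
    lo <- pmax(ev$left_bp[ei], w$start[wi] - 1)
    hi <- pmin(ev$right_bp[ei], w$end[wi])
    o <- pmax(0, hi - lo)
    contrib <- o / x[ei]
    acc <- tapply(contrib, wi, sum)
    rr[off[k] + as.integer(names(acc))] <- as.numeric(acc)
  }
  windows$raw_rr <- rr / n_gametes
  windows
}

#' Normalize window rates against a uniform-crossover null
#'
#' For each null replicate, GIII genotypes are regenerated by dropping
#' crossovers uniformly (per sire and chromosome, Poisson with mean equal to
#' that sire's observed per-gamete count) on the sire's reconstructed
#' haplotypes while keeping each son's inferred maternal contribution intact;
#' the entire phasing and crossover-mapping pipeline is then rerun and window
#' rates recomputed.  The observed rate of each window is expressed in
#' standard deviations from its null mean, which normalizes for local marker
#' density and informativeness.
#'
#' @param det a \code{\link{detect_crossovers}} result on the real data.
#' @param geno,pedigree,map the dataset the detection was run on.
#' @param chrom_lengths_bp chromosome lengths (defaults to last marker).
#' @param n_sim number of null replicates (>= 30 recommended; fewer warns).
#' @param window_bp window width (default 60 kb).
#' @param z_threshold hot/cold threshold in SD units (default 2.5).
#' @param seed integer seed for the null simulations.
#' @return object of class \code{window_rates}: windows with \code{raw_rr},
#'   \code{null_mean}, \code{null_sd}, \code{z} and \code{flag} (hot, cold,
#'   regular).
#' @export
normalize_rr <- function(det, geno, pedigree, map, chrom_lengths_bp = NULL,
                         n_sim = 1000, window_bp = 60000, z_threshold = 2.5,
                         seed = 1L) {
  stopifnot(inherits(det, "co_detection"))
  if (n_sim < 30) warning("n_sim < 30 gives unstable null standard deviations")
  chroms <- sort(unique(map$chrom))
  if (is.null(chrom_lengths_bp))
    chrom_lengths_bp <- as.numeric(tapply(map$bp, map$chrom, max))
  windows <- genome_windows(chrom_lengths_bp, window_bp)
  obs <- window_rr(det$events, windows, det$n_gametes)

  sires <- det$sires
  sons_of <- split(pedigree$id[pedigree$gen == "GIII"],
                   pedigree$sire[pedigree$gen == "GIII"])
  freq <- lapply(chroms, function(ci) colMeans(geno[[ci]]) / 2)

  ## per-sire per-chromosome mean observed CO per gamete (cleaned events)
  lam <- matrix(0, length(sires), length(chroms), dimnames = list(sires, NULL))
  if (nrow(det$events)) {
    t_ev <- table(factor(det$events$sire, levels = sires),
                  factor(det$events$chrom, levels = chroms))
    lam <- t_ev / as.numeric(det$n_sons[sires])
  }

  ## inferred maternal haplotype and sire haplotypes, fixed across replicates
  mat_hap <- list(); sire_hap <- list()
  for (k in seq_along(chroms)) {
    ci <- chroms[k]
    m <- map[map$chrom == ci, ]; m <- m[order(m$bp), ]
    gm <- geno[[ci]]
    for (s in sires) {
      ph <- det$phases[[paste(s, ci)]]
      sg <- gm[s, ]
      hapA <- ifelse(sg == 1L, NA_integer_, sg %/% 2L)
      hapA[ph$sites] <- ph$hap1
      sire_hap[[paste(s, ci)]] <- hapA
      for (son in sons_of[[s]]) {
        tr <- det$tracks[[paste(son, ci)]]
        lab <- fill_nearest(tr$label)
        pat <- ifelse(sg == 1L, NA_integer_, sg %/% 2L)
        if (length(tr$sites))
          pat[tr$sites] <- ifelse(lab == 1L, ph$hap1, 1L - ph$hap1)
        mat <- gm[son, ] - pat
        mat[is.na(mat) | mat < 0L | mat > 1L] <- NA_integer_
        mat_hap[[paste(son, ci)]] <- mat
      }
    }
  }

  ## the null must match *detected* counts: dropped crossovers are themselves
  ## subject to the pipeline's detection loss, so a pilot phase estimates the
  ## drop-to-detect ratio and inflates the drop intensity accordingly
  set.seed(derive_seed(seed, "nullrr-pilot"))
  n_pilot <- min(10L, n_sim)
  pilot_drop <- 0; pilot_det <- 0
  for (r in seq_len(n_pilot)) {
    sim <- null_replicate(det, geno, pedigree, map, chroms, chrom_lengths_bp,
                          sires, sons_of, sire_hap, mat_hap, freq, lam, windows)
    pilot_drop <- pilot_drop + sim$n_drop
    pilot_det <- pilot_det + sim$n_det
  }
  if (pilot_det > 0) lam <- lam * pilot_drop / pilot_det

  set.seed(derive_seed(seed, "nullrr"))
  rr_sims <- matrix(NA_real_, nrow(windows), n_sim)
  for (r in seq_len(n_sim)) {
    sim <- null_replicate(det, geno, pedigree, map, chroms, chrom_lengths_bp,
                          sires, sons_of, sire_hap, mat_hap, freq, lam, windows)
    rr_sims[, r] <- sim$rr
  }
  mu <- rowMeans(rr_sims)
  sdv <- apply(rr_sims, 1, stats::sd)
  z <- ifelse(sdv > 0, (obs$raw_rr - mu) / sdv, 0)
  out <- obs
  out$null_mean <- mu
  out$null_sd <- sdv
  out$z <- z
  out$flag <- ifelse(z > z_threshold, "hot", ifelse(z < -z_threshold, "cold", "regular"))
  class(out) <- c("window_rates", "data.frame")
  attr(out, "n_sim") <- n_sim
  attr(out, "z_threshold") <- z_threshold
  out
}

## one uniform-CO null replicate: regenerate GIII genotypes, rerun detection
null_replicate <- function(det, geno, pedigree, map, chroms, chrom_lengths_bp,
                           sires, sons_of, sire_hap, mat_hap, freq, lam,
                           windows) {
  n_drop <- 0L
  sim_geno <- geno
  for (k in seq_along(chroms)) {
    ci <- chroms[k]
    m <- map[map$chrom == ci, ]; m <- m[order(m$bp), ]
    L <- chrom_lengths_bp[k]
    gm <- sim_geno[[ci]]
    fq <- freq[[k]]
    for (s in sires) {
      hapA <- sire_hap[[paste(s, ci)]]
      miss <- is.na(hapA)
      if (any(miss)) hapA[miss] <- stats::rbinom(sum(miss), 1L, 0.5)
      ph2 <- rbind(hapA, 1L - hapA)
      ph2[2, geno[[ci]][s, ] != 1L] <- hapA[geno[[ci]][s, ] != 1L]
      for (son in sons_of[[s]]) {
        nco <- stats::rpois(1, lam[s, k])
        n_drop <- n_drop + nco
        co <- sort(stats::runif(nco, 0, L))
        pat_new <- simulate_gamete(ph2, m$bp, co)
        mat <- mat_hap[[paste(son, ci)]]
        mna <- is.na(mat)
        if (any(mna)) mat[mna] <- stats::rbinom(sum(mna), 1L, fq[mna])
        gm[son, ] <- pat_new + mat
      }
    }
    sim_geno[[ci]] <- gm
  }
  det_r <- detect_crossovers(sim_geno, pedigree, map)
  list(rr = window_rr(det_r$events, windows, det_r$n_gametes)$raw_rr,
       n_drop = n_drop, n_det = nrow(det_r$events))
}

## carry nearest non-NA value (ties to the left)
fill_nearest <- function(v) {
  ok <- which(!is.na(v))
  if (!length(ok)) return(v)
  idx <- findInterval(seq_along(v), ok)
  left <- ok[pmax(idx, 1L)]
  right <- ok[pmin(idx + 1L, length(ok))]
  use_r <- idx == 0L | (idx < length(ok) & (seq_along(v) - left) > (right - seq_along(v)))
  v[ifelse(use_r, right, left)]
}

#' Flag hot and cold windows and summarize
#'
#' Hot windows exceed +\code{z_threshold} normalized rate, cold windows fall
#' below -\code{z_threshold} (genome-wide threshold).  Summaries report the
#' fraction of the genome flagged hot/cold and the fraction of crossover
#' mass (\eqn{\sum o_i/x_i}) in them.
#'
#' @param rates a \code{\link{normalize_rr}} result, or any data.frame with
#'   \code{width}, \code{raw_rr} and \code{z}.
#' @param z_threshold threshold in SD units (default 2.5).
#' @return list with \code{rates} (flags refreshed), \code{summary}
#'   (\code{frac_genome_hot}, \code{frac_co_hot}, \code{frac_genome_cold},
#'   \code{frac_co_cold}).
#' @export
classify_windows <- function(rates, z_threshold = 2.5) {
  rates$flag <- ifelse(rates$z > z_threshold, "hot",
                       ifelse(rates$z < -z_threshold, "cold", "regular"))
  tot_w <- sum(rates$width)
  tot_co <- sum(rates$raw_rr)
  s <- list(
    frac_genome_hot = sum(rates$width[rates$flag == "hot"]) / tot_w,
    frac_co_hot = if (tot_co > 0) sum(rates$raw_rr[rates$flag == "hot"]) / tot_co else 0,
    frac_genome_cold = sum(rates$width[rates$flag == "cold"]) / tot_w,
    frac_co_cold = if (tot_co > 0) sum(rates$raw_rr[rates$flag == "cold"]) / tot_co else 0)
  list(rates = rates, summary = s)
}

#' Cluster flagged windows into recombination jungles and deserts
#'
#' Maximal runs of same-flag windows, allowing up to \code{max_gap}
#' interleaved regular windows within a run.
#'
#' @param rates data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{flag}.
#' @param max_gap regular windows tolerated inside a run (default 1).
#' @return data.frame \code{chrom}, \code{start}, \code{end}, \code{type}
#'   (jungle/desert), \code{n_windows} (span), \code{n_flagged}.
#' @export
jungles_deserts <- function(rates, max_gap = 1L) {
  out <- list()
  for (ci in unique(rates$chrom)) {
    w <- rates[rates$chrom == ci, ]
    for (ty in c(hot = "jungle", cold = "desert")) {
      fl <- names(which(c(hot = "jungle", cold = "desert") == ty))
      idx <- which(w$flag == fl)
      if (!length(idx)) next
      grp <- cumsum(c(1, diff(idx) - 1 > max_gap))
      for (g in unique(grp)) {
        ii <- idx[grp == g]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ci, start = w$start[ii[1]], end = w$end[ii[length(ii)]],
          type = ty, n_windows = ii[length(ii)] - ii[1] + 1L,
          n_flagged = length(ii))
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = integer(0), start = numeric(0), end = numeric(0),
                      type = character(0), n_windows = integer(0),
                      n_flagged = integer(0)))
  do.call(rbind, out)
}
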