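#' Phase a GII sire from his half-sib offspring
#'
#' Reconstructs the sire's two haplotypes at his heterozygous sites by
#' linkage over the half-sib family.  A son resolves his paternal allele at a
#' sire-heterozygous site when his own genotype is homozygous (the dam
#' contribution is then unambiguous).  Sites are chained left to right: each
#' son carries forward the haplotype-origin state from his most recent
#' resolved site, and at every new site the sons vote on the phase assignment;
#' the majority wins and the margin is recorded as a per-site confidence.
#' Sons that recombine between two sites vote against the majority, so with a
#' handful of sons the vote is dominated by the non-recombinants.
#'
#' Haplotype labels have no external meaning; the reconstruction is defined
#' up to a global flip per chromosome.
#'
#' @param sire_geno integer vector of sire genotypes (0/1/2) for one
#'   chromosome.
#' @param sons_geno integer matrix (sons x markers) of offspring genotypes.
#' @param positions_bp marker positions in bp.
#' @return an object of class \code{sire_phase}: list with \code{sites}
#'   (marker indices of heterozygous sites), \code{hap1} (allele carried by
#'   haplotype 1 at each site; haplotype 2 is the complement; NA where no son
#'   informs the site), and \code{conf} (fraction of votes agreeing with the
#'   assignment).
#' @export
phase_sire <- function(sire_geno, sons_geno, positions_bp) {
  if (is.null(dim(sons_geno)) || nrow(sons_geno) < 2L)
    stop("phasing requires at least 2 genotyped sons", call. = FALSE)
  het <- which(sire_geno == 1L)
  if (length(het) == 0L)
    return(structure(list(sites = integer(0), hap1 = integer(0),
                          conf = numeric(0)), class = "sire_phase"))
  G <- sons_geno[, het, drop = FALSE]
  ## resolved paternal allele: son homozygous => paternal allele = allele
  R <- matrix(NA_integer_, nrow(G), ncol(G))
  R[G == 0L] <- 0L
  R[G == 2L] <- 1L
  n_sites <- ncol(R)
  h <- rep(NA_integer_, n_sites)
  conf <- rep(NA_real_, n_sites)
  origin <- rep(NA_integer_, nrow(R))  # XOR(paternal allele, h) at last resolved site
  started <- FALSE
  for (t in seq_len(n_sites)) {
    r <- R[, t]
    res <- !is.na(r)
    if (!any(res)) next
    if (!started) {
      h[t] <- 0L  # arbitrary global phase
      conf[t] <- 1
      origin[res] <- bitwXor(r[res], h[t])
      started <- TRUE
      next
    }
    voters <- res & !is.na(origin)
    nv <- sum(voters)
    if (nv > 0L) {
      votes <- bitwXor(r[voters], origin[voters])
      n1 <- sum(votes)
      if (n1 * 2L != nv) {       # ties and orphan sites stay unphased
        h[t] <- if (n1 * 2L > nv) 1L else 0L
        conf[t] <- max(n1, nv - n1) / nv
      }
    }
    if (!is.na(h[t])) origin[res] <- bitwXor(r[res], h[t])
  }
  structure(list(sites = het, hap1 = h, conf = conf), class = "sire_phase")
}

#' Assign haplotype origin along a son's paternal gamete
#'
#' At each phased sire-heterozygous site where the son's paternal allele is
#' deducible (son homozygous), labels the transmitting sire haplotype
#' (1 or 2); elsewhere the site is unresolved (NA).  Mendelian-inconsistent
#' calls at sire-homozygous sites are counted.
#'
#' @param son_geno integer vector of the son's genotypes for one chromosome.
#' @param sire_geno the sire's genotypes.
#' @param phase a \code{\link{phase_sire}} result.
#' @param positions_bp marker positions in bp.
#' @return an object of class \code{origin_track}: list with \code{sites}
#'   (marker indices), \code{bp}, \code{label} (1, 2 or NA) and
#'   \code{n_mendel_err}.
#' @export
assign_origin <- function(son_geno, sire_geno, phase, positions_bp) {
  stopifnot(inherits(phase, "sire_phase"))
  sites <- phase$sites
  lab <- rep(NA_integer_, length(sites))
  if (length(sites)) {
    g <- son_geno[sites]
    pat <- rep(NA_integer_, length(sites))
    pat[g == 0L] <- 0L
    pat[g == 2L] <- 1L
    known <- !is.na(pat) & !is.na(phase$hap1)
    lab[known] <- ifelse(pat[known] == phase$hap1[known], 1L, 2L)
  }
  hom <- which(sire_geno %in% c(0L, 2L))
  n_err <- sum(abs(son_geno[hom] - sire_geno[hom]) == 2L, na.rm = TRUE)
  structure(list(sites = sites, bp = positions_bp[sites], label = lab,
                 n_mendel_err = n_err), class = "origin_track")
}

#' Call crossovers as phase switches along an origin track
#'
#' One event per adjacent pair of resolved sites with differing haplotype
#' labels; unresolved sites are skipped and widen the bounding interval.
#'
#' @param track an \code{\link{assign_origin}} result.
#' @return data.frame with one row per crossover: \code{left_idx},
#'   \code{right_idx} (marker indices of the flanking resolved informative
#'   sites), \code{left_bp}, \code{right_bp}, and \code{left_rank},
#'   \code{right_rank} (ranks among the track's resolved sites, used by the
#'   double-crossover cleanup).
#' @export
call_crossovers <- function(track) {
  stopifnot(inherits(track, "origin_track"))
  res <- which(!is.na(track$label))
  empty <- data.frame(left_idx = integer(0), right_idx = integer(0),
                      left_bp = numeric(0), right_bp = numeric(0),
                      left_rank = integer(0), right_rank = integer(0))
  if (length(res) < 2L) return(empty)
  lab <- track$label[res]
  sw <- which(diff(lab) != 0L)
  if (!length(sw)) return(empty)
  data.frame(left_idx = track$sites[res[sw]],
             right_idx = track$sites[res[sw + 1L]],
             left_bp = track$bp[res[sw]],
             right_bp = track$bp[res[sw + 1L]],
             left_rank = sw, right_rank = sw + 1L)
}

#' Clean up called crossovers
#'
#' Applies the two artifact filters: (a) double crossovers whose inner
#' segment spans fewer than \code{min_inner} informative (resolved) markers
#' are attributed to genotyping errors and both events removed; (b) for each
#' sire and each 2-Mb window, the number of sons recombining in the window is
#' tested against Binomial(n_sons, \code{p0}) one-sided; windows significantly
#' above \code{p0} = 5\% are attributed to sire phasing errors and all of the
#' sire's crossovers in them removed.
#'
#' @param events data.frame of crossovers (columns \code{sire}, \code{son},
#'   \code{chrom}, \code{left_bp}, \code{right_bp}, \code{left_rank},
#'   \code{right_rank}).
#' @param n_sons named vector: number of genotyped sons per sire.
#' @param chrom_lengths_bp chromosome lengths in bp.
#' @param min_inner double-crossover filter threshold (default 3: inner
#'   segments with < 3 informative markers are removed).
#' @param window_bp width of the sire-rate filter windows (default 2 Mb).
#' @param p0,alpha binomial null rate and test level of the window filter.
#' @return list with \code{events} (kept), \code{removed} (with a
#'   \code{reason} column: "double_co" or "sire_window").
#' @export
clean_crossovers <- function(events, n_sons, chrom_lengths_bp,
                             min_inner = 3L, window_bp = 2e6,
                             p0 = 0.05, alpha = 0.05) {
  if (nrow(events) == 0L)
    return(list(events = events, removed = cbind(events[0, ], reason = character(0))))
  events <- events[order(events$sire, events$son, events$chrom, events$left_bp), ]
  drop_dco <- rep(FALSE, nrow(events))
  key <- paste(events$sire, events$son, events$chrom)
  idx <- split(seq_len(nrow(events)), key)
  for (ii in idx) {
    if (length(ii) < 2L) next
    for (k in seq_len(length(ii) - 1L)) {
      inner <- events$left_rank[ii[k + 1L]] - events$right_rank[ii[k]] + 1L
      if (inner < min_inner) drop_dco[ii[c(k, k + 1L)]] <- TRUE
    }
  }
  kept <- events[!drop_dco, , drop = FALSE]
  removed <- events[drop_dco, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "double_co"

  ## sire x 2-Mb window filter on the double-CO-cleaned events
  drop_win <- rep(FALSE, nrow(kept))
  if (nrow(kept)) {
    mid <- (kept$left_bp + kept$right_bp) / 2
    win <- floor(mid / window_bp)
    grp <- paste(kept$sire, kept$chrom, win)
    for (g in unique(grp)) {
      rows <- which(grp == g)
      s <- kept$sire[rows[1]]
      n <- n_sons[[s]]
      k_rec <- length(unique(kept$son[rows]))
      pval <- stats::pbinom(k_rec - 1L, n, p0, lower.tail = FALSE)
      if (pval < alpha) drop_win[rows] <- TRUE
    }
  }
  rem2 <- kept[drop_win, , drop = FALSE]
  if (nrow(rem2)) rem2$reason <- "sire_window"
  removed_all <- rbind(if (nrow(removed)) removed else NULL,
                       if (nrow(rem2)) rem2 else NULL)
  if (is.null(removed_all)) removed_all <- cbind(events[0, ], reason = character(0))
  list(events = kept[!drop_win, , drop = FALSE], removed = removed_all)
}

#' Detect crossovers across a whole dataset
#'
#' Driver for the phasing / origin / switch-calling / cleanup pipeline: for
#' every GII sire with at least two genotyped GIII sons, phases the sire from
#' his half-sib family, assigns haplotype origin along every son's paternal
#' gamete, calls crossovers as phase switches and applies the cleanup
#' filters.
#'
#' @param geno list (one per chromosome) of genotype matrices
#'   (individuals x markers, rownames = ids).
#' @param pedigree data.frame with \code{id}, \code{gen}, \code{sire}.
#' @param map data.frame with \code{chrom}, \code{id}, \code{bp}, \code{cM}.
#' @param min_inner,window_filter_bp,p0,alpha cleanup parameters, see
#'   \code{\link{clean_crossovers}}.
#' @param clean apply the cleanup filters (default TRUE).
#' @return an object of class \code{co_detection}: list with \code{events}
#'   (sire, son, chrom, left/right bp and marker indices), \code{removed},
#'   \code{phases} (per sire, per chromosome), \code{tracks} (per son, per
#'   chromosome origin labels), \code{n_sons}, \code{n_gametes},
#'   \code{n_mendel_err} and the map.
#' @export
detect_crossovers <- function(geno, pedigree, map, min_inner = 3L,
                              window_filter_bp = 2e6, p0 = 0.05,
                              alpha = 0.05, clean = TRUE) {
  chroms <- sort(unique(map$chrom))
  sires <- pedigree$id[pedigree$gen == "GII"]
  sons_of <- split(pedigree$id[pedigree$gen == "GIII"],
                   pedigree$sire[pedigree$gen == "GIII"])
  sires <- sires[vapply(sires, function(s) length(sons_of[[s]] %||% character(0)) >= 2L, TRUE)]
  phases <- list(); tracks <- list(); ev <- list(); n_mendel <- 0L
  n_sons <- vapply(sires, function(s) length(sons_of[[s]]), 1L)
  names(n_sons) <- sires
  for (ci in chroms) {
    m <- map[map$chrom == ci, ]
    m <- m[order(m$bp), ]
    gmat <- geno[[ci]]
    for (s in sires) {
      sons <- sons_of[[s]]
      ph <- phase_sire(gmat[s, ], gmat[sons, , drop = FALSE], m$bp)
      phases[[paste(s, ci)]] <- ph
      for (son in sons) {
        tr <- assign_origin(gmat[son, ], gmat[s, ], ph, m$bp)
        n_mendel <- n_mendel + tr$n_mendel_err
        tracks[[paste(son, ci)]] <- tr
        e <- call_crossovers(tr)
        if (nrow(e)) {
          e$sire <- s; e$son <- son; e$chrom <- ci
          ev[[length(ev) + 1L]] <- e
        }
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(left_idx = integer(0), right_idx = integer(0),
               left_bp = numeric(0), right_bp = numeric(0),
               left_rank = integer(0), right_rank = integer(0),
               sire = character(0), son = character(0), chrom = integer(0))
  removed <- cbind(events[0, ], reason = character(0))
  if (clean && nrow(events)) {
    lens <- tapply(map$bp, map$chrom, max)
    cl <- clean_crossovers(events, n_sons, lens, min_inner = min_inner,
                           window_bp = window_filter_bp, p0 = p0, alpha = alpha)
    events <- cl$events
    removed <- cl$removed
  }
  structure(list(events = events, removed = removed, phases = phases,
                 tracks = tracks, n_sons = n_sons,
                 n_gametes = sum(n_sons), sires = sires,
                 n_mendel_err = n_mendel, map = map),
            class = "co_detection")
}

#' @export
print.co_detection <- function(x, ...) {
  cat(sprintf("Crossover detection: %d events in %d gametes (%d sires); %d removed by cleanup\n",
              nrow(x$events), x$n_gametes, length(x$sires), nrow(x$removed)))
  cat(sprintf("  %.2f CO per gamete genome-wide; %d Mendelian inconsistencies flagged\n",
              nrow(x$events) / max(1, x$n_gametes), x$n_mendel_err))
  invisible(x)
}
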