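#' Reconstructed (phased) sire haplotypes as allele matrices
#'
#' Assembles, for each chromosome, a matrix with two rows per GII sire
#' (haplotype 1 and 2) over all markers: phased alleles at heterozygous
#' sites, genotype-derived alleles at homozygous sites, NA where the phase
#' is undefined.
#'
#' @param det a \code{\link{detect_crossovers}} result.
#' @param geno genotype matrices.
#' @param map marker map.
#' @return list (per chromosome) of matrices, rownames \code{<sire>.1/.2}.
#' @export
phased_sire_haplotypes <- function(det, geno, map) {
  chroms <- sort(unique(map$chrom))
  out <- list()
  for (ci in chroms) {
    gm <- geno[[ci]]
    H <- matrix(NA_integer_, 2L * length(det$sires), ncol(gm),
                dimnames = list(paste(rep(det$sires, each = 2), 1:2, sep = "."), NULL))
    for (si in seq_along(det$sires)) {
      s <- det$sires[si]
      ph <- det$phases[[paste(s, ci)]]
      sg <- gm[s, ]
      hapA <- ifelse(sg == 1L, NA_integer_, sg %/% 2L)
      hapA[ph$sites] <- ph$hap1
      H[2L * si - 1L, ] <- hapA
      H[2L * si, ] <- ifelse(sg == 1L, 1L - hapA, hapA)
    }
    out[[ci]] <- H
  }
  out
}

#' Assign haplotypes to ancestral clusters at anchor positions
#'
#' At each anchor marker, haplotypes are clustered on the alleles of a
#' flanking marker window by hierarchical clustering (Hamming distance,
#' average linkage) cut at \code{K} clusters.  Missing alleles are imputed
#' at 0.5 for the distance computation.  Ties are broken deterministically
#' by haplotype order; when fewer than \code{K} distinct haplotypes exist
#' the number of clusters is reduced and flagged.
#'
#' @param hap haplotype allele matrix (haplotypes x markers).
#' @param bp marker positions.
#' @param anchors marker indices at which to cluster.
#' @param K number of clusters (default 20).
#' @param window_bp total width of the flanking window (default 1 Mb).
#' @return list per anchor: \code{cluster} (integer vector), \code{flagged}.
#' @export
cluster_haplotypes <- function(hap, bp, anchors, K = 20L, window_bp = 1e6) {
  lapply(anchors, function(a) {
    lo <- bp[a] - window_bp / 2; hi <- bp[a] + window_bp / 2
    cols <- which(bp >= lo & bp <= hi)
    X <- hap[, cols, drop = FALSE]
    X[is.na(X)] <- 0.5
    d <- stats::dist(X, method = "manhattan")
    n_distinct <- nrow(unique(X))
    k_use <- min(K, n_distinct)
    cl <- if (k_use == 1L) rep(1L, nrow(X)) else
      stats::cutree(stats::hclust(d, method = "average"), k = k_use)
    list(cluster = as.integer(cl), flagged = k_use < K, anchor = a)
  })
}

## restricted log-likelihood, sigma_e profiled, for all columns of Y at once.
## V = sigma_e^2 (diag(rdiag) + ga*A + gc*C);  X = 1.
rll_cols <- function(Y, rdiag, A, C, ga, gc) {
  n <- nrow(Y)
  V0 <- diag(rdiag, n) + ga * A
  if (!is.null(C) && gc > 0) V0 <- V0 + gc * C
  L <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(L)) return(rep(-Inf, ncol(Y)))
  U <- backsolve(L, Y, transpose = TRUE)
  v <- backsolve(L, rep(1, n), transpose = TRUE)
  s <- sum(v^2)
  ypy <- pmax(colSums(U^2) - drop(crossprod(v, U))^2 / s, 1e-12)
  -0.5 * (2 * sum(log(diag(L))) + log(s) + (n - 1) * log(ypy / (n - 1)) + (n - 1))
}

## grid-REML maximum over variance ratios; Y n x m
reml_grid_max <- function(Y, rdiag, A, C = NULL,
                          ga_grid = c(0, exp(seq(log(0.05), log(20), length.out = 7))),
                          gc_grid = c(0, exp(seq(log(0.05), log(30), length.out = 8)))) {
  best <- rep(-Inf, ncol(Y))
  if (is.null(C)) gc_grid <- 0
  for (ga in ga_grid) for (gc in gc_grid) {
    r <- rll_cols(Y, rdiag, A, C, ga, gc)
    best <- pmax(best, r)
  }
  best
}

#' Haplotype-cluster mixed-model genome scan
#'
#' At each anchor position the sire phenotype is modeled with an overall
#' mean, a random polygenic effect (covariance proportional to the additive
#' relationship matrix), a random i.i.d. ancestral-haplotype-cluster effect
#' (a sire's expectation receives the effects of his two cluster
#' assignments) and a residual with variance proportional to 1/(number of
#' sons).  REML maximization is by profile likelihood over a grid of
#' variance ratios (the zero ratio is on the grid, so the likelihood-ratio
#' test against the no-cluster null is nonnegative); LRT = 2(logL_full -
#' logL_null) and lod = LRT/(2 ln 10).
#'
#' @param pheno data.frame \code{sire}, \code{y}, \code{n_sons}.
#' @param A additive relationship matrix over the sires (in \code{pheno}
#'   order).
#' @param positions data.frame \code{chrom}, \code{bp} aligned with
#'   \code{clusters}.
#' @param clusters list of integer vectors (one per position), each of
#'   length 2 x sires in \code{pheno} order (haplotype 1 then 2 per sire),
#'   e.g. from \code{\link{cluster_haplotypes}} on
#'   \code{\link{phased_sire_haplotypes}}.
#' @return object of class \code{qtl_scan}: data.frame \code{chrom},
#'   \code{bp}, \code{lrt}, \code{lod}; thresholds NA until
#'   \code{\link{permutation_thresholds}} is run.
#' @export
mixed_scan <- function(pheno, clusters, positions, A) {
  Y <- matrix(pheno$y, ncol = 1)
  sc <- scan_lrt(Y, pheno, clusters, A)
  res <- data.frame(chrom = positions$chrom, bp = positions$bp,
                    lrt = sc[1, ], lod = sc[1, ] / (2 * log(10)))
  structure(list(scan = res, thresholds = c(significant = NA_real_,
                                            suggestive = NA_real_),
                 n_perm = 0L), class = "qtl_scan")
}

## LRT for every column of Y at every position; returns m x n_pos matrix
scan_lrt <- function(Y, pheno, clusters, A) {
  rdiag <- 1 / pheno$n_sons
  null_max <- reml_grid_max(Y, rdiag, A, C = NULL)
  n <- nrow(Y)
  out <- matrix(NA_real_, ncol(Y), length(clusters))
  for (j in seq_along(clusters)) {
    cl <- clusters[[j]]
    K <- max(cl)
    Z <- matrix(0, n, K)
    i1 <- cbind(seq_len(n), cl[seq(1, 2 * n, by = 2)])
    i2 <- cbind(seq_len(n), cl[seq(2, 2 * n, by = 2)])
    Z[i1] <- Z[i1] + 1
    Z[i2] <- Z[i2] + 1
    C <- tcrossprod(Z)
    full_max <- reml_grid_max(Y, rdiag, A, C)
    out[, j] <- 2 * pmax(full_max - null_max, 0)
  }
  out
}

#' Permutation thresholds for the haplotype-cluster scan
#'
#' Phenotypes are permuted amongst half-sib GII sires within grandsire
#' families, the genome scan is rerun for every permutation, and the
#' genome-wide maximum LRT stored.  The significant threshold is the 95th
#' percentile of the stored maxima (genome-wide 5\% type-I error); the
#' suggestive threshold is the \eqn{e^{-1}} quantile, i.e. the LRT exceeded
#' on average once per null genome scan (the fraction of null scans with no
#' exceedance is then \eqn{e^{-1} \approx 0.37}).
#'
#' @param scan a \code{\link{mixed_scan}} result.
#' @param pheno,clusters,A as in \code{\link{mixed_scan}}.
#' @param family grandsire id per sire (permutation blocks).
#' @param n_perm number of permutations (>= 200 recommended).
#' @param seed integer seed.
#' @return the scan with \code{thresholds} filled and the permutation maxima
#'   attached as \code{perm_max}.
#' @export
permutation_thresholds <- function(scan, pheno, clusters, A, family,
                                   n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(scan, "qtl_scan"))
  set.seed(derive_seed(seed, "permthr"))
  n <- nrow(pheno)
  P <- matrix(NA_real_, n, n_perm)
  for (r in seq_len(n_perm)) {
    idx <- seq_len(n)
    for (f in unique(family)) {
      rows <- which(family == f)
      if (length(rows) > 1L) idx[rows] <- rows[sample.int(length(rows))]
    }
    P[, r] <- pheno$y[idx]
  }
  lrt <- scan_lrt(P, pheno, clusters, A)
  perm_max <- apply(lrt, 1, max)
  scan$thresholds <- c(significant = unname(stats::quantile(perm_max, 0.95)),
                       suggestive = unname(stats::quantile(perm_max, exp(-1))))
  scan$perm_max <- perm_max
  scan$n_perm <- n_perm
  scan
}

#' @export
print.qtl_scan <- function(x, ...) {
  top <- x$scan[which.max(x$scan$lrt), ]
  cat(sprintf("Haplotype-cluster mixed-model scan over %d positions\n", nrow(x$scan)))
  cat(sprintf("  max LRT %.2f (lod %.2f) at chr%s:%.0f\n", top$lrt, top$lod,
              top$chrom, top$bp))
  if (x$n_perm > 0)
    cat(sprintf("  thresholds (%d permutations): significant %.2f, suggestive %.2f\n",
                x$n_perm, x$thresholds[["significant"]], x$thresholds[["suggestive"]]))
  invisible(x)
}

#' @export
plot.qtl_scan <- function(x, ...) {
  s <- x$scan
  off <- c(0, cumsum(tapply(s$bp, s$chrom, max)))
  xx <- s$bp + off[match(s$chrom, sort(unique(s$chrom)))]
  plot(xx, s$lod, pch = 16, cex = 0.6, xlab = "genome position",
       ylab = "lod", col = s$chrom %% 2 + 1, ...)
  if (!is.na(x$thresholds[["significant"]]))
    graphics::abline(h = x$thresholds / (2 * log(10)), lty = 2, col = c(2, 4))
  invisible(x)
}

#' Scan for cis-acting haplotype effects on local recombination rate
#'
#' At each anchor, an 800-kb window is centered on the marker; every GIII
#' son receives as phenotype the summed overlap mass o_i/x_i of his paternal
#' crossover intervals with the window, and the additive effect of the
#' sire's two ancestral-haplotype clusters on his sons' phenotypes is tested
#' by ANOVA (least squares on the sire's cluster dosages) across the sons of
#' cluster-heterozygous sires.  Positions where no crossover touches the
#' window are skipped (p = NA).
#'
#' @param det a \code{\link{detect_crossovers}} result.
#' @param clusters cluster assignments per position (as in
#'   \code{\link{mixed_scan}}, two entries per sire).
#' @param positions data.frame \code{chrom}, \code{bp}, \code{idx} (marker
#'   index).
#' @param pedigree pedigree.
#' @param window_bp window width (default 800 kb).
#' @param prep precomputed \code{\link{cis_prep}} result (built when NULL).
#' @return data.frame \code{chrom}, \code{bp}, \code{F}, \code{p},
#'   \code{n_sons_tested}.
#' @export
cis_lrr_scan <- function(det, clusters, positions, pedigree, window_bp = 8e5,
                         prep = NULL) {
  if (is.null(prep)) prep <- cis_prep(det, positions, pedigree, window_bp)
  out <- positions
  out$F <- NA_real_; out$p <- NA_real_; out$n_sons_tested <- 0L
  for (j in seq_len(nrow(positions))) {
    pj <- prep[[j]]
    if (is.null(pj)) next
    r <- cis_anova(cluster_pair(clusters[[j]]), pj$sums, pj$yy, prep$n_sons)
    out$F[j] <- r$F; out$p[j] <- r$p; out$n_sons_tested[j] <- r$n
  }
  out
}

#' Precompute per-sire crossover-mass statistics for the cis scan
#'
#' For every anchor: per-sire sums of son window-overlap phenotypes and the
#' sum of squared son phenotypes.  Because all sons of a sire share the
#' sire's cluster dosages, these sufficient statistics make the dosage
#' ANOVA independent of the number of sons.
#'
#' @inheritParams cis_lrr_scan
#' @export
cis_prep <- function(det, positions, pedigree, window_bp = 8e5) {
  ev <- det$events
  sons_of <- split(pedigree$id[pedigree$gen == "GIII"],
                   pedigree$sire[pedigree$gen == "GIII"])
  sons <- character(0); sires_idx <- integer(0)
  for (si in seq_along(det$sires)) {
    ss <- sons_of[[det$sires[si]]]
    sons <- c(sons, ss); sires_idx <- c(sires_idx, rep(si, length(ss)))
  }
  out <- lapply(seq_len(nrow(positions)), function(j) {
    ci <- positions$chrom[j]
    lo <- positions$bp[j] - window_bp / 2; hi <- positions$bp[j] + window_bp / 2
    e <- ev[ev$chrom == ci & ev$right_bp > lo & ev$left_bp < hi, ]
    if (!nrow(e)) return(NULL)
    x <- e$right_bp - e$left_bp; x[x <= 0] <- 1
    o <- pmax(0, pmin(e$right_bp, hi) - pmax(e$left_bp, lo))
    mass <- tapply(o / x, factor(e$son, levels = sons), sum)
    y <- as.numeric(mass); y[is.na(y)] <- 0
    if (sum(y) == 0) return(NULL)
    sums <- as.numeric(tapply(y, factor(sires_idx, levels = seq_along(det$sires)), sum))
    sums[is.na(sums)] <- 0
    list(sums = sums, yy = sum(y^2))
  })
  out$n_sons <- as.numeric(tabulate(sires_idx, nbins = length(det$sires)))
  out
}

## a sire's two cluster ids at one position; rows of a (sires x 2) matrix
cluster_pair <- function(cl) {
  n <- length(cl) / 2
  cbind(cl[seq(1, 2 * n, by = 2)], cl[seq(2, 2 * n, by = 2)])
}

## additive cluster-dosage ANOVA on sire-level sufficient statistics:
## son phenotype ~ intercept + dosage of each cluster carried by his sire,
## restricted to cluster-heterozygous sires
cis_anova <- function(pair, sums, yy, n_sons) {
  het <- pair[, 1] != pair[, 2] & n_sons > 0
  if (sum(het) < 2L) return(list(F = NA_real_, p = NA_real_, n = 0L))
  p1 <- pair[het, 1]; p2 <- pair[het, 2]
  sums <- sums[het]; ns <- n_sons[het]
  lev <- sort(unique(c(p1, p2)))
  if (length(lev) < 2L) return(list(F = NA_real_, p = NA_real_, n = sum(ns)))
  D <- matrix(0, length(p1), length(lev))
  D[cbind(seq_along(p1), match(p1, lev))] <- 1
  D[cbind(seq_along(p1), match(p2, lev))] <- D[cbind(seq_along(p1), match(p2, lev))] + 1
  X <- cbind(1, D[, -1, drop = FALSE])   # dosages sum to 2: drop one level
  XtX <- crossprod(X * sqrt(ns))
  Xty <- crossprod(X, sums)
  q <- qr(XtX)
  rank <- q$rank
  N <- sum(ns)
  df1 <- rank - 1L; df2 <- N - rank
  if (df1 < 1L || df2 < 1L) return(list(F = NA_real_, p = NA_real_, n = N))
  b <- qr.coef(q, Xty)
  b[is.na(b)] <- 0
  sse1 <- yy - sum(b * Xty)
  sse0 <- yy - sum(sums)^2 / N
  if (sse1 <= 1e-12) return(list(F = NA_real_, p = NA_real_, n = N))
  Fv <- ((sse0 - sse1) / df1) / (sse1 / df2)
  Fv <- max(Fv, 0)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE), n = N)
}

#' Permutation significance threshold for the cis-acting scan
#'
#' The sires' phased-haplotype (cluster-pair) identities are permuted within
#' grandsire families, the cis scan statistic recomputed at every position,
#' and the genome-wide maximum of -log10(p) stored; thresholds are the 95th
#' and \eqn{e^{-1}} quantiles of the maxima.
#'
#' @inheritParams cis_lrr_scan
#' @param family grandsire id per sire (in \code{det$sires} order).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param prep precomputed \code{\link{cis_prep}} result (built when NULL).
#' @return list \code{significant}, \code{suggestive} (on -log10 p scale),
#'   \code{perm_max}.
#' @export
cis_permutation_thresholds <- function(det, clusters, positions, pedigree,
                                       family, window_bp = 8e5,
                                       n_perm = 200L, seed = 1L, prep = NULL) {
  if (is.null(prep)) prep <- cis_prep(det, positions, pedigree, window_bp)
  set.seed(derive_seed(seed, "cisperm"))
  n_sires <- length(det$sires)
  pairs <- lapply(clusters, cluster_pair)
  perm_max <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    idx <- seq_len(n_sires)
    for (f in unique(family)) {
      rows <- which(family == f)
      if (length(rows) > 1L) idx[rows] <- rows[sample.int(length(rows))]
    }
    mx <- 0
    for (j in seq_len(length(prep) - 1L)) {
      pj <- prep[[j]]
      if (is.null(pj)) next
      a <- cis_anova(pairs[[j]][idx, , drop = FALSE], pj$sums, pj$yy, prep$n_sons)
      if (!is.na(a$p)) mx <- max(mx, -log10(a$p))
    }
    perm_max[r] <- mx
  }
  list(significant = unname(stats::quantile(perm_max, 0.95)),
       suggestive = unname(stats::quantile(perm_max, exp(-1))),
       perm_max = perm_max)
}
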