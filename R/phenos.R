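#' Genome-wide recombination rate per sire
#'
#' GRR is the mean number of (cleaned) crossovers per transmitted gamete.
#' When a correction table is supplied, sires with 10 or fewer genotyped sons
#' have the expected small-family bias subtracted; larger families are
#' reported uncorrected.
#'
#' @param det a \code{\link{detect_crossovers}} result.
#' @param correction optional \code{\link{family_size_correction}} table.
#' @return data.frame \code{sire}, \code{n_sons}, \code{grr_raw},
#'   \code{grr} (corrected).
#' @export
grr_phenotype <- function(det, correction = NULL) {
  stopifnot(inherits(det, "co_detection"))
  sires <- det$sires
  cnt <- table(factor(det$events$sire, levels = sires))
  n <- as.numeric(det$n_sons[sires])
  raw <- as.numeric(cnt) / n
  adj <- raw
  if (!is.null(correction)) {
    idx <- match(n, correction$size)
    d <- correction$delta[idx]
    use <- !is.na(d) & n <= max(correction$size)
    adj[use] <- raw[use] - d[use]
  }
  data.frame(sire = sires, n_sons = as.integer(n), grr_raw = raw, grr = adj,
             stringsAsFactors = FALSE)
}

#' Calibrate the small-family GRR bias by subsampling large families
#'
#' From calibration half-sib families with many genotyped sons, repeatedly
#' subsamples 1..\code{max_n} sons, reruns the phasing and crossover-calling
#' pipeline on the reduced family, and compares the resulting GRR with the
#' full-family GRR.  The per-size differences, averaged over replicates and
#' families, estimate the expected upward bias of GRR in small families
#' (driven by sire-phasing errors) and are subtracted from small-family GRR
#' estimates.  Size 1 is reported NA: the linkage phaser requires at least
#' two sons.
#'
#' @param geno,pedigree,map the dataset.
#' @param max_n largest corrected family size (default 10).
#' @param n_rep subsampling replicates per family and size (full-study scale
#'   1000; much smaller values are adequate at reduced scale).
#' @param min_family_size minimum size of a calibration family (default
#'   100).
#' @param n_families required number of calibration families (default 10).
#' @param seed integer seed.
#' @return data.frame of class \code{correction_table}: \code{size},
#'   \code{delta} (expected GRR bias), \code{n_families}.
#' @export
family_size_correction <- function(geno, pedigree, map, max_n = 10L,
                                   n_rep = 1000L, min_family_size = 100L,
                                   n_families = 10L, seed = 1L) {
  sons_of <- split(pedigree$id[pedigree$gen == "GIII"],
                   pedigree$sire[pedigree$gen == "GIII"])
  big <- names(sons_of)[vapply(sons_of, length, 1L) > min_family_size]
  if (length(big) < n_families)
    stop(sprintf("need %d families with > %d sons, found %d",
                 n_families, min_family_size, length(big)), call. = FALSE)
  big <- big[seq_len(n_families)]
  set.seed(derive_seed(seed, "famcorr"))
  delta <- matrix(NA_real_, length(big), max_n)
  for (fi in seq_along(big)) {
    s <- big[fi]
    sons <- sons_of[[s]]
    full <- sire_grr_once(geno, pedigree, map, s, sons)
    for (i in seq_len(max_n)) {
      if (i < 2L) next
      g <- numeric(n_rep)
      for (r in seq_len(n_rep)) {
        sub <- sample(sons, i)
        g[r] <- sire_grr_once(geno, pedigree, map, s, sub)
      }
      delta[fi, i] <- mean(g) - full
    }
  }
  out <- data.frame(size = seq_len(max_n), delta = colMeans(delta),
                    n_families = length(big))
  class(out) <- c("correction_table", "data.frame")
  out
}

## GRR of one sire computed from scratch on a subset of sons
sire_grr_once <- function(geno, pedigree, map, sire, sons) {
  n_ev <- 0L
  for (ci in sort(unique(map$chrom))) {
    m <- map[map$chrom == ci, ]; m <- m[order(m$bp), ]
    gm <- geno[[ci]]
    ph <- phase_sire(gm[sire, ], gm[sons, , drop = FALSE], m$bp)
    evs <- list()
    for (son in sons) {
      tr <- assign_origin(gm[son, ], gm[sire, ], ph, m$bp)
      e <- call_crossovers(tr)
      if (nrow(e)) { e$sire <- sire; e$son <- son; e$chrom <- ci
        evs[[length(evs) + 1L]] <- e }
    }
    if (length(evs)) {
      ev <- do.call(rbind, evs)
      ns <- stats::setNames(length(sons), sire)
      cl <- clean_crossovers(ev, ns, max(m$bp))
      n_ev <- n_ev + nrow(cl$events)
    }
  }
  n_ev / length(sons)
}

#' Genome-wide hot-window usage per sire
#'
#' The fraction of a sire's crossover mass falling in hot windows, with each
#' crossover distributing mass o_i/x_i over the windows its interval
#' overlaps (as in \code{\link{window_rr}}).
#'
#' @param events crossover data.frame.
#' @param hot_windows data.frame \code{chrom}, \code{start}, \code{end} of
#'   hot windows (e.g. flagged rows of a \code{\link{normalize_rr}} result).
#' @return data.frame \code{sire}, \code{ghu}, \code{n_co}.
#' @export
ghu_phenotype <- function(events, hot_windows) {
  sires <- sort(unique(events$sire))
  if (!nrow(events))
    return(data.frame(sire = character(0), ghu = numeric(0), n_co = integer(0)))
  hot_mass <- numeric(nrow(events))
  x <- events$right_bp - events$left_bp
  x[x <= 0] <- 1
  for (ci in unique(events$chrom)) {
    hi <- hot_windows[hot_windows$chrom == ci, ]
    ei <- which(events$chrom == ci)
    if (!nrow(hi) || !length(ei)) next
    for (k in seq_len(nrow(hi))) {
      o <- pmax(0, pmin(events$right_bp[ei], hi$end[k]) -
                   pmax(events$left_bp[ei], hi$start[k] - 1))
      hot_mass[ei] <- hot_mass[ei] + o / x[ei]
    }
  }
  agg_h <- tapply(hot_mass, events$sire, sum)
  agg_n <- table(events$sire)
  data.frame(sire = names(agg_h), ghu = as.numeric(agg_h) / as.numeric(agg_n),
             n_co = as.integer(agg_n), stringsAsFactors = FALSE)
}

#' Split-half repeatability of a sire phenotype
#'
#' Spearman rank correlation between two independent measurements of the
#' same sires (e.g. phenotypes computed from disjoint son sets).
#'
#' @param a,b data.frames with \code{sire} and a phenotype column (second
#'   column used).
#' @return list \code{rho}, \code{p}, \code{n}.
#' @export
repeatability <- function(a, b) {
  m <- merge(a, b, by = "sire")
  if (nrow(m) < 3L) stop("need at least 3 shared sires", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(m[[2]], m[[ncol(a) + 1]],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

#' Additive relationship matrix from a pedigree
#'
#' Tabular method over the recorded pedigree (founders unrelated,
#' non-inbred; dams unrecorded).
#'
#' @param pedigree data.frame \code{id}, \code{sire} (NA for founders).
#' @param ids subset and order of individuals to return.
#' @return symmetric matrix of additive relationships.
#' @export
kinship_matrix <- function(pedigree, ids = pedigree$id) {
  ord <- pedigree$id
  A <- matrix(0, length(ord), length(ord), dimnames = list(ord, ord))
  sire <- match(pedigree$sire, ord)
  for (i in seq_along(ord)) {
    s <- sire[i]
    if (!is.na(s)) {
      A[i, seq_len(i - 1)] <- A[seq_len(i - 1), i] <- 0.5 * A[s, seq_len(i - 1)]
    }
    A[i, i] <- 1    # dams unknown and founders non-inbred
  }
  A[ids, ids]
}

## ---------------------------------------------------------------------------
## REML by direct maximization of the restricted log-likelihood

## y ~ N(X b, sum_k s2[k] * G[[k]] + s2_e * R); R diagonal (vector rdiag)
reml_fit <- function(y, X, Glist, rdiag = rep(1, length(y)),
                     n_starts = 3L, tol = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  vy <- stats::var(y)
  nll <- function(logs2) {
    s2 <- exp(logs2)
    V <- diag(s2[length(s2)] * rdiag, n)
    for (k in seq_along(Glist)) V <- V + s2[k] * Glist[[k]]
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    ui <- backsolve(L, cbind(X, y), transpose = TRUE)
    Xt <- ui[, seq_len(p), drop = FALSE]
    yt <- ui[, p + 1]
    XtX <- crossprod(Xt)
    beta <- solve(XtX, crossprod(Xt, yt))
    r <- yt - Xt %*% beta
    0.5 * (2 * sum(log(diag(L))) + determinant(XtX)$modulus[1] + sum(r^2))
  }
  k <- length(Glist) + 1L
  starts <- list(log(rep(vy / k, k)),
                 log(c(rep(vy * 0.05, k - 1), vy * 0.95)),
                 log(c(rep(vy * 0.45, k - 1), vy * 0.1)))
  best <- NULL
  for (st in starts[seq_len(n_starts)]) {
    o <- stats::optim(st, nll, method = "L-BFGS-B",
                      lower = log(vy * 1e-8), upper = log(vy * 1e4),
                      control = list(factr = 10, pgtol = 1e-12, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  s2 <- exp(best$par)
  names(s2) <- c(names(Glist) %||% paste0("G", seq_along(Glist)), "residual")
  boundary <- any(best$par < log(vy * 1e-8) + 0.5) || any(best$par > log(vy * 1e4) - 0.5)
  list(sigma2 = s2, logLik = -best$value, convergence = best$convergence,
       boundary = boundary)
}

## gamete-level REML (additive + permanent sire + iid residual) computed at
## sire dimension via the Woodbury identity: V = s2e I + Z G Z' with
## G = s2a A + s2p I, so every term reduces to q x q operations on the
## per-sire sufficient statistics.
reml_gamete <- function(y, sire, A, n_starts = 3L) {
  q <- nlevels(sire)
  m <- as.numeric(tabulate(sire, nbins = q))
  if (any(m == 0)) stop("sires without gametes in the phenotype", call. = FALSE)
  sy <- as.numeric(rowsum(y, sire))
  yy <- sum(y^2)
  N <- length(y)
  vy <- stats::var(y)
  nll <- function(logs2) {
    s2 <- exp(logs2)       # additive, permanent, residual
    G <- s2[1] * A + diag(s2[2], q)
    cG <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(cG)) return(1e10)
    Ginv <- chol2inv(cG)
    H <- Ginv + diag(m / s2[3], q)
    cH <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(cH)) return(1e10)
    Hi_sy <- backsolve(cH, backsolve(cH, sy, transpose = TRUE))
    Hi_m <- backsolve(cH, backsolve(cH, m, transpose = TRUE))
    yVy <- yy / s2[3] - sum(sy * Hi_sy) / s2[3]^2
    oVo <- N / s2[3] - sum(m * Hi_m) / s2[3]^2
    oVy <- sum(y) / s2[3] - sum(m * Hi_sy) / s2[3]^2
    logdetV <- N * log(s2[3]) + 2 * sum(log(diag(cG))) + 2 * sum(log(diag(cH)))
    yPy <- yVy - oVy^2 / oVo
    0.5 * (logdetV + log(oVo) + yPy)
  }
  starts <- list(log(rep(vy / 3, 3)),
                 log(vy * c(0.05, 0.05, 0.9)),
                 log(vy * c(0.6, 0.1, 0.3)))
  best <- NULL
  for (st in starts[seq_len(n_starts)]) {
    o <- stats::optim(st, nll, method = "L-BFGS-B",
                      lower = log(vy * 1e-8), upper = log(vy * 1e4),
                      control = list(factr = 10, pgtol = 1e-12, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  s2 <- exp(best$par)
  names(s2) <- c("additive", "permanent", "residual")
  boundary <- any(best$par < log(vy * 1e-8) + 0.5) || any(best$par > log(vy * 1e4) - 0.5)
  list(sigma2 = s2, logLik = -best$value, convergence = best$convergence,
       boundary = boundary)
}

#' Narrow-sense heritability of a sire recombination phenotype
#'
#' Two REML mixed models.  Model \code{"sire_mean"} analyzes per-sire mean
#' phenotypes with a random additive animal effect (covariance twice the
#' kinship, i.e. the additive relationship matrix) and a residual whose
#' variance is proportional to 1/(number of GIII sons); h2 = additive /
#' (additive + residual).  Model \code{"gamete"} analyzes individual gamete
#' phenotypes with an additive animal effect, an uncorrelated permanent sire
#' environment effect and an i.i.d. residual; h2 = additive / total.
#'
#' @param pheno for \code{"sire_mean"}: data.frame \code{sire}, \code{y},
#'   \code{n_sons}; for \code{"gamete"}: data.frame \code{sire}, \code{y}
#'   (one row per gamete).
#' @param pedigree pedigree data.frame covering the sires.
#' @param model which mixed model.
#' @return object of class \code{h2_fit}: \code{h2}, \code{sigma2},
#'   \code{model}, \code{logLik}, \code{boundary}.
#' @export
heritability <- function(pheno, pedigree, model = c("sire_mean", "gamete")) {
  model <- match.arg(model)
  sires <- unique(pheno$sire)
  A <- kinship_matrix(pedigree, sires)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("kinship matrix not positive semi-definite", call. = FALSE)
  if (model == "sire_mean") {
    stopifnot(all(c("y", "n_sons") %in% names(pheno)))
    y <- pheno$y
    fit <- reml_fit(y, matrix(1, length(y), 1),
                    list(additive = A[pheno$sire, pheno$sire]),
                    rdiag = 1 / pheno$n_sons)
    h2 <- fit$sigma2[["additive"]] / sum(fit$sigma2)
  } else {
    fit <- reml_gamete(pheno$y, factor(pheno$sire, levels = sires), A)
    h2 <- fit$sigma2[["additive"]] / sum(fit$sigma2)
  }
  structure(list(h2 = unname(h2), sigma2 = fit$sigma2, model = model,
                 logLik = fit$logLik, boundary = fit$boundary),
            class = "h2_fit")
}

#' @export
print.h2_fit <- function(x, digits = 3, ...) {
  cat(sprintf("REML heritability (%s model): h2 = %.*f%s\n", x$model, digits,
              x$h2, if (x$boundary) " [boundary]" else ""))
  cat("  variance components:",
      paste(sprintf("%s=%.4g", names(x$sigma2), x$sigma2), collapse = " "), "\n")
  invisible(x)
}
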