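#' Probability of i crossovers given j chiasmata
#'
#' Under no chromatid interference each chiasma involves the sampled
#' chromatid independently with probability 1/2, so the crossover count on a
#' gamete from a meiosis with \code{j} chiasmata is Binomial(j, 1/2).
#'
#' @param i crossover count(s).
#' @param j chiasma count(s).
#' @return P(i CO | j chiasmata); 0 where i > j.
#' @export
co_given_chiasma <- function(i, j) {
  ifelse(i > j | i < 0, 0, choose(j, i) * 0.5^j)
}

#' Tabulate crossover counts per gamete
#'
#' @param events crossover data.frame (columns \code{sire}, \code{son},
#'   \code{chrom}).
#' @param gametes data.frame of all analyzed gametes (\code{sire},
#'   \code{son}); gametes without events count as 0 CO.
#' @param chrom chromosome to tabulate.
#' @return integer vector \code{n} with \code{n[i+1]} = number of gametes
#'   with i crossovers.
#' @export
co_count_table <- function(events, gametes, chrom) {
  e <- events[events$chrom == chrom, ]
  key <- paste(gametes$sire, gametes$son)
  cnt <- table(factor(paste(e$sire, e$son), levels = key))
  tabulate(as.integer(cnt) + 1L, nbins = max(cnt) + 1L)
}

#' Fit the chiasma-number mixture by maximum likelihood
#'
#' Deconvolves the observed gamete crossover-count distribution into the
#' proportions p_j of meioses with j = 0..\code{j_max} chiasmata, assuming no
#' chromatid interference (Binomial(j, 1/2) thinning).  The log-likelihood
#' \eqn{\sum_i n_i \log[\sum_j p_j C(j,i) 2^{-j}]} is concave in p on the
#' simplex, so the EM iteration for a fixed-component mixture converges to
#' the global maximum; boundary solutions (p_j = 0) are reached without
#' reparameterization artifacts.
#'
#' @param counts integer vector; \code{counts[i+1]} = gametes with i CO.
#' @param j_max largest chiasma number considered (default 6).
#' @param max_iter,tol EM iteration controls.
#' @return object of class \code{chiasma_fit}: \code{p} (proportions),
#'   \code{logLik}, \code{counts}, \code{flat} (TRUE when the likelihood is
#'   near-singular at the optimum).
#' @export
fit_chiasma_ml <- function(counts, j_max = 6L, max_iter = 20000L, tol = 1e-12) {
  counts <- as.numeric(counts)
  if (sum(counts) <= 0) stop("no gametes in table", call. = FALSE)
  i_obs <- max(which(counts > 0)) - 1L
  if (i_obs > j_max)
    stop(sprintf("observed %d CO exceeds j_max = %d; increase j_max", i_obs, j_max),
         call. = FALSE)
  i_seq <- 0:(length(counts) - 1L)
  B <- outer(i_seq, 0:j_max, co_given_chiasma)   # (i x j)
  N <- sum(counts)
  p <- rep(1 / (j_max + 1), j_max + 1)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    q <- pmax(as.vector(B %*% p), 1e-300)
    p <- p * as.vector(crossprod(B, counts / q)) / N
    p <- pmax(p, 0); p <- p / sum(p)
    if (it %% 50L == 0L) {
      ll <- sum(counts * log(pmax(as.vector(B %*% p), 1e-300)))
      if (ll - ll_old < tol * max(1, abs(ll))) break
      ll_old <- ll
    }
  }
  q <- pmax(as.vector(B %*% p), 1e-300)
  ll <- sum(counts * log(q))
  ## flat-likelihood flag: Fisher information of the active (p_j > 0) block
  act <- which(p > 1e-8)
  flat <- TRUE
  if (length(act) >= 1L) {
    Ba <- B[, act, drop = FALSE]
    FI <- crossprod(Ba / q * sqrt(counts + 1e-12), Ba / q * sqrt(counts + 1e-12))
    ev <- eigen(FI, symmetric = TRUE, only.values = TRUE)$values
    flat <- min(ev) < 1e-6 * max(ev)
  }
  structure(list(p = stats::setNames(p, paste0("p", 0:j_max)),
                 logLik = ll, counts = counts, j_max = j_max, flat = flat),
            class = "chiasma_fit")
}

#' @export
print.chiasma_fit <- function(x, digits = 4, ...) {
  cat("Chiasma-number mixture (no chromatid interference)\n")
  cat("  p_j:", paste(sprintf("%s=%.*f", names(x$p), digits, x$p), collapse = " "), "\n")
  cat(sprintf("  logLik %.3f over %d gametes%s\n", x$logLik, sum(x$counts),
              if (x$flat) " [flat likelihood]" else ""))
  invisible(x)
}

#' Fit the zero-truncated Poisson chiasma model
#'
#' Alternative model forcing the proportion of nullichiasmatic meioses to
#' zero: chiasma counts follow Poisson(\eqn{\lambda}) conditioned on >= 1,
#' propagated through Binomial(j, 1/2) thinning to gamete crossover counts;
#' \eqn{\lambda} is found by one-dimensional likelihood maximization.
#'
#' @param counts as in \code{\link{fit_chiasma_ml}}.
#' @param j_big internal truncation of the Poisson support (default 40).
#' @return object of class \code{trunc_pois_fit}: \code{lambda}, implied
#'   \code{p} (j = 0..6), \code{logLik}.
#' @export
fit_truncated_poisson <- function(counts, j_big = 40L) {
  counts <- as.numeric(counts)
  if (sum(counts) <= 0) stop("no gametes in table", call. = FALSE)
  i_seq <- 0:(length(counts) - 1L)
  B <- outer(i_seq, 0:j_big, co_given_chiasma)
  nll <- function(lam) {
    pj <- stats::dpois(0:j_big, lam)
    pj[1] <- 0
    pj <- pj / sum(pj)
    q <- as.vector(B %*% pj)
    -sum(counts * log(pmax(q, 1e-300)))
  }
  o <- stats::optimize(nll, c(1e-6, 30), tol = 1e-9)
  lam <- o$minimum
  pj <- stats::dpois(0:j_big, lam); pj[1] <- 0; pj <- pj / sum(pj)
  structure(list(lambda = lam,
                 p = stats::setNames(pj[1:7], paste0("p", 0:6)),
                 logLik = -o$objective, counts = counts),
            class = "trunc_pois_fit")
}

#' @export
print.trunc_pois_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Zero-truncated Poisson chiasma model: lambda = %.*f, logLik %.3f\n",
              digits, x$lambda, x$logLik))
  invisible(x)
}

#' Regress mean crossover count on chromosome length
#'
#' Ordinary least squares of the per-chromosome mean gamete crossover count
#' on physical length in Mb.  Under the obligate-chiasma model the intercept
#' approaches 0.5 CO (one mandatory chiasma transmitted with probability
#' 1/2).
#'
#' @param mean_co per-chromosome mean crossover count.
#' @param lengths_bp per-chromosome lengths in bp.
#' @return list with \code{intercept}, \code{slope} (CO per Mb), \code{r2}.
#' @export
regress_co_on_length <- function(mean_co, lengths_bp) {
  if (length(mean_co) < 3L) stop("need at least 3 chromosomes", call. = FALSE)
  mb <- lengths_bp / 1e6
  if (stats::var(mb) == 0) stop("singular design: constant lengths", call. = FALSE)
  fit <- stats::lm(mean_co ~ mb)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r2 = summary(fit)$r.squared)
}
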