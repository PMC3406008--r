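#' Simulation-derived crossover frequency tables under the gamma model
#'
#' Cuts \code{n_segments} consecutive chromosome-length segments from a long
#' stationary chiasma chain with gamma(\code{nu}, 2\code{nu}) intervals
#' (mean 50 cM), thinned to single-chromatid crossovers (mean 100 cM), and
#' tabulates: \code{f_nr} (fraction of gametes with 0, 1, 2, ... CO),
#' \code{f_sco} (position of the crossover in single-CO gametes, 5-cM bins),
#' \code{f_dco} (inter-CO distance in two-CO gametes), and \code{f_tco}
#' (the two adjacent inter-CO distances of three-CO gametes, pooled).
#'
#' When \code{u} is supplied (a vector of uniforms), the chain is built by
#' quantile transformation of the same uniforms, so tables computed across a
#' grid of \code{nu} values share common random numbers and the composite
#' likelihood is a smooth function of \code{nu}.
#'
#' @param nu gamma shape (>= 1).
#' @param length_cM chromosome length in cM; must exceed \code{bin}.
#' @param n_segments number of simulated gametes (full-study scale >= 5e5;
#'   reduced-mode values of 5e4 are adequate for grid estimation).
#' @param bin bin width in cM (default 5).
#' @param seed integer seed (ignored when \code{u} given).
#' @param u optional uniform vector for common random numbers.
#' @return object of class \code{freq_tables} with elements \code{f_nr},
#'   \code{f_sco}, \code{f_dco}, \code{f_tco}, \code{bin}, \code{length_cM},
#'   \code{nu}, \code{n_segments}.
#' @export
build_frequency_tables <- function(nu, length_cM, n_segments = 500000,
                                   bin = 5, seed = 1L, u = NULL) {
  if (length_cM < bin) stop("chromosome shorter than one bin", call. = FALSE)
  if (is.null(u)) set.seed(derive_seed(seed, paste0("ftab", round(nu * 1000))))
  cs <- chain_segments(nu, length_cM, n_segments, u = u)
  nb <- ceiling(length_cM / bin)
  nr_max <- max(cs$counts, 3L)
  f_nr <- tabulate(cs$counts + 1L, nbins = nr_max + 1L) / cs$n_segments
  first_of <- cumsum(c(0L, cs$counts))  # events sorted by segment then position
  o <- order(cs$seg, cs$within)
  within <- cs$within[o]
  sco <- within[first_of[which(cs$counts == 1L)] + 1L]
  i2 <- first_of[which(cs$counts == 2L)]
  dco <- within[i2 + 2L] - within[i2 + 1L]
  i3 <- first_of[which(cs$counts == 3L)]
  tco <- c(within[i3 + 2L] - within[i3 + 1L], within[i3 + 3L] - within[i3 + 2L])
  bin_of <- function(x) pmin(floor(x / bin), nb - 1L) + 1L
  tab <- function(x) if (length(x)) tabulate(bin_of(x), nbins = nb) / length(x) else rep(0, nb)
  structure(list(f_nr = f_nr, f_sco = tab(sco), f_dco = tab(dco),
                 f_tco = tab(tco), bin = bin, length_cM = length_cM, nu = nu,
                 n_segments = cs$n_segments,
                 n_sco = length(sco), n_dco = length(dco), n_tco = length(tco) / 2),
            class = "freq_tables")
}

## per-gamete observation summary on one chromosome:
## counts of CO per gamete plus binned positions/distances
observed_co <- function(events, map, chrom, gametes, bin = 5) {
  m <- map[map$chrom == chrom, ]
  anch <- map_anchors(map, chrom)
  e <- events[events$chrom == chrom, , drop = FALSE]
  pos_cm <- if (nrow(e)) bp_to_cm((e$left_bp + e$right_bp) / 2, anch$bp, anch$cM) else numeric(0)
  key <- paste(gametes$sire, gametes$son)
  gk <- factor(paste(e$sire, e$son), levels = key)
  n_per <- table(gk)
  counts <- tabulate(as.integer(n_per) + 1L, nbins = max(n_per, 3L) + 1L)
  pos_by <- split(pos_cm, gk)
  sco <- unlist(lapply(pos_by, function(p) if (length(p) == 1L) p else NULL))
  dco <- unlist(lapply(pos_by, function(p) if (length(p) == 2L) diff(sort(p)) else NULL))
  tco <- unlist(lapply(pos_by, function(p) if (length(p) == 3L) diff(sort(p)) else NULL))
  list(counts = counts, sco = as.numeric(sco), dco = as.numeric(dco),
       tco = as.numeric(tco), bin = bin, n_gametes = nrow(gametes))
}

#' Composite log-likelihood of observed crossover data given tables
#'
#' Components: \code{nr} (all gametes, via the CO-count distribution),
#' \code{sco} (position of the crossover in single-CO gametes), \code{dco}
#' (the inter-CO distance of two-CO gametes), and \code{tco} (the two
#' adjacent distances of three-CO gametes treated as independent).  Gametes
#' with more than three crossovers contribute only through \code{nr} (their
#' distance probability is set to 1).  Bins with zero expected mass but
#' observed data receive add-one smoothing with renormalization and the
#' result is flagged.
#'
#' @param obs list as produced internally by \code{observed_co}: elements
#'   \code{counts} (gametes with 0,1,2,... CO), \code{sco}, \code{dco},
#'   \code{tco} (cM values).
#' @param tables a \code{\link{build_frequency_tables}} result.
#' @return list with components \code{nr}, \code{sco}, \code{dco},
#'   \code{tco}, \code{total} and \code{smoothed}.
#' @export
composite_loglik <- function(obs, tables) {
  stopifnot(inherits(tables, "freq_tables"))
  bin <- tables$bin
  nb <- length(tables$f_sco)
  smoothed <- FALSE
  comp_tab <- function(values, f, n_src) {
    if (!length(values)) return(0)
    b <- pmin(floor(values / bin), nb - 1L) + 1L
    cnt <- tabulate(b, nbins = nb)
    if (any(cnt > 0 & f == 0)) {
      smoothed <<- TRUE
      f <- (f * n_src + 1) / (n_src + nb)
    }
    sum(cnt[cnt > 0] * log(f[cnt > 0]))
  }
  n_cnt <- obs$counts
  f_nr <- tables$f_nr
  if (length(n_cnt) > length(f_nr)) f_nr <- c(f_nr, rep(0, length(n_cnt) - length(f_nr)))
  f_nr <- f_nr[seq_along(n_cnt)]
  if (any(n_cnt > 0 & f_nr == 0)) {
    smoothed <- TRUE
    f_nr <- (f_nr * tables$n_segments + 1) / (tables$n_segments + length(f_nr))
  }
  l_nr <- sum(n_cnt[n_cnt > 0] * log(f_nr[n_cnt > 0]))
  l_sco <- comp_tab(obs$sco, tables$f_sco, tables$n_sco)
  l_dco <- comp_tab(obs$dco, tables$f_dco, tables$n_dco)
  l_tco <- comp_tab(obs$tco, tables$f_tco, 2 * tables$n_tco)
  list(nr = l_nr, sco = l_sco, dco = l_dco, tco = l_tco,
       total = l_nr + l_sco + l_dco + l_tco, smoothed = smoothed)
}

#' Estimate the interference shape parameter on a grid
#'
#' Evaluates the composite log-likelihood over a grid of gamma shapes
#' (default 1 to 15 in 0.1 steps) using simulation-derived frequency tables
#' with common random numbers across the grid, and reports the overall and
#' per-component maximizers.
#'
#' @param obs observation list (see \code{\link{composite_loglik}});
#'   conveniently built with \code{\link{co_interference_obs}}.
#' @param length_cM chromosome length in cM.
#' @param grid vector of nu values (default \code{seq(1, 15, 0.1)}).
#' @param n_segments simulated gametes per grid point (reduced mode 5e4).
#' @param bin bin width cM.
#' @param seed seed for the common-random-number stream.
#' @return object of class \code{interference_fit}: data.frame \code{grid}
#'   with component log-likelihoods, and \code{nu_hat} (named vector of
#'   maximizers: total, nr, sco, dco, tco).
#' @export
estimate_nu <- function(obs, length_cM, grid = seq(1, 15, by = 0.1),
                        n_segments = 50000, bin = 5, seed = 1L) {
  need <- chain_segments_nu_needed(length_cM, n_segments)
  set.seed(derive_seed(seed, "nu-crn"))
  u <- stats::runif(need)
  res <- data.frame(nu = grid, total = NA_real_, nr = NA_real_,
                    sco = NA_real_, dco = NA_real_, tco = NA_real_)
  for (k in seq_along(grid)) {
    ## thinning must also be common across the grid
    set.seed(derive_seed(seed, "nu-thin"))
    tab <- build_frequency_tables(grid[k], length_cM, n_segments, bin, u = u)
    ll <- composite_loglik(obs, tab)
    res[k, c("total", "nr", "sco", "dco", "tco")] <-
      c(ll$total, ll$nr, ll$sco, ll$dco, ll$tco)
  }
  nu_hat <- vapply(c("total", "nr", "sco", "dco", "tco"),
                   function(cmp) res$nu[which.max(res[[cmp]])], 1)
  structure(list(grid = res, nu_hat = nu_hat, length_cM = length_cM,
                 n_segments = n_segments, bin = bin),
            class = "interference_fit")
}

#' @export
print.interference_fit <- function(x, ...) {
  cat(sprintf("Gamma interference fit (%.0f cM chromosome, %d simulated gametes/grid point)\n",
              x$length_cM, x$n_segments))
  cat("  nu maximizing:", paste(sprintf("%s=%.1f", names(x$nu_hat), x$nu_hat),
                                collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.interference_fit <- function(x, ...) {
  g <- x$grid
  plot(g$nu, g$total - max(g$total), type = "l", xlab = expression(nu),
       ylab = "composite log-likelihood (rel.)", ...)
  graphics::abline(v = x$nu_hat[["total"]], lty = 2)
  invisible(x)
}

#' Build the interference observation summary from detected crossovers
#'
#' Crossover positions are interval midpoints on the cM scale (piecewise
#' linear through the marker map).
#'
#' @param events crossover data.frame.
#' @param map marker map.
#' @param chrom chromosome.
#' @param gametes data.frame (\code{sire}, \code{son}) of all gametes.
#' @param bin bin width cM.
#' @export
co_interference_obs <- function(events, map, chrom, gametes, bin = 5) {
  observed_co(events, map, chrom, gametes, bin)
}

#' Genome-wide interference level phenotype (GIL)
#'
#' For every gamete carrying exactly two crossovers on a chromosome, the
#' inter-crossover distance (midpoint to midpoint, in cM or bp) is
#' standardized by the chromosome-specific mean and standard deviation across
#' all such di-CO gametes; a sire's GIL is the mean of the standardized
#' distances over the di-CO chromosomes he transmitted.
#'
#' @param events crossover data.frame.
#' @param map marker map.
#' @param unit "cM" or "bp".
#' @return data.frame \code{sire}, \code{gil}, \code{n} (di-CO chromosomes
#'   averaged).
#' @export
gil_phenotype <- function(events, map, unit = c("cM", "bp")) {
  unit <- match.arg(unit)
  recs <- list()
  for (ci in sort(unique(events$chrom))) {
    e <- events[events$chrom == ci, ]
    mid_bp <- (e$left_bp + e$right_bp) / 2
    pos <- if (unit == "cM") {
      anch <- map_anchors(map, ci)
      bp_to_cm(mid_bp, anch$bp, anch$cM)
    } else mid_bp
    key <- paste(e$sire, e$son)
    cnt <- table(key)
    di <- names(cnt)[cnt == 2L]
    if (!length(di)) next
    d <- vapply(di, function(k) abs(diff(pos[key == k])), 1)
    z <- if (length(d) > 1L && stats::sd(d) > 0) (d - mean(d)) / stats::sd(d) else rep(0, length(d))
    recs[[length(recs) + 1L]] <- data.frame(
      sire = e$sire[match(di, key)], z = z, stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(sire = character(0), gil = numeric(0), n = integer(0)))
  all <- do.call(rbind, recs)
  agg <- stats::aggregate(z ~ sire, all, function(v) c(mean(v), length(v)))
  data.frame(sire = agg$sire, gil = agg$z[, 1], n = as.integer(agg$z[, 2]),
             stringsAsFactors = FALSE)
}
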