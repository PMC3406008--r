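#' Simulate a stationary gamma-renewal chiasma chain
#'
#' Draws chiasma positions on a chromosome segment of length \code{length_cM}
#' from a stationary renewal process whose inter-event distances are
#' gamma-distributed with shape \code{nu} and rate \code{2 nu}, scaled so that
#' the mean inter-chiasma distance is 50 cM.  \code{nu} = 1 gives a Poisson
#' (no-interference) process; larger \code{nu} gives more regular spacing,
#' i.e. positive crossover interference on the four-strand bundle.
#'
#' Stationarity of the start point is obtained by simulating the chain over a
#' long burn-in pre-segment and discarding events before the origin, so the
#' first retained event follows the equilibrium (stationary) delay
#' distribution of the renewal process.
#'
#' @param nu gamma shape parameter (>= 1); dimensionless interference strength.
#' @param length_cM segment length in centimorgan (> 0).
#' @param burn_cM length of the discarded pre-segment; defaults to 40 mean
#'   inter-event distances (2000 cM), ample for shapes in the 1..15 range.
#' @return sorted numeric vector of chiasma positions in (0, length_cM).
#' @examples
#' set.seed(1)
#' ch <- simulate_chiasma_chain(2.6, 300)
#' @export
simulate_chiasma_chain <- function(nu, length_cM, burn_cM = 2000) {
  stopifnot_scalar(nu, "nu")
  stopifnot_scalar(length_cM, "length_cM", positive = TRUE)
  if (nu < 1) stop("'nu' must be >= 1", call. = FALSE)
  total <- burn_cM + length_cM
  ## mean spacing is 50 cM; draw in blocks until the chain covers `total`
  n0 <- ceiling(total / 50 * 1.2) + 25
  pos <- cumsum(ch_intervals(n0, nu))
  while (pos[length(pos)] < total) {
    extra <- cumsum(ch_intervals(n0, nu)) + pos[length(pos)]
    pos <- c(pos, extra)
  }
  pos <- pos[pos <= total & pos > burn_cM] - burn_cM
  pos
}

## gamma(nu, rate 2*nu) intervals scaled by 100 => mean 50 cM, any nu
ch_intervals <- function(n, nu) {
  100 * stats::rgamma(n, shape = nu, rate = 2 * nu)
}

#' Thin a chiasma chain to single-chromatid crossovers
#'
#' Each chiasma on the four-strand bundle involves the sampled chromatid with
#' probability 1/2 (no chromatid interference), so events are retained
#' independently with probability 0.5.  Mean inter-crossover spacing in long
#' chains is therefore 100 cM.
#'
#' @param chiasmata sorted numeric vector of chiasma positions (cM).
#' @param p retention probability, default 0.5.
#' @return sorted numeric vector of crossover positions (cM).
#' @export
thin_to_crossovers <- function(chiasmata, p = 0.5) {
  if (length(chiasmata) == 0) return(numeric(0))
  if (is.unsorted(chiasmata)) stop("'chiasmata' must be sorted", call. = FALSE)
  chiasmata[stats::runif(length(chiasmata)) < p]
}

## Long thinned chain chopped into consecutive segments of `length_cM`;
## returns positions within segments plus per-segment counts.  Shared by the
## interference frequency tables and by parametric simulations.  When `u` is
## supplied it is a vector of uniforms reused across calls so the chain is a
## smooth function of nu (common random numbers across a likelihood grid).
chain_segments <- function(nu, length_cM, n_segments, u = NULL, thin = TRUE,
                           burn_segments = 10L) {
  n_tot <- n_segments + burn_segments
  total <- n_tot * length_cM
  need <- ceiling(total / 50 * 1.15) + 50
  if (is.null(u)) u <- stats::runif(need) else if (length(u) < need)
    stop("common-random-number vector too short: need ", need, call. = FALSE)
  iv <- 100 * stats::qgamma(u[seq_len(need)], shape = nu, rate = 2 * nu)
  pos <- cumsum(iv)
  while (pos[length(pos)] < total) {  # top-up (rare; only when u not supplied)
    pos <- c(pos, pos[length(pos)] + cumsum(100 * stats::rgamma(need, nu, rate = 2 * nu)))
  }
  pos <- pos[pos <= total]
  if (thin) pos <- pos[stats::runif(length(pos)) < 0.5]
  seg <- floor(pos / length_cM)
  keep <- seg >= burn_segments
  seg <- seg[keep] - burn_segments
  within <- pos[keep] - (seg + burn_segments) * length_cM
  counts <- tabulate(seg + 1L, nbins = n_segments)
  list(seg = seg, within = within, counts = counts, n_segments = n_segments)
}

## uniforms needed by chain_segments for given geometry (for pre-allocation)
chain_segments_nu_needed <- function(length_cM, n_segments, burn_segments = 10L) {
  ceiling((n_segments + burn_segments) * length_cM / 50 * 1.15) + 50
}
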