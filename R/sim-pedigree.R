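#' Simulate a three-generation paternal half-sib pedigree
#'
#' GI grandsires each have a zero-truncated negative-binomial number of
#' genotyped GII sons; each GII sire in turn has a zero-truncated
#' negative-binomial number of genotyped GIII sons.  The underlying NB mean is
#' calibrated (by root finding) so that the mean of the zero-truncated
#' distribution equals the configured mean.  Dams are ungenotyped and carry no
#' identifiers.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a data.frame with columns \code{id}, \code{gen} ("GI", "GII",
#'   "GIII") and \code{sire} (NA for GI founders), plus attribute
#'   \code{"pedigree"} class.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "pedigree"))
  disp <- cfg$family_size_dispersion
  n_gii <- rztnbinom(cfg$n_grandsires, cfg$sons_per_GI_mean, disp[1])
  gi_id <- sprintf("GI%04d", seq_len(cfg$n_grandsires))
  gii_id <- sprintf("GII%05d", seq_len(sum(n_gii)))
  gii_sire <- rep(gi_id, n_gii)
  n_giii <- rztnbinom(length(gii_id), cfg$sons_per_GII_mean, disp[2])
  giii_id <- sprintf("GIII%06d", seq_len(sum(n_giii)))
  giii_sire <- rep(gii_id, n_giii)
  ped <- data.frame(
    id = c(gi_id, gii_id, giii_id),
    gen = rep(c("GI", "GII", "GIII"), c(length(gi_id), length(gii_id), length(giii_id))),
    sire = c(rep(NA_character_, length(gi_id)), gii_sire, giii_sire),
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree_df", "data.frame")
  ped
}

## zero-truncated NB draws whose *truncated* mean equals `mean`
rztnbinom <- function(n, mean, size) {
  stopifnot_scalar(mean, "mean", positive = TRUE)
  if (mean < 1) stop("zero-truncated counts cannot have mean < 1", call. = FALSE)
  mu <- ztnb_mu(mean, size)
  if (mu < 1e-5) return(rep(1L, n))   # truncated mean ~1: point mass at 1
  out <- stats::rnbinom(n, mu = mu, size = size)
  while (any(out == 0L)) {
    z <- out == 0L
    out[z] <- stats::rnbinom(sum(z), mu = mu, size = size)
  }
  out
}

## underlying NB mean such that mu / (1 - P(0)) == target
ztnb_mu <- function(target, size) {
  f <- function(mu) mu / (1 - (size / (size + mu))^size) - target
  if (f(1e-8) > 0) return(1e-8)  # target barely above 1: mass at 1
  stats::uniroot(f, c(1e-8, target), tol = 1e-10)$root
}
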