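# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Piecewise-linear genetic map between anchor points.
## breaks_bp / breaks_cm are nondecreasing vectors of equal length spanning the
## chromosome (first anchor at bp 0 / cM 0).
bp_to_cm <- function(bp, breaks_bp, breaks_cm) {
  stats::approx(breaks_bp, breaks_cm, xout = bp, rule = 2, ties = "ordered")$y
}

cm_to_bp <- function(cm, breaks_bp, breaks_cm) {
  ## guard flat stretches (zero local rate) by nudging ties
  dup <- duplicated(breaks_cm)
  if (any(dup)) breaks_cm[dup] <- breaks_cm[dup] + cumsum(dup)[dup] * 1e-9
  stats::approx(breaks_cm, breaks_bp, xout = cm, rule = 2, ties = "ordered")$y
}

## map anchors (per chromosome) from a marker map data.frame; prepends the
## origin so interpolation covers [0, L].
map_anchors <- function(map, chrom, length_bp = NULL, length_cm = NULL) {
  m <- map[map$chrom == chrom, , drop = FALSE]
  m <- m[order(m$bp), , drop = FALSE]
  bb <- c(0, m$bp)
  cc <- c(0, m$cM)
  if (!is.null(length_bp) && length_bp > max(bb)) {
    bb <- c(bb, length_bp)
    cc <- c(cc, if (!is.null(length_cm)) length_cm else max(cc))
  }
  list(bp = bb, cM = cc)
}

## stable integer seed derived from a base seed and a stream label
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * (seq_along(utf8ToInt(as.character(stream))) %% 7 + 1))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483547) + 1L
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
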