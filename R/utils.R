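#' Length-weighted median
#'
#' Median of `values` with non-negative weights, using the midpoint
#' convention: if the cumulative weight hits exactly 50% at a value, the
#' median is the midpoint between that value and the next larger one.
#' With genomic-length weights this makes the median of a genome split
#' equally between copy levels 2.0 and 2.3 equal to 2.15.
#'
#' @param values numeric vector.
#' @param weights non-negative numeric vector, same length as `values`.
#' @return the weighted median (scalar).
#' @export
weighted_median <- function(values, weights) {
  stopifnot(length(values) == length(weights), length(values) >= 1L)
  if (any(weights < 0) || !all(is.finite(weights)) || !all(is.finite(values)))
    stop("weighted_median: weights must be finite and non-negative, values finite")
  tot <- sum(weights)
  if (tot <= 0) stop("weighted_median: total weight must be positive")
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord]) / tot
  i <- which(cw >= 0.5 - 1e-12)[1L]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(v)) (v[i] + v[i + 1L]) / 2 else v[i]
}

# Deterministic fan-out of per-stage / per-event seeds from one master seed.
# Result stays strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(offset)) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize chromosome names so "chr8" and "8" compare equal.
norm_chrom <- function(x) sub("^chr", "", as.character(x))

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
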