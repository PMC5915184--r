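#' @keywords internal
"_PACKAGE"

## Internal numerical helpers shared across modules.

# Numerically stable log(sum(exp(x))) over rows of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Binary entropy in bits; h(0) = h(1) = 0 by continuity.
binary_entropy <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  q <- 1 - p
  out <- numeric(length(p))
  ok <- p > 0 & p < 1
  out[ok] <- -(p[ok] * log2(p[ok]) + q[ok] * log2(q[ok]))
  out
}

# Derive a reproducible substream seed from a master seed and an index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
substream_seed <- function(master, index) {
  master <- as.double(master)
  as.integer((master * 48271 + 7919 * as.double(index)) %% 2147483647)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  invisible(x)
}
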