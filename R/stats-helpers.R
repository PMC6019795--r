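# Vectorized row summaries used in the permutation inner loop; fast paths for
# the small replicate counts typical of tissue designs.

row_medians <- function(x) {
  k <- ncol(x)
  if (k == 1L) return(x[, 1L])
  if (k == 2L) return((x[, 1L] + x[, 2L]) / 2)
  if (k == 3L) {
    hi <- pmax(x[, 1L], x[, 2L], x[, 3L])
    lo <- pmin(x[, 1L], x[, 2L], x[, 3L])
    return(x[, 1L] + x[, 2L] + x[, 3L] - hi - lo)
  }
  apply(x, 1L, stats::median)
}

row_vars <- function(x) {
  k <- ncol(x)
  mu <- rowMeans(x)
  (rowSums(x * x) - k * mu * mu) / (k - 1)
}

# All distinct assignments of N samples to labeled tissue groups of the given
# sizes. Assignments differing only by a within-group reordering of samples
# are the same assignment, so the count is the multinomial coefficient
# N! / prod(sizes!). Returns an integer matrix, one column per arrangement,
# entry = group index of each sample. Column 1 is the identity (samples in
# order filling group 1, then group 2, ...).
enumerate_arrangements <- function(sizes) {
  n <- sum(sizes)
  k <- length(sizes)
  recurse <- function(remaining, gi) {
    if (gi == k) {
      m <- matrix(0L, n, 1L)
      m[remaining, 1L] <- k
      return(m)
    }
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    cols <- lapply(picks, function(p) {
      sub <- recurse(setdiff(remaining, p), gi + 1L)
      sub[p, ] <- gi
      sub
    })
    do.call(cbind, cols)
  }
  recurse(seq_len(n), 1L)
}

count_arrangements <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# Benjamini-Hochberg step-up, delegated to stats::p.adjust; kept as a named
# seam so the adjustment family is applied in exactly one place.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
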