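# Seeded uniform subsampling of read pools (the multistage-sampling step
# of the iterative workflow).  Sampling is an explicit RNG permutation:
# simpler than hash-based reservoir schemes, equally deterministic.

#' Subsample read pairs
#'
#' Uniform sampling without replacement at pair granularity: mates are
#' never split.  If the target is at least the pool size the pool is
#' returned unchanged (original order).
#'
#' @param pairs a `pair_set`.
#' @param n_pairs target number of pairs (exclusive with `total_bp`).
#' @param total_bp target total bases; pairs are drawn until the next draw
#'   would exceed `total_bp`.
#' @param seed integer seed.
#' @return a `pair_set`.
#' @export
subsample_pairs <- function(pairs, n_pairs = NULL, total_bp = NULL,
                            seed = 1) {
  stopifnot(xor(is.null(n_pairs), is.null(total_bp)))
  n <- nrow(pairs)
  if (!is.null(n_pairs)) {
    stopifnot(n_pairs >= 0)
    if (n_pairs >= n) return(pairs)
    idx <- with_seed(seed, sample.int(n, n_pairs))
    return(pairs[sort(idx), , drop = FALSE])
  }
  stopifnot(total_bp >= 0)
  bp <- nchar(pairs$seq1) + nchar(pairs$seq2)
  if (sum(bp) <= total_bp) return(pairs)
  perm <- with_seed(seed, sample.int(n))
  cum <- cumsum(bp[perm])
  # meet the request to within one pair: stop once the total is reached
  k <- findInterval(total_bp, cum)
  if (k < n && (k == 0 || cum[k] < total_bp)) k <- k + 1L
  pairs[sort(perm[seq_len(max(1L, k))]), , drop = FALSE]
}

#' Subsample long reads
#'
#' As [subsample_pairs()] at single-read granularity.  When the target is
#' in bases, reads are drawn until the next draw would exceed the target
#' by more than 1%.
#'
#' @param reads a `seq_set`.
#' @param n_reads target read count (exclusive with `total_bp`).
#' @param total_bp target total bases.
#' @param seed integer seed.
#' @return a `seq_set`.
#' @export
subsample_long <- function(reads, n_reads = NULL, total_bp = NULL,
                           seed = 1) {
  stopifnot(xor(is.null(n_reads), is.null(total_bp)))
  n <- nrow(reads)
  if (!is.null(n_reads)) {
    stopifnot(n_reads >= 0)
    if (n_reads >= n) return(reads)
    if (n_reads == 0) return(reads[0, , drop = FALSE])
    idx <- with_seed(seed, sample.int(n, n_reads))
    return(reads[sort(idx), , drop = FALSE])
  }
  stopifnot(total_bp >= 0)
  bp <- nchar(reads$seq)
  if (sum(bp) <= total_bp) return(reads)
  perm <- with_seed(seed, sample.int(n))
  cum <- cumsum(bp[perm])
  # take reads while the running total stays within target * 1.01
  k <- sum(cum <= total_bp * 1.01)
  reads[sort(perm[seq_len(k)]), , drop = FALSE]
}
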