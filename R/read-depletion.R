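# Read recruitment and depletion: reads that belong to already-recovered
# qualified MAGs are recruited and removed, boosting the relative
# abundance of rare organisms in the residual pool for the next cycle.

#' Recruit short-read pairs to a qualified MAG set
#'
#' The built-in recruiter is a k-mer vote: a mate maps iff at least
#' `min_frac` of its k-mers occur in the MAG sequence set (an aligner
#' stand-in adequate for synthetic data; supply an external mapping via
#' `mapped1`/`mapped2` to bypass it).  Pair semantics: both mates mapped ->
#' recruited; neither -> residual; exactly one -> discarded (mate-orphans
#' are filtered so the residual pool stays properly paired).  With
#' `require_both = FALSE` a single mapped mate recruits the pair and
#' nothing is discarded.
#'
#' @param pairs a `pair_set`.
#' @param mag_seqs character vector (or seq_set) of qualified MAG contigs;
#'   empty set leaves every pair residual.
#' @param k k-mer size of the vote.
#' @param min_frac minimum fraction of read k-mers present.
#' @param require_both require both mates mapped for recruitment.
#' @param mapped1,mapped2 optional logical vectors overriding the built-in
#'   mapper (external aligner bypass).
#' @return list with `recruited`, `residual`, `discarded` pair sets; the
#'   three pools partition the input.
#' @export
recruit_short <- function(pairs, mag_seqs, k = 21, min_frac = 0.60,
                          require_both = TRUE,
                          mapped1 = NULL, mapped2 = NULL) {
  if (inherits(mag_seqs, "data.frame")) mag_seqs <- mag_seqs$seq
  n <- nrow(pairs)
  if (length(mag_seqs) == 0 || n == 0) {
    return(list(recruited = pairs[0, , drop = FALSE], residual = pairs,
                discarded = pairs[0, , drop = FALSE]))
  }
  if (is.null(mapped1) || is.null(mapped2)) {
    f1 <- cpp_kmer_vote(pairs$seq1, mag_seqs, as.integer(k))
    f2 <- cpp_kmer_vote(pairs$seq2, mag_seqs, as.integer(k))
    mapped1 <- f1 >= min_frac
    mapped2 <- f2 >= min_frac
  }
  if (require_both) {
    rec <- mapped1 & mapped2
    dis <- xor(mapped1, mapped2)
  } else {
    rec <- mapped1 | mapped2
    dis <- rep(FALSE, n)
  }
  res <- !rec & !dis
  list(recruited = pairs[rec, , drop = FALSE],
       residual = pairs[res, , drop = FALSE],
       discarded = pairs[dis, , drop = FALSE])
}

#' Recruit long reads to a qualified MAG set
#'
#' A read is recruited iff ANY alignment reaches query coverage >= 0.80
#' and identity >= 0.80 (inclusive bounds).  Alignments come either from
#' the built-in exact-anchor chain aligner against `mag_seqs` or from an
#' external PAF passed as `alignments`.
#'
#' @param long_reads a `seq_set`.
#' @param mag_seqs MAG contigs for the built-in aligner (ignored when
#'   `alignments` is given).
#' @param alignments optional alignment data frame in [parse_paf()] layout
#'   with `query_id` matching read ids.
#' @param min_cov,min_id inclusive recruitment thresholds.
#' @return list with `recruited` and `residual` seq_sets.
#' @export
recruit_long <- function(long_reads, mag_seqs = NULL, alignments = NULL,
                         min_cov = 0.80, min_id = 0.80) {
  n <- nrow(long_reads)
  if (n == 0)
    return(list(recruited = long_reads, residual = long_reads))
  if (is.null(alignments)) {
    if (inherits(mag_seqs, "data.frame")) mag_seqs <- mag_seqs$seq
    if (is.null(mag_seqs) || length(mag_seqs) == 0)
      return(list(recruited = long_reads[0, , drop = FALSE],
                  residual = long_reads))
    al <- cpp_chain_align(long_reads$seq, mag_seqs, 15L, 16L, 5L, 2000L)
    if (nrow(al) == 0)
      return(list(recruited = long_reads[0, , drop = FALSE],
                  residual = long_reads))
    # raw chain span, not homologous extension: a read anchored only on a
    # shared cassette must not be pulled to full coverage
    cov <- (al$qend - al$qstart) / al$qlen
    ident <- al$nmatch / al$blocklen
    rec_idx <- unique(al$query[cov >= min_cov & ident >= min_id])
    rec <- seq_len(n) %in% rec_idx
  } else {
    unknown <- setdiff(alignments$query_id, long_reads$id)
    if (length(unknown) > 0)
      stop("alignment references unknown read id: ", unknown[1])
    ok <- alignments$query_coverage >= min_cov &
      alignments$identity >= min_id
    rec <- long_reads$id %in% alignments$query_id[ok]
  }
  list(recruited = long_reads[rec, , drop = FALSE],
       residual = long_reads[!rec, , drop = FALSE])
}

#' Assemble cycle pools and validate the partition
#'
#' @param sr_pools result of [recruit_short()].
#' @param lr_pools result of [recruit_long()].
#' @param n_pairs_in,n_long_in input pool sizes (for the invariant check).
#' @return a `cycle_pools` list.
#' @export
cycle_pools <- function(sr_pools, lr_pools, n_pairs_in, n_long_in) {
  stopifnot(nrow(sr_pools$recruited) + nrow(sr_pools$residual) +
              nrow(sr_pools$discarded) == n_pairs_in,
            nrow(lr_pools$recruited) + nrow(lr_pools$residual) == n_long_in)
  x <- list(recruited_pairs = sr_pools$recruited,
            residual_pairs = sr_pools$residual,
            discarded_pairs = sr_pools$discarded,
            recruited_long = lr_pools$recruited,
            residual_long = lr_pools$residual)
  class(x) <- "cycle_pools"
  x
}

#' Deplete recruited reads
#'
#' Returns the residual pools plus a depletion report (counts and
#' recruited fractions).
#'
#' @param pools a [cycle_pools()].
#' @return list with `residual_pairs`, `residual_long`, `report`.
#' @export
deplete <- function(pools) {
  n_in_pairs <- nrow(pools$recruited_pairs) + nrow(pools$residual_pairs) +
    nrow(pools$discarded_pairs)
  n_in_long <- nrow(pools$recruited_long) + nrow(pools$residual_long)
  report <- data.frame(
    pool = c("pairs", "long"),
    n_input = c(n_in_pairs, n_in_long),
    n_recruited = c(nrow(pools$recruited_pairs), nrow(pools$recruited_long)),
    n_discarded = c(nrow(pools$discarded_pairs), 0L),
    n_residual = c(nrow(pools$residual_pairs), nrow(pools$residual_long)),
    recruited_frac = c(
      if (n_in_pairs > 0) nrow(pools$recruited_pairs) / n_in_pairs else 0,
      if (n_in_long > 0) nrow(pools$recruited_long) / n_in_long else 0),
    stringsAsFactors = FALSE)
  list(residual_pairs = pools$residual_pairs,
       residual_long = pools$residual_long,
       report = report)
}
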