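# Reference-based assembly evaluation: anchor-chained alignment blocks,
# NGA50, aligned genome fraction, purity, misassembly events,
# mismatch/indel rates and gene recovery.  Mismatch and indel rates are
# reported per aligned Mbp.

chain_hits <- function(hits, k, max_gap) {
  # hits: qpos/tpos ascending in qpos, one strand; vectorized split into
  # colinear chains
  n <- nrow(hits)
  if (n == 0) return(list())
  if (n == 1) return(list(hits))
  dq <- diff(hits$qpos)
  dt <- diff(hits$tpos)
  brk <- dq <= 0 | dt <= 0 | dq > max_gap + k | dt > max_gap + k |
    abs(dt - dq) > max_gap
  grp <- cumsum(c(TRUE, brk))
  unname(split(hits, grp))
}

score_chain <- function(ch, qseq, tseq, k) {
  # per-chain exact match/mismatch/indel accounting between anchors;
  # the regular case (same-diagonal short advance) is vectorized and only
  # irregular transitions are inspected
  matches <- k
  mism <- 0L
  ind <- 0L
  n <- nrow(ch)
  if (n > 1) {
    dq <- diff(ch$qpos)
    dt <- diff(ch$tpos)
    regular <- dq == dt & dq <= k
    matches <- matches + sum(dq[regular])
    for (i in which(!regular)) {
      if (dq[i] <= k || dt[i] <= k) {
        # overlapping/short advance on different diagonals
        matches <- matches + min(dq[i], dt[i])
        ind <- ind + abs(dq[i] - dt[i])
      } else {
        qseg <- substr(qseq, ch$qpos[i] + k + 1, ch$qpos[i + 1])
        tseg <- substr(tseq, ch$tpos[i] + k + 1, ch$tpos[i + 1])
        matches <- matches + k
        if (identical(qseg, tseg)) {
          matches <- matches + nchar(qseg)
        } else if (nchar(qseg) == 0 || nchar(tseg) == 0) {
          ind <- ind + abs(nchar(qseg) - nchar(tseg))
        } else {
          al <- Biostrings::pairwiseAlignment(qseg, tseg, type = "global")
          matches <- matches + Biostrings::nmatch(al)
          mism <- mism + Biostrings::nmismatch(al)
          nd <- Biostrings::nindel(al)
          ind <- ind + sum(nd@insertion[, "WidthSum"]) +
            sum(nd@deletion[, "WidthSum"])
        }
      }
    }
  }
  c(matches = matches, mismatches = mism, indels = ind)
}

#' Align contigs to a reference by exact unique anchors
#'
#' Exact k-mer anchors unique in the reference are chained colinearly
#' (maximum gap `max_gap` on both axes); chain-internal gaps are scored by
#' global alignment to yield identity, mismatch and indel counts.  All
#' coordinates are 0-based half-open; minus-strand blocks report contig
#' coordinates on the original (forward) contig.
#'
#' @param contigs a `seq_set` of contigs.
#' @param reference a `seq_set` of reference replicons.
#' @param k_anchor anchor k-mer length.
#' @param max_gap maximum chain gap in bp.
#' @param min_block minimum block length kept, bp.
#' @return data frame of aligned blocks: `contig_id`, `qstart`, `qend`,
#'   `ref_id`, `tstart`, `tend`, `strand`, `matches`, `mismatches`,
#'   `indels`, `identity`.
#' @export
align_to_reference <- function(contigs, reference, k_anchor = 31,
                               max_gap = 1000, min_block = 100) {
  stopifnot(nrow(reference) > 0)
  blocks <- list()
  for (ci in seq_len(nrow(contigs))) {
    qseq <- contigs$seq[ci]
    qlen <- nchar(qseq)
    qrc <- revcomp(qseq)
    for (ti in seq_len(nrow(reference))) {
      tseq <- reference$seq[ti]
      hits <- cpp_anchor_hits(qseq, tseq, as.integer(k_anchor))
      if (nrow(hits) == 0) next
      for (str in c(1, -1)) {
        h <- hits[hits$strand == str, , drop = FALSE]
        if (nrow(h) == 0) next
        if (str == -1) # transform to revcomp-contig coordinates
          h$qpos <- qlen - k_anchor - h$qpos
        h <- h[order(h$qpos), , drop = FALSE]
        qs <- if (str == 1) qseq else qrc
        for (ch in chain_hits(h, k_anchor, max_gap)) {
          sc <- score_chain(ch, qs, tseq, k_anchor)
          q0 <- ch$qpos[1]
          q1 <- ch$qpos[nrow(ch)] + k_anchor
          t0 <- ch$tpos[1]
          t1 <- ch$tpos[nrow(ch)] + k_anchor
          if (q1 - q0 < min_block) next
          if (str == -1) { # back to forward-contig coordinates
            tmp <- qlen - q1
            q1 <- qlen - q0
            q0 <- tmp
          }
          tot <- sc[["matches"]] + sc[["mismatches"]] + sc[["indels"]]
          blocks[[length(blocks) + 1]] <- data.frame(
            contig_id = contigs$id[ci], qstart = q0, qend = q1,
            ref_id = reference$id[ti], tstart = t0, tend = t1,
            strand = if (str == 1) "+" else "-",
            matches = sc[["matches"]], mismatches = sc[["mismatches"]],
            indels = sc[["indels"]],
            identity = if (tot > 0) sc[["matches"]] / tot else 0,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(blocks) == 0)
    return(data.frame(contig_id = character(), qstart = integer(),
                      qend = integer(), ref_id = character(),
                      tstart = integer(), tend = integer(),
                      strand = character(), matches = numeric(),
                      mismatches = numeric(), indels = numeric(),
                      identity = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, blocks)
  res[order(res$contig_id, res$qstart), , drop = FALSE]
}

#' NGA50 of aligned blocks against one reference
#'
#' Contigs are broken at misassembly breakpoints into aligned fragments;
#' fragment reference-span lengths are accumulated in descending order
#' until half the reference length is reached.  Reported as 0 (undefined)
#' when the total aligned length stays below 50%.
#'
#' @param blocks aligned blocks from [align_to_reference()].
#' @param reference_len reference length, bp.
#' @return the NGA50 length, or 0.
#' @export
nga50 <- function(blocks, reference_len) {
  if (nrow(blocks) == 0) return(0)
  spans <- sort(blocks$tend - blocks$tstart, decreasing = TRUE)
  cum <- cumsum(spans)
  if (max(cum) < 0.5 * reference_len) return(0)
  spans[which(cum >= 0.5 * reference_len)[1]]
}

interval_union_len <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start)
  start <- start[o]
  end <- end[o]
  tot <- 0
  cs <- start[1]
  ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > ce) {
      tot <- tot + (ce - cs)
      cs <- start[i]
      ce <- end[i]
    } else ce <- max(ce, end[i])
  }
  tot + (ce - cs)
}

#' Aligned genome fraction and purity
#'
#' AGF is the percent of reference positions covered by at least one block
#' (union semantics); purity is 1 minus the fraction of contig bases
#' outside every block.
#'
#' @param blocks aligned blocks.
#' @param contigs the evaluated contig set.
#' @param reference_len reference length, bp.
#' @return named numeric vector `c(agf_pct, purity)`.
#' @export
agf_and_purity <- function(blocks, contigs, reference_len) {
  agf <- 100 * interval_union_len(blocks$tstart, blocks$tend) / reference_len
  total_q <- sum(nchar(contigs$seq))
  aligned_q <- 0
  for (id in unique(blocks$contig_id)) {
    b <- blocks[blocks$contig_id == id, ]
    aligned_q <- aligned_q + interval_union_len(b$qstart, b$qend)
  }
  purity <- if (total_q > 0) 1 - (total_q - aligned_q) / total_q else NA_real_
  c(agf_pct = agf, purity = purity)
}

#' Count misassembly events
#'
#' A breakpoint between consecutive blocks of one contig counts when the
#' blocks hit different references, different strands, or the
#' reference-coordinate jump (gap or overlap) exceeds `jump` relative to
#' the contig-coordinate advance (the conventional extensive-misassembly
#' threshold of 1 kbp).
#'
#' @param blocks aligned blocks.
#' @param jump jump threshold, bp.
#' @return total misassembly count.
#' @export
count_misassemblies <- function(blocks, jump = 1000) {
  n <- 0L
  for (id in unique(blocks$contig_id)) {
    b <- blocks[blocks$contig_id == id, , drop = FALSE]
    b <- b[order(b$qstart), , drop = FALSE]
    if (nrow(b) < 2) next
    for (i in 2:nrow(b)) {
      prev <- b[i - 1, ]
      curr <- b[i, ]
      if (curr$ref_id != prev$ref_id || curr$strand != prev$strand) {
        n <- n + 1L
        next
      }
      dq <- curr$qstart - prev$qend
      dt <- if (curr$strand == "+") curr$tstart - prev$tend
            else prev$tstart - curr$tend
      if (abs(dt - dq) > jump) n <- n + 1L
    }
  }
  n
}

#' Gene recovery ratio
#'
#' Percent of reference genes with an identical predicted protein in the
#' MAG (100% amino-acid identity and 100% length coverage, i.e. exact
#' protein string equality).
#'
#' @param reference_proteins character vector of reference protein
#'   sequences.
#' @param mag_seqs MAG contigs (`seq_set` or character).
#' @param min_orf_len minimum ORF length for prediction, nt.
#' @return recovery percentage.
#' @export
gene_recovery <- function(reference_proteins, mag_seqs, min_orf_len = 90) {
  if (length(reference_proteins) == 0) return(NA_real_)
  orfs <- find_orfs(mag_seqs, min_len = min_orf_len)
  100 * sum(reference_proteins %in% orfs$protein) /
    length(reference_proteins)
}

#' Expected coverage of community members
#'
#' The expected coverage of member i is its base share of the sequencing
#' effort divided by its genome size: `share_i * total_bp / genome_size_i`.
#'
#' @param base_share fraction of sequenced bases attributed to each member.
#' @param genome_size genome sizes, bp.
#' @param class_total_bp total sequenced bases of the read class.
#' @return numeric expected coverages.
#' @export
expected_coverage <- function(base_share, genome_size, class_total_bp) {
  base_share * class_total_bp / genome_size
}

#' Spearman correlation of observed vs expected coverage
#'
#' @param observed,expected coverage vectors (>= 3 points for a defined
#'   correlation).
#' @return list with `rho` (NA when undefined) and `defined`.
#' @export
coverage_spearman <- function(observed, expected) {
  if (length(observed) < 3 || length(observed) != length(expected))
    return(list(rho = NA_real_, defined = FALSE))
  if (length(unique(observed)) < 2 || length(unique(expected)) < 2)
    return(list(rho = NA_real_, defined = FALSE))
  list(rho = suppressWarnings(cor(observed, expected, method = "spearman")),
       defined = TRUE)
}

#' Evaluate one MAG against its reference
#'
#' @param mag a `seq_set` of MAG contigs.
#' @param reference a `seq_set` (one genome, possibly several replicons).
#' @param reference_proteins optional protein set for gene recovery.
#' @param k_anchor,max_gap alignment settings.
#' @return one-row data frame of metrics (rates per aligned Mbp).
#' @export
evaluate_mag <- function(mag, reference, reference_proteins = NULL,
                         k_anchor = 31, max_gap = 1000) {
  blocks <- align_to_reference(mag, reference, k_anchor, max_gap)
  ref_len <- sum(nchar(reference$seq))
  ap <- agf_and_purity(blocks, mag, ref_len)
  aligned_mbp <- sum(blocks$qend - blocks$qstart) / 1e6
  mis <- count_misassemblies(blocks)
  data.frame(
    nga50 = nga50(blocks, ref_len),
    agf_pct = ap[["agf_pct"]],
    purity = ap[["purity"]],
    n_misassemblies = mis,
    misassemblies_per_mbp = if (aligned_mbp > 0) mis / aligned_mbp else NA,
    mismatches_per_mbp = if (aligned_mbp > 0)
      sum(blocks$mismatches) / aligned_mbp else NA,
    indels_per_mbp = if (aligned_mbp > 0)
      sum(blocks$indels) / aligned_mbp else NA,
    gene_recovery_pct = if (!is.null(reference_proteins))
      gene_recovery(reference_proteins, mag) else NA,
    stringsAsFactors = FALSE)
}
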