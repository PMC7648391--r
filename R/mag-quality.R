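# CheckM-like quality emulation and the MAG quality-tier gate.
#
# Completeness and contamination come from an explicit single-copy marker
# library: completeness = percent of markers present at least once,
# contamination = percent of extra marker copies (the "extra copies / K"
# convention).  Tiers follow the MIMAG-style definitions used for
# enrichment-reactor MAG curation:
#   FINISHED  single circular contig meeting the HQ thresholds
#   HQ        all three rRNA genes, >= 18 tRNAs, > 90% completeness,
#             < 5% contamination
#   DQ        > 70% completeness, < 10% contamination, 16S present,
#             >= 18 tRNAs
#   LQ        all DQ criteria except the 16S rRNA
#   high contiguity (HC): <= 5 contigs

#' Scan a bin for marker copies
#'
#' A marker copy is counted per alignment chain with identity >=
#' `min_identity` and marker coverage >= `min_coverage` (exact-anchor
#' chain aligner).
#'
#' @param contigs `contig_set`/`seq_set` of the bin.
#' @param lib a [marker_library()].
#' @param min_identity minimum alignment identity.
#' @param min_coverage minimum fraction of the marker covered.
#' @return named integer vector of per-marker copy counts.
#' @export
marker_scan <- function(contigs, lib, min_identity = 0.95,
                        min_coverage = 0.95) {
  count_hits(lib$markers$seq, lib$markers$id, contigs,
             min_identity, min_coverage)
}

# exact-anchor chain scan of query elements against contigs; identity of
# each chain is refined by exact comparison of the framed target segment
# when the frame fits (planted-element divergence is substitution-only)
scan_hits <- function(query_seqs, contigs, min_identity, min_coverage,
                      max_occ = 64L) {
  empty <- data.frame(query = integer(), target = integer(),
                      qstart = integer(), qend = integer(),
                      tstart = integer(), tend = integer(),
                      cov_ext = numeric())
  if (nrow(contigs) == 0 || length(query_seqs) == 0) return(empty)
  al <- cpp_chain_align(query_seqs, contigs$seq, 15L, as.integer(max_occ),
                        2L, 500L)
  if (nrow(al) == 0) return(empty)
  qlen <- nchar(query_seqs)[al$query]
  ident <- al$nmatch / al$blocklen
  for (r in seq_len(nrow(al))) {
    tlen <- al$tlen[r]
    if (al$strand[r] > 0) {
      t0 <- al$tstart[r] - al$qstart[r]
      t1 <- t0 + qlen[r]
    } else {
      t1 <- al$tend[r] + al$qstart[r]
      t0 <- t1 - qlen[r]
    }
    # clip the frame to the contig so element pieces at contig edges are
    # still compared exactly over their aligned part
    t0c <- max(t0, 0)
    t1c <- min(t1, tlen)
    if (t1c - t0c < 50) next
    seg <- substr(contigs$seq[al$target[r]], t0c + 1, t1c)
    if (al$strand[r] < 0) seg <- revcomp(seg)
    q <- query_seqs[al$query[r]]
    qseg <- if (al$strand[r] > 0) substr(q, t0c - t0 + 1, t1c - t0)
            else substr(q, t1 - t1c + 1, t1 - t0c)
    if (nchar(seg) == nchar(qseg) && nchar(qseg) > 0) {
      # the exact comparison supersedes the k-mer survival estimate
      # (which is wildly optimistic for spurious micro-chains)
      mism <- sum(charToRaw(seg) != charToRaw(qseg))
      ident[r] <- 1 - mism / nchar(qseg)
    }
  }
  keep <- ident >= min_identity
  data.frame(query = al$query[keep], target = al$target[keep],
             qstart = al$qstart[keep], qend = al$qend[keep],
             tstart = al$tstart[keep], tend = al$tend[keep],
             cov_ext = al$qcov_ext[keep])
}

# per-query copy counts over a bin: full-coverage chains count copies; a
# query whose pieces are split across contig breaks still counts as
# present when its aggregate (union) coverage reaches the threshold
count_hits <- function(query_seqs, query_ids, contigs,
                       min_identity, min_coverage) {
  counts <- setNames(integer(length(query_seqs)), query_ids)
  hits <- scan_hits(query_seqs, contigs, min_identity, min_coverage)
  if (nrow(hits) == 0) return(counts)
  qlen <- nchar(query_seqs)
  for (q in unique(hits$query)) {
    h <- hits[hits$query == q, , drop = FALSE]
    n_full <- sum(h$cov_ext >= min_coverage)
    agg <- interval_union_len(h$qstart, h$qend) / qlen[q]
    counts[q] <- max(n_full, as.integer(agg >= min_coverage))
  }
  counts
}

#' Completeness and contamination from marker copy counts
#'
#' completeness = 100 x (markers present) / K;
#' contamination = 100 x (extra copies) / K.
#'
#' @param copy_counts named integer vector from [marker_scan()].
#' @param K marker library size.
#' @return named numeric vector `c(completeness, contamination)`.
#' @export
#' @examples
#' completeness_contamination(c(a = 1, b = 1, c = 0, d = 3), 4)
completeness_contamination <- function(copy_counts, K) {
  stopifnot(K > 0)
  c(completeness = 100 * sum(copy_counts >= 1) / K,
    contamination = 100 * sum(pmax(copy_counts - 1, 0)) / K)
}

#' Count rRNA and tRNA cassettes in a bin
#'
#' @param contigs bin contigs.
#' @param lib a [marker_library()].
#' @param min_identity,min_coverage alignment acceptance thresholds.
#' @return list with `rrna` (named counts for 5S/16S/23S) and `trna`.
#' @export
detect_cassettes <- function(contigs, lib, min_identity = 0.95,
                             min_coverage = 0.95) {
  cass <- rbind(lib$rrna, lib$trna)
  counts <- count_hits(cass$seq, cass$id, contigs,
                       min_identity, min_coverage)
  list(rrna = c(`5S` = unname(counts["rrna_5S"]),
                `16S` = unname(counts["rrna_16S"]),
                `23S` = unname(counts["rrna_23S"])),
       trna = sum(counts[grepl("^trna", names(counts))]))
}

#' Classify a MAG into a quality tier
#'
#' Strict inequalities exactly as conventionally printed: HQ requires
#' completeness above 90 and contamination below 5 (plus all three rRNAs
#' and at least 18 tRNAs); DQ requires completeness above 70, contamination
#' below 10, a 16S and at least 18 tRNAs; LQ is DQ-except-16S; FINISHED is
#' a single circular contig meeting HQ.  "Multiple rRNA genes" reads as at
#' least one of each of 5S/16S/23S.  High contiguity means at most 5
#' contigs.
#'
#' @param completeness percent in `[0, 100]`.
#' @param contamination percent, >= 0.
#' @param n_contigs contig count.
#' @param circular_single single circular sequence?
#' @param rrna_counts named counts for `5S`, `16S`, `23S`.
#' @param trna_count tRNA count.
#' @return list with `tier` (one of FINISHED, HQ, DQ, LQ, UNQUALIFIED)
#'   and `high_contiguity`.
#' @export
classify_tier <- function(completeness, contamination, n_contigs,
                          circular_single, rrna_counts, trna_count) {
  rr <- rrna_counts[c("5S", "16S", "23S")]
  hq <- all(rr >= 1) && trna_count >= 18 &&
    completeness > 90 && contamination < 5
  dq <- completeness > 70 && contamination < 10 &&
    rr[["16S"]] >= 1 && trna_count >= 18
  lq <- completeness > 70 && contamination < 10 &&
    rr[["16S"]] < 1 && trna_count >= 18
  tier <- if (hq && n_contigs == 1 && circular_single) "FINISHED"
          else if (hq) "HQ"
          else if (dq) "DQ"
          else if (lq) "LQ"
          else "UNQUALIFIED"
  list(tier = tier, high_contiguity = n_contigs <= 5)
}

#' Full quality assessment of a bin
#'
#' @param contigs bin contigs (`contig_set`).
#' @param lib a [marker_library()].
#' @param min_identity,min_coverage marker/cassette scan thresholds.
#' @return a `quality_assessment` list: completeness, contamination,
#'   n_contigs, genome_size, n50, gc, circular_single, rrna_counts,
#'   trna_count, tier, high_contiguity.
#' @export
assess_bin <- function(contigs, lib, min_identity = 0.95,
                       min_coverage = 0.95) {
  counts <- marker_scan(contigs, lib, min_identity, min_coverage)
  cc <- completeness_contamination(counts, nrow(lib$markers))
  cass <- detect_cassettes(contigs, lib, min_identity, min_coverage)
  n <- nrow(contigs)
  circ1 <- n == 1 && isTRUE(contigs$circular[1])
  tier <- classify_tier(cc[["completeness"]], cc[["contamination"]],
                        n, circ1, cass$rrna, cass$trna)
  qa <- list(completeness = cc[["completeness"]],
             contamination = cc[["contamination"]],
             n_contigs = n,
             genome_size = sum(nchar(contigs$seq)),
             n50 = calc_n50(nchar(contigs$seq)),
             gc = gc_fraction(contigs$seq),
             circular_single = circ1,
             rrna_counts = cass$rrna,
             trna_count = cass$trna,
             tier = tier$tier,
             high_contiguity = tier$high_contiguity)
  class(qa) <- "quality_assessment"
  qa
}

#' Is a MAG qualified for the iterative gate?
#'
#' The default gate keeps high-quality, high-contiguity MAGs (FINISHED
#' counts as HQ); a `"DQ"` gate relaxes the tier to draft quality.
#'
#' @param qa a `quality_assessment`.
#' @param gate `"HQ"` (default) or `"DQ"`.
#' @return logical.
#' @export
is_qualified <- function(qa, gate = "HQ") {
  tiers <- if (gate == "HQ") c("FINISHED", "HQ")
           else c("FINISHED", "HQ", "DQ")
  (qa$tier %in% tiers) && qa$high_contiguity
}

#' Build a manifest row from a MAG record
#' @param mag_id MAG id (`H{cycle}_{label}` convention).
#' @param qa a `quality_assessment`.
#' @return one-row data frame.
#' @export
manifest_row <- function(mag_id, qa) {
  data.frame(mag_id = mag_id,
             status = if (qa$circular_single) "circular" else "linear",
             size_bp = qa$genome_size, n50_bp = qa$n50,
             n_contigs = qa$n_contigs, gc = round(qa$gc, 3),
             completeness = qa$completeness,
             contamination = qa$contamination,
             rrna = sum(qa$rrna_counts), trna = qa$trna_count,
             tier = qa$tier, hc = qa$high_contiguity,
             stringsAsFactors = FALSE)
}

#' Summarize a MAG manifest
#'
#' Aggregates counts per tier and mean/sample-sd statistics over a
#' selectable subset (id pattern and/or tiers).  The sd over a single MAG
#' is undefined and reported as 0 with `sd_defined = FALSE`.
#'
#' @param manifest data frame with at least `mag_id`, `status`, `n50_bp`,
#'   `n_contigs`, `completeness`, `contamination`, `tier`, `hc`.
#' @param id_pattern optional regex on `mag_id` for the statistics subset.
#' @param tiers optional tier filter for the statistics subset.
#' @param exclude optional mag ids excluded from the statistics subset.
#' @return list of aggregate statistics.
#' @export
summarize_manifest <- function(manifest, id_pattern = NULL, tiers = NULL,
                               exclude = NULL) {
  sub <- manifest
  if (!is.null(id_pattern)) sub <- sub[grepl(id_pattern, sub$mag_id), ]
  if (!is.null(tiers)) sub <- sub[sub$tier %in% tiers, ]
  if (!is.null(exclude)) sub <- sub[!(sub$mag_id %in% exclude), ]
  sd_or_0 <- function(x) if (length(x) < 2) 0 else sd(x)
  list(
    n_total = nrow(manifest),
    n_by_tier = table(factor(manifest$tier,
                             levels = c("FINISHED", "HQ", "DQ", "LQ",
                                        "UNQUALIFIED"))),
    n_hqhc = sum(manifest$tier %in% c("FINISHED", "HQ") & manifest$hc),
    n_finished = sum(manifest$tier == "FINISHED"),
    n_circular = sum(manifest$status == "circular"),
    subset_n = nrow(sub),
    mean_n50 = mean(sub$n50_bp),
    sd_n50 = sd_or_0(sub$n50_bp),
    mean_completeness = mean(sub$completeness),
    sd_completeness = sd_or_0(sub$completeness),
    mean_contamination = mean(sub$contamination),
    sd_contamination = sd_or_0(sub$contamination),
    sd_defined = nrow(sub) >= 2)
}

#' Classify the rows of a printed-style MAG feature table
#'
#' Reads a manifest-style TSV (columns `mag_id`, `status`, `size_mbp`,
#' `n50_mbp`, `n_contigs`, `gc`, `completeness`, `contamination`, `cds`,
#' `rrna`, `trna`) and applies [classify_tier()] to every row.  The rRNA
#' feature count is interpreted as the total over the three genes, with
#' equal copy numbers (3 means one of each, 6 two of each).
#'
#' @param tab data frame as described (e.g. from [read_manifest()]).
#' @return the table with `tier` and `hc` columns appended.
#' @export
classify_manifest <- function(tab) {
  tab$tier <- NA_character_
  tab$hc <- NA
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    per_gene <- r$rrna / 3
    cl <- classify_tier(r$completeness, r$contamination, r$n_contigs,
                        identical(r$status, "circular") && r$n_contigs == 1,
                        c(`5S` = per_gene, `16S` = per_gene,
                          `23S` = per_gene), r$trna)
    tab$tier[i] <- cl$tier
    tab$hc[i] <- cl$high_contiguity
  }
  tab
}
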