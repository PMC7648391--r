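# Pluggable assembler/binner stage.  The built-in assembler is a de Bruijn
# graph on short-read k-mers with long-read bridging (see src/assemble.cpp);
# it targets error-free or low-error synthetic reads and stands in for a
# production hybrid assembler so the iterative loop runs without external
# tools.  An adapter ingests externally assembled contigs identically.

#' Assemble reads with the built-in hybrid assembler
#'
#' Short-read k-mers with count below `min_depth` are dropped; unitigs are
#' extracted from the resulting graph and bridged by chaining exact k-mer
#' anchors along each long read (colinear chains only, majority-vote link
#' ordering, junction sequence taken from the unitig copy; repeat-flanked
#' junctions are resolved by read-level spans across the repeat).  A contig
#' is marked circular when its terminal (k-1)-mers coincide or a long-read
#' chain links its end back to its start.  Contigs shorter than
#' `min_contig_len` are discarded.
#'
#' @param pairs a `pair_set` of short reads (or `NULL`).
#' @param long_reads a `seq_set` of long reads (or `NULL` for SR-only).
#' @param k odd k-mer size in `[15, 31]`.
#' @param min_depth minimum k-mer count kept in the graph.
#' @param min_contig_len minimum emitted contig length (bp).
#' @param min_links minimum long-read support for a junction.
#' @param erode_frac unitigs with mean depth below `erode_frac * min_depth`
#'   are eroded before bridging (read noise of organisms too rare to
#'   assemble this cycle); 0 disables.
#' @return a `contig_set`: seq_set with a `depth` column (mean k-mer count).
#' @export
toy_hybrid_assemble <- function(pairs, long_reads = NULL, k = 31,
                                min_depth = 3, min_contig_len = 1000,
                                min_links = 2, erode_frac = 2) {
  if (k %% 2 == 0 || k < 15 || k > 31)
    stop("config error: k must be odd and within [15, 31]")
  sr <- character(0)
  if (!is.null(pairs) && nrow(pairs) > 0) sr <- c(pairs$seq1, pairs$seq2)
  lr <- if (!is.null(long_reads) && nrow(long_reads) > 0) long_reads$seq
        else character(0)
  if (length(sr) == 0 && length(lr) == 0)
    stop("no reads supplied")
  res <- cpp_toy_assemble(sr, lr, as.integer(k), as.integer(min_depth),
                          as.integer(min_contig_len), as.integer(min_links),
                          as.numeric(erode_frac))
  n <- length(res$seq)
  contigs <- seq_set(id = sprintf("ctg_%04d", seq_len(n)),
                     seq = as.character(res$seq),
                     circular = as.logical(res$circular))
  contigs$depth <- as.numeric(res$depth)
  class(contigs) <- c("contig_set", "seq_set", "data.frame")
  contigs
}

#' Ingest externally assembled contigs
#'
#' External assembler outputs dropped as FASTA are ingested identically to
#' built-in contigs; `depth` is taken from the optional `depth=<x>` key in
#' the description (0 when absent), circularity from the `circular=true`
#' key.  Contigs below the length filter are dropped.
#'
#' @param path FASTA path.
#' @param min_contig_len minimum contig length (bp).
#' @return a `contig_set`.
#' @export
read_external_contigs <- function(path, min_contig_len = 1000) {
  x <- read_fasta(path)
  x <- x[nchar(x$seq) >= min_contig_len, , drop = FALSE]
  d <- regmatches(x$desc, regexpr("depth=[0-9.]+", x$desc))
  depth <- rep(0, nrow(x))
  has <- grepl("depth=[0-9.]+", x$desc)
  depth[has] <- as.numeric(sub("depth=", "", d))
  x$depth <- depth
  class(x) <- c("contig_set", "seq_set", "data.frame")
  x
}

#' Bin contigs by composition and depth
#'
#' Per-contig feature: the normalized tetranucleotide frequency vector
#' plus log mean short-read depth.  Greedy centroid clustering: contigs
#' are visited longest-first and joined to the nearest centroid (cosine
#' distance on the tetranucleotide vector plus a scaled log-depth
#' difference) when within `threshold`; otherwise a contig at least
#' `seed_min_len` long seeds a new cluster (up to `max_clusters`) and a
#' shorter one is left unbinned rather than polluting a bin.  The
#' procedure is deterministic.
#'
#' @param contigs a `contig_set`.
#' @param k_feature tetranucleotide word size.
#' @param max_clusters maximum number of bins.
#' @param threshold joining distance.
#' @param depth_weight weight of the log10-depth term in the distance.
#' @param seed_min_len minimum contig length allowed to seed a cluster.
#' @return list with `bins` (each `list(bin_id, contigs)`) and `unbinned`
#'   (contig_set, possibly empty).
#' @export
toy_bin <- function(contigs, k_feature = 4, max_clusters = 24,
                    threshold = 0.15, depth_weight = 0.3,
                    seed_min_len = 2500) {
  stopifnot(nrow(contigs) > 0)
  tnf <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(contigs$seq), width = k_feature)
  tnf <- tnf / pmax(1, rowSums(tnf))
  ldepth <- log10(pmax(contigs$depth, 0.1))
  ord <- order(-nchar(contigs$seq), contigs$id)
  centroids <- list()
  assign <- integer(nrow(contigs))   # 0 = unbinned
  cosdist <- function(a, b) {
    1 - sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  }
  for (i in ord) {
    best <- NA_integer_
    best_d <- Inf
    for (ci in seq_along(centroids)) {
      cc <- centroids[[ci]]
      d <- cosdist(tnf[i, ], cc$tnf) + depth_weight * abs(ldepth[i] - cc$ldepth)
      if (d < best_d) { best_d <- d; best <- ci }
    }
    if (!is.na(best) && best_d <= threshold) {
      assign[i] <- best
      cc <- centroids[[best]]
      w2 <- nchar(contigs$seq[i])
      wt <- cc$w + w2
      centroids[[best]] <- list(tnf = (cc$tnf * cc$w + tnf[i, ] * w2) / wt,
                                ldepth = (cc$ldepth * cc$w + ldepth[i] * w2) / wt,
                                w = wt)
    } else if (nchar(contigs$seq[i]) >= seed_min_len &&
               length(centroids) < max_clusters) {
      centroids[[length(centroids) + 1]] <-
        list(tnf = tnf[i, ], ldepth = ldepth[i], w = nchar(contigs$seq[i]))
      assign[i] <- length(centroids)
    }                                # else left unbinned
  }
  bins <- lapply(seq_along(centroids), function(ci) {
    sub <- contigs[assign == ci, , drop = FALSE]
    class(sub) <- class(contigs)
    list(bin_id = sprintf("bin_%03d", ci), contigs = sub)
  })
  bins <- Filter(function(b) nrow(b$contigs) > 0, bins)
  unbinned <- contigs[assign == 0, , drop = FALSE]
  class(unbinned) <- class(contigs)
  list(bins = bins, unbinned = unbinned)
}

#' Refine bins on completeness/contamination thresholds
#'
#' Bins failing `completeness > min_completeness` or
#' `contamination < max_contamination` (both strict, the conventional
#' refinement gate `-c 70 -x 10`) are dropped.  Within surviving bins, a
#' contig carrying a duplicate marker already present on a larger contig of
#' the same bin is reassigned to the unbinned pool.
#'
#' @param bins list of bins from [toy_bin()].
#' @param lib marker library used for the quality scan.
#' @param min_completeness completeness gate (percent, strict >).
#' @param max_contamination contamination gate (percent, strict <).
#' @return list with `bins` (surviving, possibly pruned) and `unbinned`
#'   (contig_set of reassigned contigs).
#' @export
refine_bins <- function(bins, lib, min_completeness = 70,
                        max_contamination = 10) {
  kept <- list()
  unbinned <- NULL
  for (b in bins) {
    qa <- completeness_contamination(
      marker_scan(b$contigs, lib), nrow(lib$markers))
    if (!(qa[["completeness"]] > min_completeness &&
          qa[["contamination"]] < max_contamination)) next
    contigs <- b$contigs
    if (nrow(contigs) > 1 && qa[["contamination"]] > 0) {
      ord <- order(-nchar(contigs$seq))
      seen <- character(0)
      drop <- logical(nrow(contigs))
      for (i in ord) {
        hits <- marker_scan(contigs[i, , drop = FALSE], lib)
        mk <- names(hits)[hits > 0]
        if (length(intersect(mk, seen)) > 0 && length(mk) > 0)
          drop[i] <- TRUE
        else seen <- union(seen, mk)
      }
      if (any(drop)) {
        ub <- contigs[drop, , drop = FALSE]
        unbinned <- if (is.null(unbinned)) ub else rbind(unbinned, ub)
        contigs <- contigs[!drop, , drop = FALSE]
        class(contigs) <- class(b$contigs)
      }
    }
    kept[[length(kept) + 1]] <- list(bin_id = b$bin_id, contigs = contigs)
  }
  if (!is.null(unbinned)) class(unbinned) <- c("contig_set", "seq_set",
                                               "data.frame")
  list(bins = kept, unbinned = unbinned)
}
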