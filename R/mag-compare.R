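# MAG-pair analytics: MinHash genome distances, greedy genome pairing,
# identical-gene classification with functional sets I-IV, and
# dereplication of redundant genome versions.

#' MinHash sketch of a genome
#'
#' Bottom-s sketch of the canonical k-mer set (Mash-style).
#'
#' @param seqs genome sequence(s), character or `seq_set`.
#' @param k k-mer size.
#' @param s sketch size.
#' @return a `minhash_sketch` list with `k`, `s` and the sorted hash set.
#' @export
minhash_sketch <- function(seqs, k = 21, s = 1000) {
  if (inherits(seqs, "data.frame")) seqs <- seqs$seq
  if (all(nchar(seqs) <= k))
    stop("genome shorter than k: no k-mers to sketch")
  x <- list(k = k, s = s,
            hashes = as.numeric(cpp_minhash_sketch(seqs, as.integer(k),
                                                   as.integer(s))))
  class(x) <- "minhash_sketch"
  x
}

#' MinHash (Mash) distance between two sketches
#'
#' The Jaccard index is estimated from the bottom-s sketch of the union;
#' the distance is `-log(2j / (1 + j)) / k`, capped at 1 (and 1 exactly
#' when no hashes are shared).
#'
#' @param a,b `minhash_sketch` objects with equal `k` and `s`.
#' @return distance in `[0, 1]`.
#' @export
minhash_distance <- function(a, b) {
  stopifnot(a$k == b$k, a$s == b$s)
  u <- sort(unique(c(a$hashes, b$hashes)))
  bottom <- u[seq_len(min(a$s, length(u)))]
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- shared / length(bottom)
  if (j <= 0) return(1)
  min(1, -log(2 * j / (1 + j)) / a$k)
}

#' Exact Jaccard index of two k-mer sets
#'
#' Brute-force oracle support: the full (hashed) canonical k-mer sets.
#'
#' @param seqs_a,seqs_b sequences of the two genomes.
#' @param k k-mer size.
#' @return exact Jaccard index.
#' @export
exact_jaccard <- function(seqs_a, seqs_b, k = 21) {
  if (inherits(seqs_a, "data.frame")) seqs_a <- seqs_a$seq
  if (inherits(seqs_b, "data.frame")) seqs_b <- seqs_b$seq
  ha <- as.numeric(cpp_kmer_hash_set(seqs_a, as.integer(k)))
  hb <- as.numeric(cpp_kmer_hash_set(seqs_b, as.integer(k)))
  length(intersect(ha, hb)) / length(union(ha, hb))
}

#' Pair MAGs between two sets by genome distance
#'
#' Greedy minimum-distance matching: the globally closest unmatched pair
#' is matched first; pairs above `max_distance` are never matched; each
#' MAG joins at most one pair.
#'
#' @param set_a,set_b lists of `seq_set`s (or a named list of MAG records
#'   with a `contigs` element).
#' @param max_distance maximum pairing distance.
#' @param k,s sketch settings.
#' @return data frame with `id_a`, `id_b`, `distance`.
#' @export
find_pairs <- function(set_a, set_b, max_distance = 0.05, k = 21, s = 1000) {
  get_seqs <- function(m) if (!is.null(m$contigs)) m$contigs else m
  ids_from <- function(set, pre) {
    nm <- names(set)
    vapply(seq_along(set), function(i) {
      if (!is.null(nm) && nzchar(nm[i])) nm[i]
      else if (!is.null(set[[i]]$mag_id)) set[[i]]$mag_id
      else paste0(pre, i)
    }, character(1))
  }
  sk_a <- lapply(set_a, function(m) minhash_sketch(get_seqs(m), k, s))
  sk_b <- lapply(set_b, function(m) minhash_sketch(get_seqs(m), k, s))
  ids_a <- ids_from(set_a, "a")
  ids_b <- ids_from(set_b, "b")
  cand <- expand.grid(i = seq_along(set_a), j = seq_along(set_b))
  cand$d <- mapply(function(i, j) minhash_distance(sk_a[[i]], sk_b[[j]]),
                   cand$i, cand$j)
  cand <- cand[cand$d <= max_distance, , drop = FALSE]
  cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
  used_a <- logical(length(set_a))
  used_b <- logical(length(set_b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_a[i] && !used_b[j]) {
      keep[r] <- TRUE
      used_a[i] <- TRUE
      used_b[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(id_a = ids_a[cand$i], id_b = ids_b[cand$j],
             distance = cand$d, stringsAsFactors = FALSE)
}

#' Annotate predicted genes of a MAG against the planted marker library
#'
#' ORFs are called and labelled with the library's function labels when
#' their DNA aligns to a library marker (chain identity and coverage
#' thresholds); unlabelled ORFs are hypothetical proteins.
#'
#' @param mag_seqs MAG contigs.
#' @param lib a [marker_library()].
#' @param min_identity,min_coverage labelling thresholds.
#' @param min_orf_len minimum ORF length, nt.
#' @return data frame with `protein`, `func` (NA = hypothetical).
#' @export
annotate_genes <- function(mag_seqs, lib, min_identity = 0.9,
                           min_coverage = 0.9, min_orf_len = 90) {
  if (!inherits(mag_seqs, "data.frame"))
    mag_seqs <- seq_set(id = sprintf("seq%d", seq_along(mag_seqs)),
                        seq = mag_seqs)
  orfs <- find_orfs(mag_seqs, min_len = min_orf_len)
  if (nrow(orfs) == 0)
    return(data.frame(protein = character(), func = character(),
                      stringsAsFactors = FALSE))
  func <- rep(NA_character_, nrow(orfs))
  hits <- scan_hits(lib$markers$seq, mag_seqs, min_identity, min_coverage)
  # map marker hits onto ORFs by coordinate overlap on the same contig
  for (r in seq_len(nrow(hits))) {
    tcid <- mag_seqs$id[hits$target[r]]
    sel <- which(orfs$contig == tcid &
                   orfs$start < hits$tend[r] & orfs$end > hits$tstart[r])
    if (length(sel) > 0)
      func[sel] <- lib$function_labels[[lib$markers$id[hits$query[r]]]]
  }
  data.frame(protein = orfs$protein, func = func, stringsAsFactors = FALSE)
}

#' Compare the gene inventories of a MAG pair
#'
#' Identical genes are exact protein string matches, counted greedily
#' one-to-one.  Non-hypothetical functions are compared by copy number:
#' set I = shared without a hybrid excess (equal or fewer copies in the
#' hybrid MAG), set II = more copies in the hybrid MAG (both present),
#' set III = hybrid-only, set IV = short-read-only.  Weighted tallies
#' count genes, unweighted tallies count distinct functions; the four
#' sets partition the union of non-hypothetical functions.
#'
#' @param genes_a hybrid-MAG gene table (`protein`, `func`) from
#'   [annotate_genes()] or an external annotation.
#' @param genes_b short-read-only MAG gene table.
#' @return a `pair_comparison` list.
#' @export
classify_genes <- function(genes_a, genes_b) {
  pa <- table(genes_a$protein)
  pb <- table(genes_b$protein)
  shared_names <- intersect(names(pa), names(pb))
  identical_n <- sum(pmin(pa[shared_names], pb[shared_names]))
  fa <- table(genes_a$func[!is.na(genes_a$func)])
  fb <- table(genes_b$func[!is.na(genes_b$func)])
  funcs <- union(names(fa), names(fb))
  ca <- setNames(rep(0, length(funcs)), funcs)
  cb <- ca
  ca[names(fa)] <- as.numeric(fa)
  cb[names(fb)] <- as.numeric(fb)
  set <- ifelse(cb == 0, "III",
                ifelse(ca == 0, "IV",
                       ifelse(ca > cb, "II", "I")))
  weighted <- vapply(c("I", "II", "III", "IV"), function(s)
    sum(pmax(ca, cb)[set == s]), numeric(1))
  unweighted <- vapply(c("I", "II", "III", "IV"), function(s)
    sum(set == s), numeric(1))
  res <- list(
    identical_gene_count = as.numeric(identical_n),
    identical_ratio_vs_a = if (nrow(genes_a) > 0)
      100 * identical_n / nrow(genes_a) else NA_real_,
    identical_ratio_vs_b = if (nrow(genes_b) > 0)
      100 * identical_n / nrow(genes_b) else NA_real_,
    functional_sets = data.frame(
      set = c("I", "II", "III", "IV"),
      weighted = as.numeric(weighted),
      unweighted = as.numeric(unweighted),
      stringsAsFactors = FALSE),
    n_functions = length(funcs))
  class(res) <- "pair_comparison"
  res
}

#' Dereplicate MAGs by MinHash distance
#'
#' Single-linkage clusters at `max_distance`; the representative of each
#' cluster maximizes completeness - 5 x contamination, with ties broken
#' by fewer contigs, then larger N50, then lexicographic id.
#'
#' @param mags list of MAG records (`mag_id`, `contigs`, `qa`).
#' @param max_distance clustering distance.
#' @param k,s sketch settings.
#' @return the representative subset of `mags`.
#' @export
dereplicate <- function(mags, max_distance = 0.05, k = 21, s = 1000) {
  n <- length(mags)
  if (n <= 1) return(mags)
  sk <- lapply(mags, function(m) minhash_sketch(m$contigs, k, s))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (minhash_distance(sk[[i]], sk[[j]]) <= max_distance) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  score <- vapply(mags, function(m)
    m$qa$completeness - 5 * m$qa$contamination, numeric(1))
  keep <- integer(0)
  for (r in unique(roots)) {
    members <- which(roots == r)
    o <- order(-score[members],
               vapply(mags[members], function(m) m$qa$n_contigs, numeric(1)),
               -vapply(mags[members], function(m) m$qa$n50, numeric(1)),
               vapply(mags[members], function(m) m$mag_id, character(1)))
    keep <- c(keep, members[o[1]])
  }
  mags[sort(keep)]
}
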