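# Minimal prokaryotic ORF caller: 6-frame scan, starts {ATG, GTG, TTG},
# standard genetic code, minimum 90 nt, longest-ORF-per-stop convention
# (the earliest in-frame start after the previous stop).

#' Find open reading frames
#'
#' @param seqs character vector (or seq_set) of contig sequences.
#' @param min_len minimum ORF length in nt, including the stop codon.
#' @return data frame with `contig`, `start`, `end` (0-based half-open on
#'   the forward strand), `strand`, `length_nt` and `protein` (alternative
#'   starts translated as M; stop not included).
#' @export
find_orfs <- function(seqs, min_len = 90) {
  if (inherits(seqs, "data.frame")) {
    ids <- seqs$id
    seqs <- seqs$seq
  } else {
    ids <- if (!is.null(names(seqs))) names(seqs)
           else sprintf("seq%d", seq_along(seqs))
  }
  starts3 <- c("ATG", "GTG", "TTG")
  stops3 <- c("TAA", "TAG", "TGA")
  out <- list()
  for (si in seq_along(seqs)) {
    L <- nchar(seqs[si])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[si] else revcomp(seqs[si])
      for (frame in 0:2) {
        pos <- seq(frame + 1, L - 2, by = 3)
        if (length(pos) == 0) next
        codons <- substring(s, pos, pos + 2)
        is_stop <- codons %in% stops3
        is_start <- codons %in% starts3
        stop_idx <- which(is_stop)
        prev_stop <- 0L
        for (st in stop_idx) {
          cand <- which(is_start[seq(prev_stop + 1L, st)]) + prev_stop
          prev <- prev_stop
          prev_stop <- st
          if (length(cand) == 0) next
          a <- cand[1]
          len_nt <- (st - a + 1L) * 3L
          if (len_nt < min_len) next
          from <- pos[a]
          to <- pos[st] + 2L
          orf_seq <- substr(s, from, to - 3L)
          prot <- as.character(Biostrings::translate(
            Biostrings::DNAString(orf_seq), no.init.codon = TRUE))
          substr(prot, 1, 1) <- "M"
          if (strand == "+") {
            q0 <- from - 1L
            q1 <- to
          } else {
            q0 <- L - to
            q1 <- L - from + 1L
          }
          out[[length(out) + 1]] <- data.frame(
            contig = ids[si], start = q0, end = q1, strand = strand,
            length_nt = len_nt, protein = prot, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      length_nt = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE]
}
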