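# FASTA / FASTQ / PAF readers and writers, and the in-memory sequence
# containers used throughout the package.
#
# Conventions fixed here for the whole package:
#   * all coordinates are 0-based half-open; conversions happen only at
#     file boundaries
#   * FASTA is written 60-column wrapped; circularity is encoded as a
#     trailing "circular=true" key in the description (FASTA itself has no
#     standard for it)
#   * FASTQ qualities are phred-33

#' Construct a sequence set
#'
#' The universal sequence container: a data frame with one row per record
#' and columns `id`, `desc`, `seq`, `qual` (phred-33 string or `NA`) and
#' `circular`.  Used for genomes, contigs and long reads alike.
#'
#' @param id character ids (no whitespace).
#' @param seq uppercase DNA strings over A,C,G,T,N; non-empty.
#' @param desc descriptions (default empty).
#' @param qual phred-33 quality strings or `NA`; when present each must
#'   match its sequence length.
#' @param circular logical circularity flags.
#' @return a `seq_set` data frame.
#' @export
#' @examples
#' seq_set("g1", "ACGT", circular = TRUE)
seq_set <- function(id = character(), seq = character(),
                    desc = "", qual = NA_character_, circular = FALSE) {
  n <- length(id)
  x <- data.frame(id = as.character(id),
                  desc = rep_len(as.character(desc), n),
                  seq = toupper(as.character(seq)),
                  qual = rep_len(as.character(qual), n),
                  circular = rep_len(as.logical(circular), n),
                  stringsAsFactors = FALSE)
  class(x) <- c("seq_set", "data.frame")
  validate_seq_set(x)
}

validate_seq_set <- function(x) {
  if (any(grepl("[[:space:]]", x$id)))
    stop("sequence ids must not contain whitespace")
  if (any(!nzchar(x$seq)))
    stop("sequences must be non-empty")
  if (any(grepl("[^ACGTN]", x$seq)))
    stop("sequences must be over the alphabet {A,C,G,T,N}")
  bad <- !is.na(x$qual) & nchar(x$qual) != nchar(x$seq)
  if (any(bad))
    stop("quality string length must equal sequence length for: ",
         paste(x$id[bad], collapse = ", "))
  x
}

#' Construct a paired-read set
#'
#' Mates are stored side by side; mate ids derive from the pair id by the
#' `/1`, `/2` suffix convention.
#'
#' @param pair_id character pair ids.
#' @param seq1,seq2 mate sequences.
#' @param qual1,qual2 phred-33 quality strings (or `NA`).
#' @return a `pair_set` data frame.
#' @export
pair_set <- function(pair_id = character(), seq1 = character(),
                     seq2 = character(), qual1 = NA_character_,
                     qual2 = NA_character_) {
  n <- length(pair_id)
  x <- data.frame(pair_id = as.character(pair_id),
                  id1 = paste0(pair_id, "/1"),
                  seq1 = toupper(as.character(seq1)),
                  qual1 = rep_len(as.character(qual1), n),
                  id2 = paste0(pair_id, "/2"),
                  seq2 = toupper(as.character(seq2)),
                  qual2 = rep_len(as.character(qual2), n),
                  stringsAsFactors = FALSE)
  class(x) <- c("pair_set", "data.frame")
  x
}

#' Total bases in a sequence or pair set
#' @param x a `seq_set` or `pair_set`.
#' @return total base count.
#' @export
total_bp <- function(x) {
  if (inherits(x, "pair_set")) sum(nchar(x$seq1)) + sum(nchar(x$seq2))
  else sum(nchar(x$seq))
}

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated; the header token before the first
#' whitespace becomes the id; a trailing `circular=true` key in the
#' description sets the circular flag.
#'
#' @param path file path.
#' @return a `seq_set` in file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(seq_set())
  hdr <- grepl("^>", lines)
  if (!hdr[1]) {
    first_bad <- which(!hdr)[1]
    stop("malformed FASTA: line ", first_bad, " precedes any '>' header")
  }
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  # records with no sequence lines at all
  all_ids <- as.character(seq_len(sum(hdr)))
  seqs <- seqs[all_ids]
  seqs[is.na(seqs)] <- ""
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1]
    stop("malformed FASTA: record ", bad, " (line ",
         which(hdr)[bad], ") has an empty sequence")
  }
  id <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  circ <- grepl("(^|[[:space:]])circular=true([[:space:]]|$)", desc)
  seq_set(id = id, seq = toupper(seqs), desc = desc, circular = circ)
}

#' Write a FASTA file (60-column wrapped)
#'
#' A `circular=true` key is appended to the description of circular
#' records unless already present.
#'
#' @param x a `seq_set`.
#' @param path output path.
#' @param width wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    desc <- x$desc[i]
    if (isTRUE(x$circular[i]) && !grepl("circular=true", desc))
      desc <- trimws(paste(desc, "circular=true"))
    hdr <- if (nzchar(desc)) paste0(">", x$id[i], " ", desc)
           else paste0(">", x$id[i])
    writeLines(hdr, con)
    s <- x$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#' @param path file path.
#' @return a `seq_set` with phred-33 quality strings.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(seq_set())
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: line count not a multiple of 4")
  ids <- lines[seq(1, length(lines), by = 4)]
  if (any(!grepl("^@", ids)))
    stop("malformed FASTQ: record header missing '@'")
  seq_set(id = sub("[[:space:]].*$", "", sub("^@", "", ids)),
          seq = toupper(lines[seq(2, length(lines), by = 4)]),
          qual = lines[seq(4, length(lines), by = 4)])
}

#' Write a FASTQ file
#' @param x a `seq_set`; records without qualities get uniform Q40.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  qual <- ifelse(is.na(x$qual),
                 vapply(nchar(x$seq), function(n) strrep("I", n), character(1)),
                 x$qual)
  out <- rbind(paste0("@", x$id), x$seq, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read two synchronized FASTQ files as pairs
#'
#' @param path1,path2 mate-1 and mate-2 FASTQ paths.
#' @return a `pair_set`.
#' @export
read_paired_fastq <- function(path1, path2) {
  m1 <- read_fastq(path1)
  m2 <- read_fastq(path2)
  if (nrow(m1) != nrow(m2))
    stop("pairing error: ", nrow(m1), " vs ", nrow(m2), " records")
  base1 <- sub("/[12]$", "", m1$id)
  base2 <- sub("/[12]$", "", m2$id)
  if (!all(base1 == base2)) {
    bad <- which(base1 != base2)[1]
    stop("pairing error: id mismatch at record ", bad, " (",
         m1$id[bad], " vs ", m2$id[bad], ")")
  }
  pair_set(pair_id = base1, seq1 = m1$seq, seq2 = m2$seq,
           qual1 = m1$qual, qual2 = m2$qual)
}

#' Write a pair set as two synchronized FASTQ files
#' @param x a `pair_set`.
#' @param path1,path2 output paths.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_paired_fastq <- function(x, path1, path2) {
  write_fastq(seq_set(id = x$id1, seq = x$seq1, qual = x$qual1), path1)
  write_fastq(seq_set(id = x$id2, seq = x$seq2, qual = x$qual2), path2)
  invisible(c(path1, path2))
}

#' Decode a phred-33 quality string
#' @param qual quality string.
#' @return integer vector of phred scores.
#' @export
#' @examples
#' phred_scores("II") # 40 40
phred_scores <- function(qual) {
  if (is.na(qual) || !nzchar(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' Parse a PAF alignment file
#'
#' Columns 1-11 of minimap2's default output map to the alignment record
#' fields (column 10 is the match count, column 11 the block length); extra
#' columns are ignored.  Coordinates are 0-based half-open.
#'
#' @param path PAF file path.
#' @return a data frame of alignment records with derived `identity` and
#'   `query_coverage` columns.
#' @export
parse_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("PAF parse error: line ", which(nf < 12)[1], " has ",
         nf[nf < 12][1], " columns (>= 12 required)")
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  x <- data.frame(
    query_id = m[, 1], query_len = as.integer(m[, 2]),
    query_start = as.integer(m[, 3]), query_end = as.integer(m[, 4]),
    strand = m[, 5],
    target_id = m[, 6], target_len = as.integer(m[, 7]),
    target_start = as.integer(m[, 8]), target_end = as.integer(m[, 9]),
    n_matches = as.integer(m[, 10]), block_len = as.integer(m[, 11]),
    stringsAsFactors = FALSE)
  validate_alignments(x)
  x$identity <- x$n_matches / x$block_len
  x$query_coverage <- (x$query_end - x$query_start) / x$query_len
  x
}

empty_paf <- function() {
  data.frame(query_id = character(), query_len = integer(),
             query_start = integer(), query_end = integer(),
             strand = character(), target_id = character(),
             target_len = integer(), target_start = integer(),
             target_end = integer(), n_matches = integer(),
             block_len = integer(), identity = numeric(),
             query_coverage = numeric(), stringsAsFactors = FALSE)
}

validate_alignments <- function(x) {
  ok <- x$query_start >= 0 & x$query_start < x$query_end &
    x$query_end <= x$query_len &
    x$target_start >= 0 & x$target_start < x$target_end &
    x$target_end <= x$target_len &
    x$n_matches <= x$block_len &
    x$strand %in% c("+", "-")
  if (any(!ok))
    stop("alignment validation error at record ", which(!ok)[1])
  invisible(x)
}

#' Write alignments as PAF
#' @param x alignment data frame as returned by [parse_paf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(x, path) {
  m <- cbind(x$query_id, x$query_len, x$query_start, x$query_end, x$strand,
             x$target_id, x$target_len, x$target_start, x$target_end,
             x$n_matches, x$block_len, 60L)
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a TSV manifest with a header row
#' @param path file path.
#' @return data frame.
#' @export
read_manifest <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a TSV manifest with a header row
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
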