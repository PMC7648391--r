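# Truth-known synthetic communities: genome specs, a single-copy marker
# library, genome generation with planted features, and short/long read
# simulators.  Every simulated read carries a truth record so downstream
# stages can be tested against exact labels.

#' Describe one genome of a synthetic community
#'
#' @param name genome name.
#' @param length chromosome length in bp.
#' @param gc GC fraction, within `[0.25, 0.75]`.
#' @param circular logical; circular chromosome.
#' @param abundance relative abundance weight (> 0); weights are
#'   normalized over the community.
#' @param repeats list of `c(unit_length, copy_count)` long-repeat elements
#'   planted as identical copies (e.g. a `c(2100, 13)` element emulates a
#'   high-copy repeat in an anammox chromosome).
#' @param plasmids list of `c(length, copy_number)` plasmid replicons; the
#'   copy number multiplies the abundance weight for read sampling.
#' @param marker_count number of library markers planted (each exactly once).
#' @param rrna_operons number of contiguous 5S+16S+23S operon copies.
#' @param trna_count number of tRNA cassettes planted.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(name, length, gc = 0.5, circular = TRUE,
                        abundance = 1, repeats = list(), plasmids = list(),
                        marker_count = 20, rrna_operons = 1,
                        trna_count = 20) {
  stopifnot(length > 0, gc >= 0.25, gc <= 0.75, abundance > 0,
            marker_count >= 0, rrna_operons >= 0, trna_count >= 0)
  spec <- list(name = name, length = as.integer(length), gc = gc,
               circular = circular, abundance = abundance,
               repeats = repeats, plasmids = plasmids,
               marker_count = as.integer(marker_count),
               rrna_operons = as.integer(rrna_operons),
               trna_count = as.integer(trna_count))
  class(spec) <- "genome_spec"
  spec
}

random_orf <- function(len) {
  # a planted gene is a real ORF: ATG + sense codons + stop
  len <- max(90L, as.integer(len))
  ncod <- len %/% 3L
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  paste0("ATG", paste(sample(sense, ncod - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Build a marker library
#'
#' A community-wide library of named single-copy marker genes (planted once
#' per genome, the basis of the CheckM-style completeness/contamination
#' emulation), rRNA cassettes (5S/16S/23S) and a tRNA cassette.  Markers are
#' random fixed ORFs per library seed, not real genes: detection by
#' alignment is what the pipeline exercises.
#'
#' @param n_markers number of single-copy markers (K).
#' @param marker_len marker gene length in bp (multiple of 3 enforced).
#' @param n_trna number of distinct tRNA cassettes (isoacceptor-style
#'   diversity; each genome plants each cassette at most once).
#' @param seed integer seed.
#' @return a `marker_library` list with elements `markers` (seq_set),
#'   `rrna` (named 5S/16S/23S seq_set), `trna` (cassette seq_set) and
#'   `function_labels` (named character, gene id to function string).
#' @export
marker_library <- function(n_markers = 20, marker_len = 300, n_trna = 20,
                           seed = 1) {
  with_seed(seed, {
    marker_len <- (marker_len %/% 3L) * 3L
    ids <- sprintf("marker_%02d", seq_len(n_markers))
    markers <- seq_set(id = ids,
                       seq = vapply(seq_len(n_markers),
                                    function(i) random_orf(marker_len),
                                    character(1)))
    rrna <- seq_set(id = c("rrna_5S", "rrna_16S", "rrna_23S"),
                    seq = c(random_dna(120), random_dna(1000),
                            random_dna(1600)))
    trna <- seq_set(id = sprintf("trna_%02d", seq_len(n_trna)),
                    seq = vapply(seq_len(n_trna),
                                 function(i) random_dna(80), character(1)))
    stopifnot(!anyDuplicated(c(markers$seq, rrna$seq, trna$seq)))
    labels <- setNames(sprintf("F_%02d", seq_len(n_markers)), ids)
    lib <- list(markers = markers, rrna = rrna, trna = trna,
                function_labels = labels)
    class(lib) <- "marker_library"
    lib
  })
}

# Divergence of a planted element copy: substitutions at regular spacing
# (uniform divergence).  With rate >= k/length spacing stays below the
# assembly k-mer size, so two genomes' copies of the same element share no
# k-mers and the de Bruijn graphs of community members stay separate,
# while the realized identity versus the library sequence is exactly
# 1 - rate for deterministic detection at the scan threshold.
mutate_dna <- function(seqs, rate, seed) {
  if (rate <= 0) return(seqs)
  with_seed(seed, vapply(seqs, function(s) {
    len <- nchar(s)
    n <- floor(len * rate)
    if (n < 1) return(s)
    spacing <- len / n
    offset <- runif(1, 0, spacing)
    pos <- pmin(len, pmax(1, floor(offset + (0:(n - 1)) * spacing) + 1L))
    pos <- unique(pos)
    ch <- strsplit(s, "")[[1]]
    alt <- c(A = "C", C = "G", G = "T", T = "A")
    shift <- sample(1:3, length(pos), replace = TRUE)
    bases <- c("A", "C", "G", "T")
    for (i in seq_along(pos)) {
      b <- match(ch[pos[i]], bases)
      if (is.na(b)) next
      ch[pos[i]] <- bases[(b - 1 + shift[i]) %% 4 + 1]
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Generate one genome from its spec
#'
#' The chromosome is i.i.d. GC-weighted background with planted elements at
#' random non-overlapping positions: each library marker exactly once,
#' `rrna_operons` contiguous 5S+16S+23S operons, one copy of each of the
#' first `trna_count` tRNA cassettes, and the requested long-repeat
#' elements as identical copies.  By default library elements are planted
#' verbatim, so shared markers and cassettes form the same cross-genome
#' repeat structure that conserved genes and rRNA operons create in real
#' communities; a nonzero `divergence` instead substitutes that fraction
#' of bases per genome (homolog emulation, still detected at the default
#' 95% identity scan threshold).
#'
#' @param spec a [genome_spec()].
#' @param lib a [marker_library()].
#' @param seed integer seed; generation is deterministic given the seed.
#' @param divergence per-base substitution divergence of planted library
#'   elements for this genome (0 plants them verbatim).
#' @return list with `chromosome` (one-row seq_set), `plasmids` (seq_set)
#'   and `features` (truth table with 0-based half-open coordinates).
#' @export
generate_genome <- function(spec, lib, seed = 1, divergence = 0.04) {
  with_seed(seed, {
    if (spec$marker_count > nrow(lib$markers))
      stop("spec requests more markers than the library provides")
    elements <- list()
    add <- function(name, type, seq_str) {
      elements[[length(elements) + 1]] <<-
        list(name = name, type = type, seq = seq_str)
    }
    mseed <- sample.int(2^31 - 2, 1)
    if (spec$marker_count > 0) {
      mseq <- mutate_dna(lib$markers$seq[seq_len(spec$marker_count)],
                         divergence, mseed)
      for (i in seq_len(spec$marker_count))
        add(lib$markers$id[i], "marker", mseq[i])
    }
    if (spec$rrna_operons > 0) {
      operon <- paste(mutate_dna(lib$rrna$seq, divergence, mseed + 1),
                      collapse = "")
      for (i in seq_len(spec$rrna_operons))
        add(sprintf("rrna_operon_%d", i), "rrna_operon", operon)
    }
    if (spec$trna_count > 0) {
      nt <- min(spec$trna_count, nrow(lib$trna))
      tseq <- mutate_dna(lib$trna$seq[seq_len(nt)], divergence, mseed + 2)
      for (i in seq_len(nt))
        add(lib$trna$id[i], "trna", tseq[i])
    }
    for (ri in seq_along(spec$repeats)) {
      rp <- spec$repeats[[ri]]
      unit <- random_dna(rp[1], spec$gc)
      for (ci in seq_len(rp[2]))
        add(sprintf("repeat%d_copy%02d", ri, ci), "repeat", unit)
    }
    planted_len <- sum(vapply(elements, function(e) nchar(e$seq), numeric(1)))
    if (planted_len >= spec$length)
      stop("planted element lengths (", planted_len,
           ") exceed genome length (", spec$length, ")")

    chrom <- random_dna(spec$length, spec$gc)
    # place longer elements first; bounded retries for non-overlap.
    # planted elements keep a minimum spacing (intergenic background), so
    # every junction between elements carries unique anchor sequence
    min_spacing <- 150
    ord <- order(-vapply(elements, function(e) nchar(e$seq), numeric(1)),
                 vapply(elements, function(e) e$name, character(1)))
    occupied <- matrix(numeric(0), ncol = 2)
    feat <- list()
    for (ei in ord) {
      el <- elements[[ei]]
      len <- nchar(el$seq)
      placed <- FALSE
      for (try in 1:2000) {
        start <- sample.int(spec$length - len + 1L, 1) - 1L
        end <- start + len
        if (nrow(occupied) == 0 ||
            all(end + min_spacing <= occupied[, 1] |
                start >= occupied[, 2] + min_spacing)) {
          occupied <- rbind(occupied, c(start, end))
          substr(chrom, start + 1, end) <- el$seq
          feat[[length(feat) + 1]] <-
            data.frame(feature_id = el$name, type = el$type,
                       replicon = spec$name, start = start, end = end,
                       strand = "+", stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("generation error: could not place element ", el$name,
             " without overlap")
    }
    features <- if (length(feat) > 0) do.call(rbind, feat)
      else data.frame(feature_id = character(), type = character(),
                      replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL

    plasmids <- seq_set()
    if (length(spec$plasmids) > 0) {
      pl <- lapply(seq_along(spec$plasmids), function(i) {
        p <- spec$plasmids[[i]]
        seq_set(id = sprintf("%s_plasmid%d", spec$name, i),
                seq = random_dna(p[1], spec$gc), circular = TRUE)
      })
      plasmids <- do.call(rbind, pl)
      class(plasmids) <- c("seq_set", "data.frame")
    }
    list(chromosome = seq_set(id = spec$name, seq = chrom,
                              circular = spec$circular),
         plasmids = plasmids, features = features)
  })
}

#' Generate a whole community
#'
#' @param specs list of [genome_spec()]s; abundance weights are normalized.
#' @param lib a [marker_library()].
#' @param seed integer seed.
#' @param divergence per-genome divergence of planted library elements.
#' @return a `community` list: `replicons` (seq_set with `genome` and
#'   `weight` columns; plasmid weight = abundance x copy number),
#'   `features`, `specs` and `lib`.
#' @export
generate_community <- function(specs, lib, seed = 1, divergence = 0.04) {
  wtot <- sum(vapply(specs, function(s) s$abundance, numeric(1)))
  reps <- list()
  feats <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    g <- generate_genome(sp, lib, seed = stage_seed(seed, sp$name),
                         divergence = divergence)
    chrom <- g$chromosome
    chrom$genome <- sp$name
    chrom$weight <- sp$abundance / wtot
    reps[[length(reps) + 1]] <- chrom
    if (nrow(g$plasmids) > 0) {
      pl <- g$plasmids
      pl$genome <- sp$name
      pl$weight <- sp$abundance / wtot *
        vapply(sp$plasmids, function(p) p[2], numeric(1))
      reps[[length(reps) + 1]] <- pl
    }
    feats[[i]] <- g$features
  }
  replicons <- do.call(rbind, reps)
  class(replicons) <- c("seq_set", "data.frame")
  comm <- list(replicons = replicons, features = do.call(rbind, feats),
               specs = specs, lib = lib)
  class(comm) <- "community"
  comm
}

#' Simulate paired-end short reads
#'
#' Replicons are sampled proportional to abundance weight x replicon
#' length; insert sizes are Gaussian; circular replicons are sampled across
#' the origin; substitution errors only (Illumina-like).
#'
#' @param community a [generate_community()] result.
#' @param total_bp total bases to emit (mate1 + mate2).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd insert size distribution (outer distance).
#' @param error_rate per-base substitution rate.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `pairs` (pair_set) and `truth` (data frame mapping
#'   pair id to source replicon, genome, 0-based start and strand).
#' @export
simulate_short_reads <- function(community, total_bp, read_len = 150,
                                 insert_mean = 350, insert_sd = 35,
                                 error_rate = 0, seed = 1) {
  stopifnot(total_bp > 0, read_len < insert_mean)
  with_seed(seed, {
    reps <- community$replicons
    lens <- nchar(reps$seq)
    usable <- reps$circular | lens >= insert_mean + 4 * insert_sd
    if (any(!usable))
      warning("skipping replicons shorter than the insert size: ",
              paste(reps$id[!usable], collapse = ", "))
    reps <- reps[usable, , drop = FALSE]
    lens <- lens[usable]
    w <- reps$weight * lens
    n_pairs <- max(1L, round(total_bp / (2 * read_len)))
    alloc <- as.vector(rmultinom(1, n_pairs, w / sum(w)))
    out <- vector("list", nrow(reps))
    for (i in seq_len(nrow(reps))) {
      n <- alloc[i]
      if (n == 0) next
      L <- lens[i]
      ins <- pmax(read_len, pmin(round(rnorm(n, insert_mean, insert_sd)),
                                 if (reps$circular[i]) L else L))
      if (reps$circular[i]) {
        start <- sample.int(L, n, replace = TRUE) - 1L
        g2 <- paste0(reps$seq[i], substr(reps$seq[i], 1, insert_mean + 5 * insert_sd))
      } else {
        start <- floor(runif(n, 0, L - ins + 1))
        g2 <- reps$seq[i]
      }
      left <- substring(g2, start + 1, start + read_len)
      right <- revcomp(substring(g2, start + ins - read_len + 1, start + ins))
      flip <- runif(n) < 0.5
      seq1 <- ifelse(flip, right, left)
      seq2 <- ifelse(flip, left, right)
      out[[i]] <- data.frame(replicon = reps$id[i], genome = reps$genome[i],
                             start = start,
                             strand = ifelse(flip, "-", "+"),
                             seq1 = seq1, seq2 = seq2,
                             stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    pair_id <- sprintf("sr%07d", seq_len(nrow(df)))
    if (error_rate > 0) {
      eseed <- sample.int(2^31 - 2, 1)
      df$seq1 <- as.character(cpp_mutate_seqs(df$seq1, error_rate, 0, 0, eseed))
      df$seq2 <- as.character(cpp_mutate_seqs(df$seq2, error_rate, 0, 0,
                                              eseed + 1))
    }
    q <- strrep("I", read_len)
    pairs <- pair_set(pair_id = pair_id, seq1 = df$seq1, seq2 = df$seq2,
                      qual1 = q, qual2 = q)
    truth <- data.frame(pair_id = pair_id, replicon = df$replicon,
                        genome = df$genome, start = df$start,
                        strand = df$strand, stringsAsFactors = FALSE)
    list(pairs = pairs, truth = truth)
  })
}

#' Simulate nanopore-style long reads
#'
#' Log-normal read lengths calibrated so the retained set's N50 sits near
#' the target; reads shorter than `min_len` are discarded before output;
#' errors are substitutions, insertions and deletions in a fixed 60/20/20
#' split of `error_rate`.
#'
#' @param community a [generate_community()] result.
#' @param total_bp total bases to emit (after the length filter).
#' @param n50_target target N50 of the retained reads, bp.
#' @param min_len minimum retained read length, bp.
#' @param error_rate total per-base error rate.
#' @param seed integer seed.
#' @return list with `reads` (seq_set) and `truth`.
#' @export
simulate_long_reads <- function(community, total_bp, n50_target = 23000,
                                min_len = 1000, error_rate = 0.10,
                                seed = 1) {
  stopifnot(total_bp > 0, n50_target > min_len)
  with_seed(seed, {
    reps <- community$replicons
    lens <- nchar(reps$seq)
    w <- reps$weight * lens
    sdlog <- 0.55
    meanlog <- log(n50_target) - sdlog^2
    lengths <- numeric(0)
    while (sum(lengths) < total_bp) {
      need <- total_bp - sum(lengths)
      n_draw <- max(32L, ceiling(need / exp(meanlog + sdlog^2 / 2) * 1.3))
      cand <- round(rlnorm(n_draw, meanlog, sdlog))
      cand <- cand[cand >= min_len]
      lengths <- c(lengths, cand)
    }
    cum <- cumsum(lengths)
    lengths <- lengths[seq_len(which(cum >= total_bp)[1])]
    n <- length(lengths)
    ri <- sample.int(nrow(reps), n, replace = TRUE, prob = w / sum(w))
    L <- lens[ri]
    lengths <- pmin(lengths, L)
    start <- integer(n)
    circ <- reps$circular[ri]
    start[circ] <- floor(runif(sum(circ), 0, L[circ]))
    start[!circ] <- floor(runif(sum(!circ), 0, L[!circ] - lengths[!circ] + 1))
    seqs <- character(n)
    for (i in seq_len(nrow(reps))) {
      sel <- ri == i
      if (!any(sel)) next
      g2 <- if (reps$circular[i])
        paste0(reps$seq[i], substr(reps$seq[i], 1, max(lengths[sel])))
      else reps$seq[i]
      seqs[sel] <- substring(g2, start[sel] + 1, start[sel] + lengths[sel])
    }
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    if (error_rate > 0) {
      eseed <- sample.int(2^31 - 2, 1)
      seqs <- as.character(cpp_mutate_seqs(
        seqs, 0.6 * error_rate, 0.2 * error_rate, 0.2 * error_rate, eseed))
    }
    keep <- nchar(seqs) >= min_len
    seqs <- seqs[keep]
    id <- sprintf("lr%07d", seq_len(length(seqs)))
    reads <- seq_set(id = id, seq = seqs,
                     qual = strrep("I", nchar(seqs)))
    truth <- data.frame(read_id = id, replicon = reps$id[ri][keep],
                        genome = reps$genome[ri][keep],
                        start = start[keep], strand = strand[keep],
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}
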