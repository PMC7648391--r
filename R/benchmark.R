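# The packaged six-genome benchmark community: a truth-known enrichment
# ecosystem spanning a wide abundance range, with one high-copy long
# repeat (13 identical copies of a 2.1 kbp element, the signature of the
# anammox chromosome that defeats short-read assembly), one multi-copy
# plasmid and the usual marker/rRNA/tRNA inventory.  Used by the worked
# examples, the end-to-end tests and the acceptance script.

#' Genome specifications of the six-genome benchmark community
#'
#' Six circular genomes totalling ~3 Mbp with relative abundances
#' 40/25/15/10/7/3%; member GC contents are spread so that
#' composition+depth binning has signal, one dominant genome carries a
#' 2,100 bp repeat at 13 copies and the most abundant genome carries a
#' 3-copy 8 kbp plasmid.
#'
#' @return list of [genome_spec()] objects.
#' @export
benchmark_specs <- function() {
  list(
    genome_spec("g1", 650000, gc = 0.62, abundance = 40,
                plasmids = list(c(8000, 3))),
    genome_spec("g2", 600000, gc = 0.40, abundance = 25,
                repeats = list(c(2100, 13))),
    genome_spec("g3", 550000, gc = 0.56, abundance = 15),
    genome_spec("g4", 500000, gc = 0.28, abundance = 10),
    genome_spec("g5", 400000, gc = 0.47, abundance = 7),
    genome_spec("g6", 300000, gc = 0.68, abundance = 3))
}

#' Run the iterative workflow on the benchmark community
#'
#' Simulates the community (error-free short reads, 2%-error long reads
#' with N50 near 15 kbp), runs the full iterative hybrid assembly loop,
#' and resolves every final MAG against the truth genomes by MinHash
#' distance.  Cycle sizes default to desk-scale values that keep the
#' reference workflow's shape: a moderate cycle-1 draw from a much larger
#' pool, and fixed later-cycle draws from the shrinking residual.
#'
#' @param seed run seed; every stage derives a child seed from it.
#' @param sr_pool_bp,lr_pool_bp total simulated pool sizes in bases.
#' @param cycle1_sr_bp,cycle1_lr_bp cycle-1 subsample sizes.
#' @param later_sr_pairs,later_lr_reads later-cycle subsample sizes.
#' @param max_cycles maximum cycles.
#' @return list with `result` (from [run_iha()]), `community`, `matches`
#'   (per-MAG best truth genome and distance), `recovery` (per-genome
#'   earliest recovering cycle at distance <= 0.05), and `rare_fraction`
#'   (per-cycle fraction of residual pairs from the rarest genome).
#' @export
run_benchmark <- function(seed = 1, sr_pool_bp = 200e6, lr_pool_bp = 80e6,
                          cycle1_sr_bp = 30e6, cycle1_lr_bp = 25e6,
                          later_sr_pairs = 100000, later_lr_reads = 2000,
                          max_cycles = 5) {
  lib <- marker_library(n_markers = 20, seed = stage_seed(seed, "library"))
  specs <- benchmark_specs()
  comm <- generate_community(specs, lib,
                             seed = stage_seed(seed, "community"))
  sr <- simulate_short_reads(comm, total_bp = sr_pool_bp, error_rate = 0,
                             seed = stage_seed(seed, "sr"))
  lr <- simulate_long_reads(comm, total_bp = lr_pool_bp,
                            n50_target = 15000, error_rate = 0.02,
                            seed = stage_seed(seed, "lr"))
  cfg <- iha_config(cycle1_sr_bp = cycle1_sr_bp,
                    cycle1_lr_bp = cycle1_lr_bp,
                    later_sr_pairs = later_sr_pairs,
                    later_lr_reads = later_lr_reads,
                    max_cycles = max_cycles, seed = seed)
  rare_genome <- "g6"
  truth_of <- setNames(sr$truth$genome, sr$truth$pair_id)
  rare_fraction <- numeric(0)
  on_cycle <- function(state) {
    gn <- truth_of[state$pairs$pair_id]
    rare_fraction <<- c(rare_fraction, mean(gn == rare_genome))
  }
  res <- run_iha(sr$pairs, lr$reads, cfg, comm$lib, on_cycle = on_cycle)

  chrom_ids <- vapply(specs, function(s) s$name, character(1))
  chroms <- comm$replicons[match(chrom_ids, comm$replicons$id), ]
  truth_sk <- lapply(chroms$seq, minhash_sketch)
  matches <- data.frame(mag_id = character(), tier = character(),
                        hc = logical(), genome = character(),
                        distance = numeric(), cycle = integer(),
                        stringsAsFactors = FALSE)
  for (m in res$mags) {
    sk <- minhash_sketch(m$contigs)
    ds <- vapply(truth_sk, function(t) minhash_distance(sk, t), numeric(1))
    b <- which.min(ds)
    matches <- rbind(matches, data.frame(
      mag_id = m$mag_id, tier = m$qa$tier, hc = m$qa$high_contiguity,
      genome = chrom_ids[b], distance = ds[b],
      cycle = as.integer(sub("^H(\\d+)_.*", "\\1", m$mag_id)),
      stringsAsFactors = FALSE))
  }
  recovery <- setNames(rep(NA_integer_, length(chrom_ids)), chrom_ids)
  ok <- matches[matches$distance <= 0.05, , drop = FALSE]
  for (i in seq_len(nrow(ok))) {
    g <- ok$genome[i]
    if (is.na(recovery[g]) || ok$cycle[i] < recovery[g])
      recovery[g] <- ok$cycle[i]
  }
  # initial rare fraction (before any depletion) for the monotonicity check
  rare0 <- mean(truth_of[sr$pairs$pair_id] == rare_genome)
  list(result = res, community = comm, matches = matches,
       recovery = recovery,
       rare_fraction = c(rare0, rare_fraction),
       reads = list(sr_truth = sr$truth, lr_truth = lr$truth))
}
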