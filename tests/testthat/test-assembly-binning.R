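# The built-in hybrid assembler and the composition/depth binner.

test_that("error-free 30x short reads assemble a clean circular genome exactly", {
  comm <- fixture_plain_genome(len = 50000)
  sim <- simulate_short_reads(comm, total_bp = 50000 * 30, seed = 3)
  ctg <- toy_hybrid_assemble(sim$pairs, NULL)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$circular[1])
  expect_equal(nchar(ctg$seq[1]), 50000)
  expect_true(matches_rotation(ctg$seq[1], comm$replicons$seq[1]))
})

test_that("a 5 kbp repeat x2 tangles SR-only assembly; long reads resolve it", {
  comm <- fixture_plain_genome(len = 50000, repeats = list(c(5000, 2)))
  sim <- simulate_short_reads(comm, total_bp = 50000 * 30, seed = 3)
  sr_only <- toy_hybrid_assemble(sim$pairs, NULL)
  expect_gte(nrow(sr_only), 2)

  lr <- simulate_long_reads(comm, total_bp = 50000 * 20, n50_target = 15000,
                            error_rate = 0, seed = 4)
  hybrid <- toy_hybrid_assemble(sim$pairs, lr$reads)
  expect_equal(nrow(hybrid), 1)
  expect_true(hybrid$circular[1])
  expect_true(matches_rotation(hybrid$seq[1], comm$replicons$seq[1]))

  # bridging also works at the documented 2% long-read error
  lr2 <- simulate_long_reads(comm, total_bp = 50000 * 20, n50_target = 15000,
                             error_rate = 0.02, seed = 6)
  hybrid2 <- toy_hybrid_assemble(sim$pairs, lr2$reads)
  expect_equal(nrow(hybrid2), 1)
  expect_true(matches_rotation(hybrid2$seq[1], comm$replicons$seq[1]))
})

test_that("error-free assemblies never invent k-mers absent from the reads", {
  comm <- fixture_plain_genome(len = 30000, repeats = list(c(3000, 2)))
  sim <- simulate_short_reads(comm, total_bp = 30000 * 30, seed = 3)
  lr <- simulate_long_reads(comm, total_bp = 30000 * 15, n50_target = 9000,
                            error_rate = 0, seed = 4)
  ctg <- toy_hybrid_assemble(sim$pairs, lr$reads)
  read_kmers <- ihamag:::cpp_kmer_hash_set(
    c(sim$pairs$seq1, sim$pairs$seq2), 31L)
  contig_kmers <- ihamag:::cpp_kmer_hash_set(ctg$seq, 31L)
  expect_true(all(contig_kmers %in% read_kmers))
})

test_that("contigs respect the length filter and config validation", {
  comm <- fixture_plain_genome(len = 30000)
  sim <- simulate_short_reads(comm, total_bp = 30000 * 20, seed = 3)
  ctg <- toy_hybrid_assemble(sim$pairs, NULL)
  expect_true(all(nchar(ctg$seq) >= 1000))
  expect_error(toy_hybrid_assemble(sim$pairs, NULL, k = 30), "config error")
  expect_error(toy_hybrid_assemble(sim$pairs, NULL, k = 13), "config error")
})

test_that("external contigs are ingested like built-in ones", {
  f <- withr::local_tempfile(fileext = ".fa")
  x <- seq_set(id = c("c1", "c2", "small"),
               seq = c(random_seq(5000, 1), random_seq(2000, 2),
                       random_seq(300, 3)),
               desc = c("depth=12.5", "circular=true depth=3.0", ""),
               circular = c(FALSE, TRUE, FALSE))
  write_fasta(x, f)
  y <- read_external_contigs(f)
  expect_equal(nrow(y), 2) # 300 bp contig filtered
  expect_equal(y$depth, c(12.5, 3.0))
  expect_equal(y$circular, c(FALSE, TRUE))
})

test_that("binning separates genomes by composition and depth, purely", {
  lib <- fixture_lib()
  specs <- list(
    genome_spec("hot", 60000, gc = 0.65, abundance = 10,
                marker_count = 0, rrna_operons = 0, trna_count = 0),
    genome_spec("cold", 60000, gc = 0.35, abundance = 1,
                marker_count = 0, rrna_operons = 0, trna_count = 0))
  comm <- generate_community(specs, lib, seed = 4)
  sim <- simulate_short_reads(comm, total_bp = 60000 * 55, seed = 5)
  ctg <- toy_hybrid_assemble(sim$pairs, NULL, min_depth = 2, erode_frac = 0)
  expect_gt(nrow(ctg), 1)
  truth <- vapply(seq_len(nrow(ctg)), function(i) {
    fr <- vapply(comm$replicons$seq, function(g)
      ihamag:::cpp_kmer_vote(ctg$seq[i], g, 21L), numeric(1))
    comm$replicons$id[which.max(fr)]
  }, character(1))
  binned <- toy_bin(ctg)
  expect_gte(length(binned$bins), 2)
  for (b in binned$bins) {
    lab <- truth[match(b$contigs$id, ctg$id)]
    expect_equal(length(unique(lab)), 1) # truth-pure bins
  }
  # determinism
  binned2 <- toy_bin(ctg)
  expect_identical(lapply(binned$bins, function(b) b$contigs$id),
                   lapply(binned2$bins, function(b) b$contigs$id))
  # single contig -> single bin
  one <- toy_bin(ctg[1, , drop = FALSE])
  expect_equal(length(one$bins), 1)
})

test_that("bin refinement applies the -c 70 -x 10 gate with strict bounds", {
  lib <- fixture_lib()
  comm <- fixture_two_genomes(len = 50000)
  gA <- seq_set("gA", comm$replicons$seq[1])
  gA$depth <- 30
  class(gA) <- c("contig_set", "seq_set", "data.frame")

  # a pure full-genome bin passes untouched
  res <- refine_bins(list(list(bin_id = "b1", contigs = gA)), comm$lib)
  expect_equal(length(res$bins), 1)
  expect_equal(nrow(res$bins[[1]]$contigs), 1)

  # drop 7 of 20 markers -> completeness 65 < 70 -> dropped
  feats <- comm$features[comm$features$replicon == "gA" &
                           comm$features$type == "marker", ]
  cut <- gA
  s <- cut$seq
  for (i in 1:7) { # blank the marker copies in place
    substr(s, feats$start[i] + 1, feats$end[i]) <-
      strrep("A", feats$end[i] - feats$start[i])
  }
  cut$seq <- s
  res <- refine_bins(list(list(bin_id = "b1", contigs = cut)), comm$lib)
  expect_equal(length(res$bins), 0)

  # duplicate-marker contig in a surviving bin is reassigned to unbinned
  dup_piece <- substr(gA$seq, feats$start[1] - 500, feats$end[1] + 500)
  dup <- seq_set("dup", dup_piece)
  dup$depth <- 30
  two <- rbind(gA, dup)
  class(two) <- c("contig_set", "seq_set", "data.frame")
  res <- refine_bins(list(list(bin_id = "b1", contigs = two)), comm$lib)
  expect_equal(length(res$bins), 1)
  expect_equal(res$bins[[1]]$contigs$id, gA$id)
  expect_equal(res$unbinned$id, "dup")
})
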