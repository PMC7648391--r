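# Truth-known community generation and read simulation.

test_that("planted markers are each found exactly once by exact search", {
  lib <- fixture_lib()
  spec <- genome_spec("g", 100000, marker_count = 20)
  g <- generate_genome(spec, lib, seed = 2, divergence = 0)
  hits <- vapply(lib$markers$seq, function(m)
    length(gregexpr(m, g$chromosome$seq, fixed = TRUE)[[1]]) *
      (regexpr(m, g$chromosome$seq, fixed = TRUE) > 0), numeric(1))
  expect_true(all(hits == 1))
  # and the truth table records each planted feature once
  expect_equal(sum(g$features$type == "marker"), 20)
})

test_that("planted long repeats appear at the requested copy number", {
  comm <- fixture_plain_genome(len = 60000, repeats = list(c(2100, 13)))
  g <- comm$replicons$seq[1]
  unit <- comm$features
  unit <- unit[unit$type == "repeat", ]
  expect_equal(nrow(unit), 13)
  rep_seq <- substr(g, unit$start[1] + 1, unit$end[1])
  expect_gte(length(gregexpr(rep_seq, g, fixed = TRUE)[[1]]), 13)
})

test_that("genome generation is deterministic and rejects impossible packing", {
  lib <- fixture_lib()
  spec <- genome_spec("g", 80000)
  a <- generate_genome(spec, lib, seed = 5)
  b <- generate_genome(spec, lib, seed = 5)
  expect_identical(a$chromosome$seq, b$chromosome$seq)
  expect_identical(a$features, b$features)
  c <- generate_genome(spec, lib, seed = 6)
  expect_false(identical(a$chromosome$seq, c$chromosome$seq))

  tight <- genome_spec("t", 7000, marker_count = 20, trna_count = 20)
  expect_error(generate_genome(tight, lib, seed = 1), "element")
})

test_that("short-read simulation recovers truth loci exactly at zero error", {
  comm <- fixture_plain_genome(len = 30000)
  sim <- simulate_short_reads(comm, total_bp = 3e5, seed = 3)
  g2 <- paste0(comm$replicons$seq[1], comm$replicons$seq[1])
  idx <- sample(nrow(sim$pairs), 50)
  for (i in idx) {
    tr <- sim$truth[i, ]
    frag <- substr(g2, tr$start + 1, tr$start + 150)
    if (tr$strand == "+") expect_identical(sim$pairs$seq1[i], frag)
    else expect_identical(sim$pairs$seq2[i], frag)
  }
})

test_that("read counts follow abundance x length weights", {
  lib <- fixture_lib()
  specs <- list(
    genome_spec("hi", 40000, gc = 0.55, abundance = 0.9,
                marker_count = 0, rrna_operons = 0, trna_count = 0),
    genome_spec("lo", 40000, gc = 0.45, abundance = 0.1,
                marker_count = 0, rrna_operons = 0, trna_count = 0))
  comm <- generate_community(specs, lib, seed = 4)
  sim <- simulate_short_reads(comm, total_bp = 1e6, seed = 5)
  n <- nrow(sim$pairs)
  n_hi <- sum(sim$truth$genome == "hi")
  # binomial oracle: within 3 sd of 9:1
  expect_lt(abs(n_hi - 0.9 * n), 3 * sqrt(n * 0.9 * 0.1) + 1)
})

test_that("short-read simulation is deterministic and meets the bp request", {
  comm <- fixture_plain_genome(len = 30000)
  a <- simulate_short_reads(comm, total_bp = 2e5, seed = 9)
  b <- simulate_short_reads(comm, total_bp = 2e5, seed = 9)
  expect_identical(a$pairs, b$pairs)
  expect_lte(abs(total_bp(a$pairs) - 2e5), 300)
})

test_that("long reads honor the length filter, N50 target and error model", {
  comm <- fixture_plain_genome(len = 50000)
  sim <- simulate_long_reads(comm, total_bp = 2e6, n50_target = 9000,
                             min_len = 1000, error_rate = 0, seed = 6)
  lens <- nchar(sim$reads$seq)
  expect_true(all(lens >= 1000))
  n50 <- calc_n50(lens)
  expect_gt(n50, 0.85 * 9000)
  expect_lt(n50, 1.15 * 9000)
  # zero error: every read is an exact substring (mod circular wrap)
  g2 <- paste0(comm$replicons$seq[1], comm$replicons$seq[1])
  for (i in sample(nrow(sim$reads), 25))
    expect_true(grepl(sim$reads$seq[i], g2, fixed = TRUE) ||
                  grepl(revcomp(sim$reads$seq[i]), g2, fixed = TRUE))
  # determinism
  sim2 <- simulate_long_reads(comm, total_bp = 2e6, n50_target = 9000,
                              min_len = 1000, error_rate = 0, seed = 6)
  expect_identical(sim$reads, sim2$reads)
})

test_that("realized per-genome base fractions converge to abundance weights", {
  lib <- fixture_lib()
  specs <- list(
    genome_spec("a", 30000, gc = 0.55, abundance = 0.5, marker_count = 0,
                rrna_operons = 0, trna_count = 0),
    genome_spec("b", 30000, gc = 0.50, abundance = 0.3, marker_count = 0,
                rrna_operons = 0, trna_count = 0),
    genome_spec("c", 30000, gc = 0.45, abundance = 0.2, marker_count = 0,
                rrna_operons = 0, trna_count = 0))
  comm <- generate_community(specs, lib, seed = 8)
  sim <- simulate_short_reads(comm, total_bp = 2e6, seed = 9)
  obs <- table(factor(sim$truth$genome, levels = c("a", "b", "c")))
  p <- c(0.5, 0.3, 0.2) # equal lengths: weights = base fractions
  expect_gt(chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("divergence plants detectable but k-mer-distinct element copies", {
  lib <- fixture_lib()
  comm <- fixture_two_genomes()
  # same marker, two genomes: no shared 31-mers at default divergence
  gA <- comm$replicons$seq[1]
  gB <- comm$replicons$seq[2]
  fa <- comm$features[comm$features$replicon == "gA" &
                        comm$features$type == "marker", ][1, ]
  fb <- comm$features[comm$features$replicon == "gB" &
                        comm$features$feature_id == fa$feature_id, ]
  copy_a <- substr(gA, fa$start + 1, fa$end)
  copy_b <- substr(gB, fb$start + 1, fb$end)
  expect_equal(exact_jaccard(copy_a, copy_b, k = 31), 0)
  # both copies still pass the 95% identity scan against the library
  lib2 <- comm$lib
  ca <- marker_scan(seq_set("x", copy_a), lib2)
  expect_equal(unname(ca[fa$feature_id]), 1L)
})
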