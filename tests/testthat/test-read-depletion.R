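# Read recruitment against qualified MAGs and pool depletion.

test_that("pair recruitment implements the both-mates / orphan-filter rule", {
  comm <- fixture_plain_genome(len = 30000)
  g <- comm$replicons$seq[1]
  # a pair from the MAG, a pair from elsewhere, and a chimeric pair
  inpair <- pair_set("in", substr(g, 1001, 1150),
                     revcomp(substr(g, 1201, 1350)))
  other <- random_seq(5000, seed = 99)
  outpair <- pair_set("out", substr(other, 1, 150), substr(other, 301, 450))
  chim <- pair_set("chim", substr(g, 2001, 2150), substr(other, 1001, 1150))
  pool <- rbind(inpair, outpair, chim)
  class(pool) <- c("pair_set", "data.frame")
  res <- recruit_short(pool, g)
  expect_equal(res$recruited$pair_id, "in")
  expect_equal(res$residual$pair_id, "out")
  expect_equal(res$discarded$pair_id, "chim")

  # either-mate mode recruits the chimera instead of discarding it
  res2 <- recruit_short(pool, g, require_both = FALSE)
  expect_setequal(res2$recruited$pair_id, c("in", "chim"))
  expect_equal(nrow(res2$discarded), 0)

  # empty MAG set: everything residual
  res3 <- recruit_short(pool, character(0))
  expect_equal(nrow(res3$residual), 3)
})

test_that("long-read recruitment is inclusive at 80/80 with ANY-semantics", {
  reads <- seq_set(c("r1", "r2", "r3"),
                   c(strrep("ACGT", 250), strrep("GGCA", 250),
                     strrep("TTGC", 250)))
  al <- data.frame(
    query_id = c("r1", "r2", "r3", "r3"),
    query_len = 1000L, query_start = 0L,
    query_end = c(800L, 790L, 500L, 850L),
    strand = "+", target_id = "m", target_len = 10000L,
    target_start = 0L, target_end = 900L,
    n_matches = c(640L, 782L, 450L, 689L),
    block_len = c(800L, 790L, 500L, 850L), stringsAsFactors = FALSE)
  al$identity <- al$n_matches / al$block_len
  al$query_coverage <- (al$query_end - al$query_start) / al$query_len
  # r1: coverage 0.80, identity 0.80 exactly -> recruited (inclusive)
  # r2: coverage 0.79, identity 0.99 -> residual
  # r3: one failing and one passing alignment -> recruited (ANY)
  res <- recruit_long(reads, alignments = al)
  expect_setequal(res$recruited$id, c("r1", "r3"))
  expect_equal(res$residual$id, "r2")

  bad <- al
  bad$query_id[1] <- "ghost"
  expect_error(recruit_long(reads, alignments = bad), "unknown read id")
})

test_that("built-in long-read recruiter separates own reads from foreign", {
  comm <- fixture_plain_genome(len = 40000)
  lr <- simulate_long_reads(comm, total_bp = 3e5, n50_target = 8000,
                            error_rate = 0.02, seed = 5)
  foreign <- seq_set("f1", random_seq(8000, seed = 123))
  pool <- rbind(lr$reads, foreign)
  class(pool) <- c("seq_set", "data.frame")
  res <- recruit_long(pool, comm$replicons$seq[1])
  # reads spanning the circular origin align in two sub-threshold pieces
  # against the linearized genome; judge recall on the non-spanning rest
  linear <- lr$truth$read_id[lr$truth$start +
                               nchar(lr$reads$seq) <= 40000]
  expect_gte(mean(linear %in% res$recruited$id), 0.95)
  expect_true("f1" %in% res$residual$id)
})

test_that("pools partition the input and depletion conserves counts", {
  comm <- fixture_plain_genome(len = 30000)
  sr <- simulate_short_reads(comm, total_bp = 2e5, seed = 3)
  lr <- simulate_long_reads(comm, total_bp = 2e5, n50_target = 8000,
                            error_rate = 0.02, seed = 4)
  srp <- recruit_short(sr$pairs, comm$replicons$seq[1])
  lrp <- recruit_long(lr$reads, comm$replicons$seq[1])
  pools <- cycle_pools(srp, lrp, nrow(sr$pairs), nrow(lr$reads))
  # disjoint and exhaustive
  ids <- c(pools$recruited_pairs$pair_id, pools$residual_pairs$pair_id,
           pools$discarded_pairs$pair_id)
  expect_equal(sort(ids), sort(sr$pairs$pair_id))
  expect_equal(anyDuplicated(ids), 0)
  dep <- deplete(pools)
  expect_equal(dep$report$n_input,
               dep$report$n_recruited + dep$report$n_discarded +
                 dep$report$n_residual)
  # recruitment recall on zero-error reads of a perfect MAG
  expect_gte(dep$report$recruited_frac[1], 0.99)
})

test_that("depleting a dominant MAG enriches the rare genome past 50%", {
  lib <- fixture_lib()
  specs <- list(
    genome_spec("dom", 40000, gc = 0.58, abundance = 95,
                marker_count = 0, rrna_operons = 0, trna_count = 0),
    genome_spec("rare", 40000, gc = 0.42, abundance = 5,
                marker_count = 0, rrna_operons = 0, trna_count = 0))
  comm <- generate_community(specs, lib, seed = 6)
  sr <- simulate_short_reads(comm, total_bp = 2e6, seed = 7)
  dom_seq <- comm$replicons$seq[comm$replicons$id == "dom"]
  res <- recruit_short(sr$pairs, dom_seq)
  truth <- sr$truth$genome[match(res$residual$pair_id, sr$truth$pair_id)]
  expect_gt(mean(truth == "rare"), 0.5)
})
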