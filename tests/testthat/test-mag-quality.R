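# Marker-based completeness/contamination, cassette detection, quality
# tiers and manifest summaries.

test_that("marker scan counts planted, missing and duplicated copies", {
  lib <- fixture_lib()
  spec <- genome_spec("g", 80000, marker_count = 20)
  g <- generate_genome(spec, lib, seed = 3)
  full <- seq_set("c1", g$chromosome$seq)
  counts <- marker_scan(full, lib)
  expect_true(all(counts == 1))

  # remove two markers: 18 ones, 2 zeros
  feats <- g$features[g$features$type == "marker", ]
  s <- full$seq
  for (i in 1:2)
    substr(s, feats$start[i] + 1, feats$end[i]) <-
      strrep("G", feats$end[i] - feats$start[i])
  counts2 <- marker_scan(seq_set("c1", s), lib)
  expect_equal(sum(counts2 == 1), 18)
  expect_equal(sum(counts2 == 0), 2)

  # duplicate one marker on an extra contig
  dup <- substr(full$seq, feats$start[3] + 1, feats$end[3])
  counts3 <- marker_scan(seq_set(c("c1", "c2"), c(full$seq, dup)), lib)
  expect_equal(unname(counts3[feats$feature_id[3]]), 2L)
})

test_that("completeness/contamination follow the extra-copies convention", {
  cc <- completeness_contamination(setNames(rep(1, 20), letters[1:20]), 20)
  expect_equal(unname(cc), c(100, 0))
  cc <- completeness_contamination(c(rep(1, 18), 0, 0), 20)
  expect_equal(unname(cc), c(90, 0))
  cc <- completeness_contamination(c(rep(1, 19), 3), 20)
  expect_equal(unname(cc), c(100, 10))
})

test_that("tier classification matches the printed definitions", {
  rr <- c(`5S` = 1, `16S` = 1, `23S` = 1)
  # finished: single circular contig at HQ thresholds
  t <- classify_tier(100, 1.6, 1, TRUE, rr, 47)
  expect_equal(t$tier, "FINISHED")
  expect_true(t$high_contiguity)
  # HQ: single non-circular contig
  t <- classify_tier(98.5, 0.3, 1, FALSE, rr, 40)
  expect_equal(t$tier, "HQ")
  # completeness exactly 90 is NOT HQ (strict >)
  t <- classify_tier(90, 0.3, 1, FALSE, rr, 40)
  expect_equal(t$tier, "DQ")
  # contamination exactly 5 is not HQ either
  t <- classify_tier(95, 5, 2, FALSE, rr, 40)
  expect_equal(t$tier, "DQ")
  # DQ-except-16S is LQ
  t <- classify_tier(80, 2, 4, FALSE, c(`5S` = 1, `16S` = 0, `23S` = 1), 20)
  expect_equal(t$tier, "LQ")
  # missing tRNAs disqualifies
  t <- classify_tier(95, 1, 2, FALSE, rr, 17)
  expect_equal(t$tier, "UNQUALIFIED")
  # HC boundary: 5 contigs are HC, 6 are not
  expect_true(classify_tier(95, 1, 5, FALSE, rr, 20)$high_contiguity)
  expect_false(classify_tier(95, 1, 6, FALSE, rr, 20)$high_contiguity)
})

test_that("tier assignment is monotone in completeness and contamination", {
  rr <- c(`5S` = 1, `16S` = 1, `23S` = 1)
  rank <- c(UNQUALIFIED = 0, LQ = 1, DQ = 2, HQ = 3, FINISHED = 4)
  set.seed(10)
  for (r in 1:60) {
    comp <- runif(1, 50, 100)
    cont <- runif(1, 0, 12)
    t0 <- rank[classify_tier(comp, cont, 3, FALSE, rr, 20)$tier]
    t_up <- rank[classify_tier(min(100, comp + runif(1, 0, 20)), cont,
                               3, FALSE, rr, 20)$tier]
    t_dn <- rank[classify_tier(comp, max(0, cont - runif(1, 0, 5)),
                               3, FALSE, rr, 20)$tier]
    expect_gte(t_up, t0)
    expect_gte(t_dn, t0)
  }
})

test_that("whole truth genomes assess as complete, uncontaminated, finished", {
  lib <- fixture_lib()
  spec <- genome_spec("g", 80000)
  g <- generate_genome(spec, lib, seed = 12)
  ctg <- g$chromosome
  ctg$depth <- 30
  class(ctg) <- c("contig_set", "seq_set", "data.frame")
  qa <- assess_bin(ctg, lib)
  expect_equal(qa$completeness, 100)
  expect_equal(qa$contamination, 0)
  expect_equal(unname(qa$rrna_counts), c(1, 1, 1))
  expect_equal(qa$trna_count, 20)
  expect_equal(qa$tier, "FINISHED")
  expect_true(is_qualified(qa))
})

test_that("the packaged reference table reproduces the printed statistics", {
  chk <- reference_table_check()
  expect_equal(nrow(chk$table), 27)
  expect_equal(chk$n_hqhc, 27)
  expect_equal(chk$n_finished, 8)
  expect_equal(chk$h1_single_contig, 11)
  expect_equal(chk$h1_circular, 7)
  s <- chk$stats
  expect_equal(s$subset_n, 26)
  expect_equal(round(s$mean_n50 / 1e6, 3), 2.827)
  expect_equal(round(s$mean_completeness, 2), 97.22)
  expect_equal(round(s$sd_completeness, 2), 2.58)
  expect_equal(round(s$mean_contamination, 2), 1.00)
  expect_equal(round(s$sd_contamination, 2), 1.08)
})

test_that("manifest summaries handle subsets and the degenerate single MAG", {
  man <- data.frame(mag_id = c("H1_A", "H1_B", "H2_C"),
                    status = c("circular", "linear", "linear"),
                    n50_bp = c(3e6, 2e6, 1e6), n_contigs = c(1, 2, 3),
                    completeness = c(99, 95, 80),
                    contamination = c(0.5, 1, 3),
                    tier = c("FINISHED", "HQ", "DQ"),
                    hc = c(TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  s <- summarize_manifest(man, id_pattern = "^H1_")
  expect_equal(s$subset_n, 2)
  expect_equal(s$mean_n50, 2.5e6)
  expect_equal(s$n_hqhc, 2)
  one <- summarize_manifest(man, tiers = "DQ")
  expect_equal(one$subset_n, 1)
  expect_false(one$sd_defined)
  expect_equal(one$sd_completeness, 0)
})
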