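# Reference-based evaluation metrics: aligned blocks, NGA50, AGF/purity,
# misassemblies, gene recovery, coverage correlation.

test_that("exact substrings and reverse complements align as single blocks", {
  ref <- seq_set("ref", random_seq(20000, seed = 1))
  ctg <- seq_set("c", substr(ref$seq, 5001, 12000))
  bl <- align_to_reference(ctg, ref)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$identity, 1)
  expect_equal(bl$tstart, 5000)
  expect_equal(bl$tend, 12000)
  expect_equal(bl$qend - bl$qstart, 7000)

  rc <- seq_set("c", revcomp(ctg$seq))
  bl2 <- align_to_reference(rc, ref)
  expect_equal(nrow(bl2), 1)
  expect_equal(bl2$strand, "-")
  expect_equal(bl2$tstart, 5000)
})

test_that("substitutions are counted into mismatch rates", {
  ref <- seq_set("ref", random_seq(12000, seed = 2))
  s <- substr(ref$seq, 1001, 11000)
  for (p in c(2500, 5000, 7500)) {
    b <- substr(s, p, p)
    substr(s, p, p) <- chartr("ACGT", "GTAC", b)
  }
  bl <- align_to_reference(seq_set("c", s), ref)
  expect_equal(sum(bl$mismatches), 3)
  mism_per_mbp <- sum(bl$mismatches) / (sum(bl$qend - bl$qstart) / 1e6)
  expect_equal(round(mism_per_mbp), 300)
  expect_gt(min(bl$identity), 0.999)
})

test_that("nga50 equals a brute-force cumulative oracle on random fixtures", {
  brute_nga50 <- function(spans, ref_len) {
    spans <- sort(spans, decreasing = TRUE)
    acc <- 0
    for (s in spans) {
      acc <- acc + s
      if (acc >= ref_len / 2) return(s)
    }
    0
  }
  set.seed(33)
  for (r in 1:20) {
    n <- sample(1:12, 1)
    spans <- sample(1000:50000, n, replace = TRUE)
    ref_len <- round(sum(spans) * runif(1, 1.0, 2.5))
    blocks <- data.frame(tstart = 0, tend = spans)
    expect_equal(nga50(blocks, ref_len), brute_nga50(spans, ref_len))
  }
  # worked example: blocks of 60/30/10 kb on a 100 kb reference
  bl <- data.frame(tstart = c(0, 0, 0), tend = c(60000, 30000, 10000))
  expect_equal(nga50(bl, 100000), 60000)
  # below half coverage -> undefined, reported as 0
  expect_equal(nga50(data.frame(tstart = 0, tend = 40000), 100000), 0)
  # single full-length block
  expect_equal(nga50(data.frame(tstart = 0, tend = 70000), 70000), 70000)
})

test_that("AGF uses union semantics and purity counts unaligned contig bp", {
  ref <- seq_set("ref", random_seq(10000, seed = 3))
  ctg <- seq_set("c", ref$seq)
  bl <- align_to_reference(ctg, ref)
  ap <- agf_and_purity(bl, ctg, 10000)
  expect_equal(unname(ap["agf_pct"]), 100)
  expect_equal(unname(ap["purity"]), 1)

  # overlapping blocks counted once
  bl2 <- data.frame(contig_id = c("c", "c"), qstart = c(0, 0),
                    qend = c(6000, 6000), tstart = c(0, 2000),
                    tend = c(6000, 8000))
  ap2 <- agf_and_purity(bl2, ctg, 10000)
  expect_equal(unname(ap2["agf_pct"]), 80)

  # a 1 Mbp MAG with a 0.1 Mbp unalignable insert: purity 0.9
  big <- seq_set("m", strrep("A", 10))
  bl3 <- data.frame(contig_id = "m", qstart = 0, qend = 900000,
                    tstart = 0, tend = 900000)
  big$seq <- random_seq(1000000, seed = 4)
  ap3 <- agf_and_purity(bl3, big, 1000000)
  expect_equal(unname(ap3["purity"]), 0.9)

  # invariance to contig order and reverse-complement
  comm <- fixture_plain_genome(len = 20000, seed = 5)
  ref2 <- comm$replicons[1, , drop = FALSE]
  parts <- seq_set(c("p1", "p2"),
                   c(substr(ref2$seq, 1, 9000),
                     revcomp(substr(ref2$seq, 9501, 20000))))
  for (ord in list(1:2, 2:1)) {
    p <- parts[ord, , drop = FALSE]
    ap <- agf_and_purity(align_to_reference(p, ref2), p, 20000)
    expect_equal(unname(round(ap["agf_pct"], 1)), 97.5)
    expect_equal(unname(ap["purity"]), 1)
  }
})

test_that("misassembly counting flags fusions and inversions, not small gaps", {
  ref <- seq_set("ref", random_seq(40000, seed = 6))
  # colinear blocks with a 200 bp gap: no event
  bl <- data.frame(contig_id = "c", qstart = c(0, 5000), qend = c(4800, 9800),
                   ref_id = "ref", tstart = c(0, 5200), tend = c(4800, 10000),
                   strand = "+")
  expect_equal(count_misassemblies(bl), 0)

  # fusion of two references: 1 event
  ref_b <- seq_set("refB", random_seq(20000, seed = 7))
  fusion <- seq_set("f", paste0(substr(ref$seq, 1, 8000),
                                substr(ref_b$seq, 1, 8000)))
  bl2 <- align_to_reference(fusion, rbind(ref, ref_b))
  expect_equal(count_misassemblies(bl2), 1)

  # inverted interior segment: entry+exit strand flips = 2 events
  s <- ref$seq
  inv <- paste0(substr(s, 1, 15000),
                revcomp(substr(s, 15001, 25000)),
                substr(s, 25001, 40000))
  bl3 <- align_to_reference(seq_set("i", inv), ref)
  expect_equal(count_misassemblies(bl3), 2)

  # large reference-coordinate jump relative to contig advance
  jump <- paste0(substr(s, 1, 10000), substr(s, 20001, 30000))
  bl4 <- align_to_reference(seq_set("j", jump), ref)
  expect_equal(count_misassemblies(bl4), 1)
})

test_that("NGA50 never exceeds N50 after breakpoint fragmentation", {
  set.seed(44)
  ref <- seq_set("ref", random_seq(30000, seed = 8))
  s <- ref$seq
  fused <- paste0(substr(s, 1, 9000), substr(s, 20001, 30000))
  ctgs <- seq_set(c("a", "b"), c(fused, substr(s, 9001, 15000)))
  bl <- align_to_reference(ctgs, ref)
  n50 <- calc_n50(nchar(ctgs$seq))
  expect_lte(nga50(bl, 30000), n50)
})

test_that("gene recovery requires exact full-length protein identity", {
  lib <- fixture_lib()
  spec <- genome_spec("g", 60000, marker_count = 20)
  g <- generate_genome(spec, lib, seed = 9, divergence = 0)
  ref_orfs <- find_orfs(g$chromosome)
  ref_prot <- ref_orfs$protein
  expect_gte(length(ref_prot), 20) # at least the planted marker ORFs

  # verbatim MAG recovers 100%
  expect_equal(gene_recovery(ref_prot, g$chromosome), 100)

  # a single aa substitution in one gene loses exactly that gene
  markers <- g$features[g$features$type == "marker", ]
  s <- g$chromosome$seq
  p <- markers$start[1] + 4 # second codon, first base
  substr(s, p, p) <- chartr("ACGT", "GTAC", substr(s, p, p))
  rec <- gene_recovery(ref_prot, seq_set("m", s))
  lost <- length(ref_prot) * (100 - rec) / 100
  # the point substitution loses that gene (and possibly one overlapping
  # background ORF on the other strand), never more
  expect_gte(round(lost), 1)
  expect_lte(round(lost), 2)
})

test_that("expected coverage and the rank correlation behave at the edges", {
  expect_equal(expected_coverage(c(0.5, 0.5), c(1e6, 1e6), 10e6),
               c(5, 5))
  expect_equal(coverage_spearman(c(1, 2, 3), c(2, 4, 6))$rho, 1)
  expect_equal(coverage_spearman(c(3, 2, 1), c(2, 4, 6))$rho, -1)
  expect_false(coverage_spearman(c(1, 1, 1), c(2, 4, 6))$defined)
  expect_false(coverage_spearman(c(1, 2), c(2, 4))$defined)
})

test_that("the ORF caller honors frame, strand, starts and minimum length", {
  # one ORF on the forward strand: ATG + 32 sense codons + TAA = 102 nt
  set.seed(55)
  codons <- apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                              c("T","C","A","G")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  orf <- paste0("ATG", paste(sample(sense, 32, TRUE), collapse = ""), "TAA")
  host <- paste0(strrep("C", 501), orf, strrep("C", 400))
  res <- find_orfs(host, min_len = 90)
  fwd <- res[res$strand == "+" & res$length_nt == 102, ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$start, 501)
  expect_equal(substr(fwd$protein, 1, 1), "M")
  expect_equal(nchar(fwd$protein), 33)
  # on the reverse strand it is found with mirrored coordinates
  res_rc <- find_orfs(revcomp(host), min_len = 90)
  rev <- res_rc[res_rc$strand == "-" & res_rc$length_nt == 102, ]
  expect_equal(nrow(rev), 1)
  expect_equal(rev$protein, fwd$protein)
  # below the length floor nothing is called
  short <- paste0("ATG", paste(sample(sense, 20, TRUE), collapse = ""), "TAA")
  host2 <- paste0(strrep("C", 90), short, strrep("C", 90))
  expect_equal(nrow(find_orfs(host2, min_len = 90)), 0)
})
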