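# MinHash distances, genome pairing, gene-inventory comparison and
# dereplication.

test_that("minhash distance is 0 for identical and 1 for disjoint genomes", {
  a <- random_seq(50000, seed = 1)
  b <- random_seq(50000, seed = 2)
  sa <- minhash_sketch(a)
  sb <- minhash_sketch(b)
  expect_equal(minhash_distance(sa, sa), 0)
  expect_equal(minhash_distance(sa, minhash_sketch(a)), 0)
  expect_equal(minhash_distance(sa, sb), 1) # no shared 21-mers
  # symmetry
  expect_equal(minhash_distance(sa, sb), minhash_distance(sb, sa))
  expect_error(minhash_sketch("ACGT"), "shorter than k")
})

test_that("minhash agrees with the exact-Jaccard Mash formula", {
  mash_from_j <- function(j, k = 21) {
    if (j <= 0) return(1)
    min(1, -log(2 * j / (1 + j)) / k)
  }
  set.seed(77)
  errs <- numeric(0)
  for (r in 1:12) {
    g <- random_seq(100000, seed = 100 + r)
    # ~1% substitutions
    s <- strsplit(g, "")[[1]]
    pos <- sample(length(s), 1000)
    s[pos] <- chartr("ACGT", "GTAC", s[pos])
    g2 <- paste(s, collapse = "")
    d_est <- minhash_distance(minhash_sketch(g), minhash_sketch(g2))
    d_exact <- mash_from_j(exact_jaccard(g, g2))
    errs <- c(errs, abs(d_est - d_exact))
    expect_lt(abs(d_est - d_exact), 0.005)
  }
  # sketch Jaccard converges to exact Jaccard within 2/sqrt(s)
  expect_lt(mean(errs), 2 / sqrt(1000))
})

test_that("pairing matches same-organism assemblies and skips unrelated", {
  g1 <- random_seq(60000, seed = 5)
  g2 <- random_seq(60000, seed = 6)
  g3 <- random_seq(60000, seed = 7)
  # set A: three truth genomes; set B: slightly perturbed versions
  perturb <- function(g, n) {
    s <- strsplit(g, "")[[1]]
    pos <- sample(length(s), n)
    s[pos] <- chartr("ACGT", "CAGT", s[pos])
    paste(s, collapse = "")
  }
  set.seed(8)
  A <- list(a1 = seq_set("a1", g1), a2 = seq_set("a2", g2),
            a3 = seq_set("a3", g3))
  B <- list(b3 = seq_set("b3", perturb(g3, 300)),
            b1 = seq_set("b1", perturb(g1, 300)),
            b2 = seq_set("b2", perturb(g2, 300)))
  pr <- find_pairs(A, B)
  expect_equal(nrow(pr), 3)
  expect_true(all(substr(pr$id_a, 2, 2) == substr(pr$id_b, 2, 2)))
  expect_true(all(pr$distance <= 0.05))
  # unrelated genomes only: no pairs
  pr2 <- find_pairs(list(seq_set("x", g1)),
                    list(seq_set("y", random_seq(60000, seed = 9))))
  expect_equal(nrow(pr2), 0)
})

test_that("gene classification counts identical proteins and sets I-IV", {
  genes <- function(...) {
    x <- list(...)
    data.frame(protein = vapply(x, `[[`, character(1), 1),
               func = vapply(x, function(e)
                 if (length(e) > 1) e[[2]] else NA_character_, character(1)),
               stringsAsFactors = FALSE)
  }
  a <- genes(list("MAAA", "F1"), list("MBBB", "F2"), list("MBBC", "F2"),
             list("MCCC", "F3"), list("MHYP"))
  b <- genes(list("MAAA", "F1"), list("MBBB", "F2"), list("MDDD", "F4"),
             list("MHYP"))
  pc <- classify_genes(a, b)
  # identical proteins: MAAA, MBBB, MHYP
  expect_equal(pc$identical_gene_count, 3)
  expect_equal(pc$identical_ratio_vs_a, 100 * 3 / 5)
  expect_equal(pc$identical_ratio_vs_b, 100 * 3 / 4)
  fs <- pc$functional_sets
  expect_equal(fs$unweighted[fs$set == "I"], 1)   # F1 equal
  expect_equal(fs$unweighted[fs$set == "II"], 1)  # F2: 2 copies vs 1
  expect_equal(fs$unweighted[fs$set == "III"], 1) # F3 hybrid-only
  expect_equal(fs$unweighted[fs$set == "IV"], 1)  # F4 SR-only
  # partition invariants: unweighted sums to distinct functions,
  # weighted to the union gene count
  expect_equal(sum(fs$unweighted), pc$n_functions)
  expect_equal(sum(fs$weighted), 1 + 2 + 1 + 1)

  # identical MAGs: everything set I, ratios 100
  pc2 <- classify_genes(a, a)
  expect_equal(pc2$identical_ratio_vs_a, 100)
  expect_equal(sum(pc2$functional_sets$unweighted[
    pc2$functional_sets$set == "I"]), pc2$n_functions)
})

test_that("annotated synthetic MAG pairs classify planted functions", {
  lib <- fixture_lib()
  spec <- genome_spec("g", 60000, marker_count = 10)
  g <- generate_genome(spec, lib, seed = 21, divergence = 0)
  full <- seq_set("m", g$chromosome$seq)
  ann <- annotate_genes(full, lib)
  expect_gte(sum(!is.na(ann$func)), 10) # all planted functions labelled
  pc <- classify_genes(ann, ann)
  fs <- pc$functional_sets
  expect_equal(sum(fs$unweighted[fs$set != "I"]), 0)
})

test_that("dereplication keeps the higher-quality version per cluster", {
  g <- random_seq(50000, seed = 30)
  qa <- function(comp, cont, n, n50) {
    structure(list(completeness = comp, contamination = cont,
                   n_contigs = n, n50 = n50), class = "quality_assessment")
  }
  mags <- list(
    list(mag_id = "good", contigs = seq_set("c", g), qa = qa(97, 0.5, 1, 5e4)),
    list(mag_id = "bad", contigs = seq_set("c", substr(g, 1, 48000)),
         qa = qa(94, 0.5, 80, 2e4)),
    list(mag_id = "other", contigs = seq_set("c", random_seq(50000, seed = 31)),
         qa = qa(90, 1, 3, 3e4)))
  reps <- dereplicate(mags)
  expect_setequal(vapply(reps, `[[`, character(1), "mag_id"),
                  c("good", "other"))
  # all singletons: unchanged
  reps2 <- dereplicate(mags[c(1, 3)])
  expect_equal(length(reps2), 2)
  # tie on score and contigs: larger N50 wins
  mags3 <- list(
    list(mag_id = "zz", contigs = seq_set("c", g), qa = qa(95, 1, 2, 9e4)),
    list(mag_id = "aa", contigs = seq_set("c", g), qa = qa(95, 1, 2, 1e4)))
  reps3 <- dereplicate(mags3)
  expect_equal(reps3[[1]]$mag_id, "zz")
})
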