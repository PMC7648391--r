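# Shared fixtures: tiny communities and assemblies reused across tests.
# Everything is generated in code under fixed seeds; nothing is read from
# disk except the packaged reference table.

fixture_lib <- function(seed = 11) marker_library(n_markers = 20, seed = seed)

# two clearly separable genomes at equal abundance
fixture_two_genomes <- function(seed = 7, len = 60000) {
  lib <- fixture_lib()
  specs <- list(
    genome_spec("gA", len, gc = 0.60, abundance = 50),
    genome_spec("gB", len, gc = 0.40, abundance = 50))
  generate_community(specs, lib, seed = seed)
}

# a single clean genome with no planted elements (pure background)
fixture_plain_genome <- function(len = 50000, seed = 2, circular = TRUE,
                                 repeats = list()) {
  lib <- fixture_lib()
  spec <- genome_spec("gP", len, gc = 0.5, circular = circular,
                      marker_count = 0, rrna_operons = 0, trna_count = 0,
                      repeats = repeats)
  generate_community(list(spec), lib, seed = seed)
}

random_seq <- function(n, seed = 1, gc = 0.5) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# does `contig` exactly match a rotation of circular `genome` (either strand)?
matches_rotation <- function(contig, genome) {
  dbl <- paste0(genome, genome)
  grepl(contig, dbl, fixed = TRUE) || grepl(revcomp(contig), dbl, fixed = TRUE)
}
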