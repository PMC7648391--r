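# ihamag — iterative hybrid assembly for enrichment metagenomes

Genome-centric studies of enrichment bioreactors (for example
partial-nitritation anammox communities) want *complete* genomes, but
short-read assembly and binning deliver fragmented drafts: rRNA operons,
conserved genes and long intragenomic repeats collapse in the assembly
graph, and rare organisms drown under the dominant members' coverage.
`ihamag` implements the iterative hybrid assembly (IHA) workflow that
addresses both problems with one loop, plus the analytics used to judge
its output.

Each cycle:

1. subsamples short reads (SRs) and long reads (LRs) from the pool,
2. hybrid-assembles the draw (built-in de Bruijn assembler with
   long-read bridging, or any external assembler via the contig adapter)
   and bins the contigs by tetranucleotide composition and depth,
3. keeps only *qualified* MAGs — high quality (completeness > 90%,
   contamination < 5%, 5S/16S/23S rRNAs, ≥ 18 tRNAs) **and** high
   contiguity (≤ 5 contigs); cycle-`c` MAGs are named `H{c}_*`,
4. recruits every pool read mapping to the accumulated qualified MAGs
   and removes it, so the next cycle sees an enriched residual pool.

The loop runs until `max_cycles`, a cycle with no newly qualified MAG,
or pool exhaustion; the final set adds the last cycle's draft-quality
bins and is dereplicated by MinHash distance.

The package also provides:

* a truth-known **synthetic community generator** (genomes with planted
  single-copy markers, rRNA/tRNA cassettes, long repeats, plasmids;
  paired 150 bp SRs, log-normal nanopore-style LRs, full truth tables),
* **MAG quality emulation**: marker-based completeness/contamination,
  cassette detection and the FINISHED/HQ/DQ/LQ tier classifier,
* **reference-based evaluation**: NGA50, aligned genome fraction,
  purity, misassembly events, mismatch/indel rates, gene recovery,
  observed-vs-expected coverage correlation,
* **MAG-pair analytics**: MinHash sketches and Mash distances, genome
  pairing, identical-gene counts, functional gene sets I–IV, and
  quality-aware dereplication,
* a CLI (`inst/cli/iha`) with `simulate`, `subsample`, `assemble`,
  `run`, `evaluate` and `table1-check` subcommands.

## Worked example

The packaged benchmark community has six circular genomes (3 Mbp total)
at abundances 40/25/15/10/7/3%, one genome with a 2,100 bp repeat at 13
identical copies, and a 3-copy plasmid; pools are 200 Mbp error-free SRs
and 80 Mbp 2%-error LRs:

```r
library(ihamag)
bm <- run_benchmark(seed = 1)
bm$result$manifest
```

```
  mag_id   status size_bp n50_bp n_contigs    gc completeness contamination rrna trna     tier    hc
1 H1_B01   linear  657556 650000         2 0.618          100             0    3   20       HQ  TRUE
2 H2_B01   linear  601151 348216         4 0.402           95             0    3   20       HQ  TRUE
3 H3_B01   linear  542602 542602         1 0.557          100             0    3   20       HQ  TRUE
4 H3_B02   linear  504779 273759         3 0.285          100             0    3   20       HQ  TRUE
5 H4_B01 circular  400000 400000         1 0.472          100             0    3   19 FINISHED  TRUE
6 H5_B01   linear  281185   6930        63 0.673           90             0    3   20       DQ FALSE
```

Reading the manifest: the dominant genome is recovered in cycle 1
(`H1_*`); the 13-copy-repeat genome appears in cycle 2 with N50 348 kbp
(long-read bridging resolved the repeat that defeats SR-only assembly);
the 7% genome becomes a FINISHED circular genome in cycle 4; and the 3%
genome — invisible in cycle 1 — is rescued in cycle 5 after four rounds
of depletion.  `bm$recovery` confirms every truth genome is matched by a
final MAG at MinHash distance ≤ 0.05, and `bm$rare_fraction` shows the
rarest genome's share of the residual pool rising after every depletion.

The tier classifier reproduces the published feature table of 27 HQ-HC
MAGs from a deep-sequenced anammox enrichment:

```r
reference_table_check()$stats   # or: inst/cli/iha table1-check
```

```
MAGs: 27; HQ-HC: 27; finished (circular single-contig): 8
H1 MAGs: 11 single-contig, 7 circular
comparison subset (n=26): mean N50 2.827 Mbp; completeness 97.22 +/- 2.58%; contamination 1.00 +/- 1.08%
```

## Notes

The built-in assembler targets error-free/low-error synthetic reads (2%
LR error for bridging); production data should flow through the external
assembler adapter.  Design rationale, the generator's assumptions and
all numerical choices are documented in
`vignettes/iterative-hybrid-assembly.Rmd`.
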