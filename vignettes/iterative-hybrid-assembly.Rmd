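---
title: "Iterative hybrid assembly: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative hybrid assembly: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihamag)
```

## The problem and the method

Short-read metagenome assembly of enrichment communities (such as
partial-nitritation anammox reactors) yields fragmented genome bins:
conserved genes, rRNA operons and long intragenomic repeats collapse in
the de Bruijn graph, and rare community members drown in the coverage of
the dominant organisms.  The iterative hybrid assembly (IHA) workflow
implemented here attacks both problems with one loop:

1. **subsample** a manageable draw of short reads (SRs) and long reads
   (LRs) from the pool;
2. **hybrid-assemble** and **bin** the draw;
3. **gate** the bins: only high-quality, high-contiguity (HQ-HC) MAGs
   are *qualified* — completeness above 90%, contamination below 5%, all
   three rRNA genes, at least 18 tRNAs, and at most 5 contigs;
4. **deplete**: recruit every pool read that maps to the accumulated
   qualified MAGs and remove it, so the next cycle's draw over-represents
   whatever is not yet assembled.

Cycle-`c` MAGs are named `H{c}_*`.  The loop stops at `max_cycles`
(default 5), when a cycle qualifies no new MAG, or when the residual pool
is exhausted.  The final genome set is the accumulated qualified MAGs
plus the last cycle's draft-quality-or-better bins, dereplicated by
MinHash distance.

The package is a self-contained, testable realization of that workflow:
every stage that would normally call an external tool (assembler, binner,
CheckM, mash, QUAST) is implemented as a compact, documented algorithm
with the same contract, and an adapter ingests externally assembled
contigs whenever a production assembler is preferred.

## The synthetic community generator

All tests and the shipped benchmark run on truth-known synthetic
communities.  A community is a set of genome specifications (length, GC,
circularity, abundance weight, long-repeat elements, plasmids with copy
number) plus a marker library: `K` single-copy marker ORFs, a 5S/16S/23S
rRNA cassette trio and a set of distinct tRNA cassettes.  Each genome
plants each marker exactly once, its rRNA operon(s) as contiguous
5S+16S+23S blocks, one copy of each tRNA cassette, and its repeat
elements as identical copies at random positions; planted elements keep a
150 bp minimum spacing (intergenic background) so every junction carries
unique anchor sequence.

**Element divergence.** Each genome receives its own variant of every
library element, diverged by substitutions at *regular spacing* (default
rate 0.04, one substitution every 25 bp).  This choice has three
consequences that mirror real communities:

* detection still works — the scan identity against the library sequence
  is exactly `1 - 0.04 = 0.96`, safely above the 0.95 acceptance
  threshold of the marker scan;
* the copies of an element in two different genomes share **no** 31-mers
  (every 31 bp window contains at least one substitution, and the
  substitution patterns of two genomes essentially never coincide), so
  the de Bruijn graphs of community members stay separate, as they do for
  real inter-genus homologs;
* the k-mer-vote read recruiter cannot cross-recruit another genome's
  conserved regions, so iterative depletion does not erode the marker
  regions of not-yet-assembled genomes — the property that makes the
  real workflow's depletion safe is reproduced rather than assumed.

Setting `divergence = 0` plants elements verbatim (identical cross-genome
repeats); the unit tests use this to verify exact-search planting.

Reads: SRs are 150 bp pairs with Gaussian 350 bp inserts, sampled
proportional to abundance weight x replicon length, across the origin for
circular replicons, substitution errors only.  LRs have log-normal
lengths calibrated to an N50 target (the retained-set N50 lands within
15% of the target; reads under 1 kbp are discarded), with errors split
60/20/20 between substitutions, insertions and deletions.  Every read
carries a truth record.  What the generator does **not** emulate:
quality-score profiles, chimeric long reads, strain-level microdiversity,
and inter-genome homology gradients beyond the planted elements — so
passing tests demonstrate the pipeline's logic, not robustness to every
artifact of real sequencing.

## The built-in hybrid assembler

The assembler is intentionally compact and targets error-free or
low-error synthetic reads; the package's contribution is the iterative
loop and its analytics, not a production assembler.

* **Graph**: canonical k-mer de Bruijn graph (default `k = 31`) over the
  short reads; k-mers with count below `min_depth = 3` are dropped;
  unitigs are maximal unbranched paths.  A unitig whose path closes on
  itself is a finished circular replicon.
* **Erosion**: unitigs with mean depth below `2 x min_depth` are noise
  from organisms too rare to assemble in this cycle; they are removed so
  they cannot tangle the junctions of the assemblable genomes.  This is
  the same judgement the iterative workflow itself makes — rare genomes
  are deferred, not half-assembled.
* **Bridging**: each long read is scanned for exact k-mer anchors into
  the unitig index and segmented into colinear unitig visits.  Adjacent
  visits vote for junctions (links); visit triples spanning a middle
  unitig vote for repeat resolutions.  Junction gap estimates come from
  anchor extrapolation; since adjacent unitigs always overlap by up to
  `k-1` bases, candidate junctions with positive gap estimates (a skipped
  unitig) are rejected, and transitive links (reads that missed a small
  unitig's anchors) are reduced away.
* **Resolution** runs to a fixpoint: (i) joins whose two ends are each
  other's only unconsumed partner are applied; (ii) a triple may insert a
  *copy* of its middle unitig between its flanks, but only when the
  middle unitig's own ends show multiple partners — the signature of a
  collapsed multi-copy element; duplication of unique sequence is never
  justified.  Each resolved junction can unlock further unique joins, so
  the two passes alternate.  (iii) When the fixpoint stalls, a candidate
  whose read support is at least twice every competitor at both of its
  ends is applied (weight-majority fallback): this frees the dominant
  genome's junctions from ambiguity created by a minority genome whose
  own coverage is too low to resolve its side.
* **Emission**: paths are written with exact suffix/prefix overlap
  verification at every junction (junction sequence always comes from
  unitig copies, never from error-containing long reads); a failed
  verification splits the contig.  Contigs are circularized when the path
  closes or the terminal `k-1`-mers coincide.  Contig depth is the
  length-weighted *median* of element depths, robust to collapsed-repeat
  inserts.  Contigs under 1 kbp are discarded, matching the workflow's
  downstream filter.

Documented limitation: at the nanopore-realistic 10% LR error rate the
exact-anchor bridging loses most of its anchors; bridging-dependent tests
and the benchmark therefore use 2% LR error (e.g. corrected or
high-accuracy long reads), as stated wherever it matters.

## Binning and the quality gate

Per-contig features are the normalized tetranucleotide frequency vector
plus log10 median SR depth.  Greedy centroid clustering visits contigs
longest-first and joins a contig to the nearest centroid (cosine distance
plus `0.3 x |delta log10 depth|`) when within 0.15; otherwise contigs of
at least 2.5 kbp seed new clusters and shorter ones stay unbinned rather
than polluting a bin.  The procedure is deterministic; ties break
lexicographically.

Completeness and contamination emulate the single-copy marker logic:
completeness = percent of library markers present, contamination =
percent of extra marker copies.  Copies are counted per full-coverage
alignment chain (>= 95% identity and coverage, with identity refined by
exact comparison of the framed target segment); a marker split across a
contig break still counts as *present* when its pieces' union coverage
reaches the threshold.  Tier definitions follow the MIMAG-style reading:
"multiple rRNA genes" means at least one each of 5S/16S/23S, and all
inequalities are strict exactly as printed (> 90, < 5, > 70, < 10,
>= 18 tRNAs, <= 5 contigs).  The iterative gate defaults to HQ-and-HC;
a configurable DQ gate exists because the source workflow's wording
("only high-quality and high-contiguity MAGs are reserved") leaves the
tier requirement implicit.

## Depletion

The built-in SR recruiter is a k-mer vote (a mate maps when at least 60%
of its 21-mers occur in the combined qualified MAG set) standing in for a
sensitive aligner on synthetic data; an external aligner can be
substituted by passing mapped flags or PAF alignments.  Pair semantics
follow the unpaired-read filter: both mates mapped — recruited; one mate
— discarded (so the residual pool stays properly paired); neither —
residual.  The either-mate interpretation is available behind a flag.
Long reads are recruited when *any* alignment reaches 80% read coverage
and 80% identity, both inclusive; the built-in LR aligner uses raw chain
span for coverage so that a read anchored only on a shared cassette is
not recruited.

## Evaluation metrics

Reference-based evaluation chains exact unique 31-mer anchors (1 kbp
maximum gap), scores chain-internal gaps by global alignment, and
reports: NGA50 (aligned fragment length at which the cumulative aligned
length reaches half the reference), aligned genome fraction (union of
covered reference positions), purity (1 minus the fraction of contig
bases outside every block — the unaligned-contig-bases reading of the
ambiguous published phrase, matching the hybrid-assembler benchmark
convention the workflow cites), misassembly events (reference switch,
strand flip, or a coordinate jump exceeding 1 kbp — the conventional
extensive-misassembly threshold), and gene recovery (exact full-length
protein identity of ORFs called by a 6-frame scanner with ATG/GTG/TTG
starts and a 90 nt floor).  Mismatch and indel rates are reported per
*aligned* Mbp; the published figures do not state their denominator, so
this choice is flagged here.

MAG pairs are matched by MinHash (bottom-1000 sketches of canonical
21-mers, Mash distance formula) with greedy minimum-distance matching at
0.05 (about 95% ANI; the source text names no threshold).
Dereplication clusters at the same distance by single linkage and keeps
the representative maximizing `completeness - 5 x contamination` (the
dRep convention; "higher quality" is otherwise undefined), breaking ties
by fewer contigs, then larger N50, then id.  In the functional-set
comparison of a hybrid/SR-only MAG pair, set I holds functions present in
both without a hybrid excess, set II functions with more copies in the
hybrid MAG, sets III/IV functions exclusive to one side; the rare case of
a function with *more* copies in the SR-only MAG is kept in set I so that
the four sets partition the function universe.

## The six-genome benchmark

`run_benchmark()` builds the packaged study community: six circular
genomes totalling 3 Mbp at abundances 40/25/15/10/7/3%, GC spread so
depth-adjacent genomes differ in composition, one dominant genome
carrying a 2,100 bp repeat at 13 identical copies (the structure that
keeps the anammox chromosome fragmented in SR-only assemblies) and the
most abundant genome carrying a 3-copy plasmid.  Pools are 200 Mbp of
error-free SRs and 80 Mbp of 2%-error LRs (N50 15 kbp); cycle 1 draws
30 Mbp SR + 25 Mbp LR and later cycles draw 100k pairs + 2,000 LRs, the
same shape as the reference workflow's 6 Gbp/22 Gbp initial and
20M-pair/1M-read later draws, scaled to desk size.  At seed 1 the run
recovers all six genomes — the dominant in cycle 1, the 13-copy-repeat
genome in cycle 2, and the 3% genome in cycle 5 — with five of six as
HQ-HC MAGs, in about two minutes on one CPU.  These sizes were chosen
once as the smallest community that exercises every mechanism
(repeat bridging, plasmid recovery, depth-based deferral, multi-cycle
rescue); they are the package's study conditions, not tuned quantities.

```{r, eval = FALSE}
bm <- run_benchmark(seed = 1)
bm$result$manifest
bm$recovery        # earliest recovering cycle per truth genome
bm$rare_fraction   # residual-pool share of the rarest genome, per cycle
```

## Numerical choices and degenerate inputs

* All coordinates are 0-based half-open; conversion happens only at file
  boundaries.  FASTA is written 60-column wrapped; circularity is a
  `circular=true` description key (FASTA has no standard); FASTQ is
  phred-33.
* Subsampling is an explicit seeded RNG permutation, not hash-based
  sampling — simpler and equally deterministic; a bp-targeted pair draw
  meets the request to within one pair.
* Every stage derives its own child seed from the run seed keyed by a
  stable stage name, so adding a stage never perturbs unrelated streams.
* The sample standard deviation over a single MAG is undefined and
  reported as 0 with a flag; Spearman's rho needs at least three
  non-constant points and is flagged otherwise; NGA50 below 50% aligned
  is reported as 0.
* Tie-breaks everywhere (binning order, dereplication, assembler
  candidate order) are lexicographic for determinism.

## Known limitations

The toy assembler neither error-corrects nor scaffolds with paired-end
inserts; it requires low LR error for bridging.  The marker library is
synthetic: completeness/contamination emulate the single-copy-gene logic
but not lineage-specific marker sets, so absolute values are not
comparable to CheckM on real genomes.  The k-mer-vote recruiter is not a
replacement for a real aligner on error-rich reads.  Taxonomy,
annotation, and polishing are out of scope; external assemblers and
aligners plug in through the contig adapter and PAF inputs.
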