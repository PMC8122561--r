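---
title: "Comparative plastome analysis with plastcomp: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcomp)
```

## The problem

Land-plant chloroplast genomes (plastomes) are circular molecules of
roughly 120--220 kb with a strongly conserved quadripartite architecture: a
large single-copy region (LSC), a small single-copy region (SSC), and two
identical inverted repeats (IRa, IRb) separating them.  Comparative studies
of a genome panel typically ask four questions:

1. How do the region lengths, GC contents and gene complements vary across
   the panel (IR expansion/contraction being the main driver of genome-size
   differences)?
2. Which genes sit on, or near, the four IR/SC junctions, and at what
   distance?
3. Which homologous loci (genes, introns, intergenic spacers) are most
   variable across taxa -- the hypervariable regions proposed as DNA
   barcodes?
4. Do the resulting distances produce a sane phylogenetic signal?

`plastcomp` implements this pipeline as composable functions with a
synthetic-data generator that provides exact ground truth for every stage,
so each computation is testable without downloading genomes.

## Quadripartite detection

`detect_inverted_repeat()` treats the sequence as circular and finds the
longest pair of disjoint, reverse-complementary segments by seed-and-extend:
24-mers sampled from the doubled sequence at a stride of
`min_ir_len - 23` (so any repeat of at least `min_ir_len` bp must contain a
sampled seed) are matched exactly against the reverse complement, and every
hit is extended to its maximal common substring.  With the default
`max_mismatch = 0` the contract is exact: the reported IR is the maximal
pair, `IRa` is byte-for-byte the reverse complement of `IRb`, and the four
region lengths tile the genome.  Candidates of equal maximal length are
resolved by smallest start coordinate (logged), and a genome without a
repeat of at least `min_ir_len` bp (default 1000 -- comfortably below real
plastome IRs of ~10--45 kb, but above incidental repeats) raises a `no-IR`
error rather than guessing; IR loss is a real phenomenon in some lineages
and should surface as an explicit condition.

The single-copy gaps between the two repeat copies are oriented purely by
length: the longer gap is the LSC.  Equal gaps are biologically implausible
and raise an error.  The linearization is then normalized to start at the
first LSC base, which makes the four junctions well-defined:

* `JLB` (LSC/IRb), `JSB` (IRb/SSC), `JSA` (SSC/IRa), `JLA` (IRa/LSC).

All coordinates are 0-based half-open internally and 1-based inclusive in
anything written for humans (TSV, GenBank).  The partition records the
`offset` of the canonical origin in the input, so detection is
rotation-invariant while reports stay comparable across genomes.

## Junction reports

For each junction, `junction_report()` emits the spanning gene if one
exists (distance 0, with the bp of the gene on each side of the boundary),
otherwise the nearest gene on each side within `flank_window` (default
1500 bp, wide enough to capture the conventional junction markers --
`rps19`, `rpl2`, `trnH` at the LSC ends, `ndhF`/`ycf1` around the SSC).
Distances are measured to the outermost endpoint of the (possibly
compound) feature; whether annotated stop codons or introns are inside
that span is deliberately not second-guessed, because annotation practice
varies between depositors.  When two genes tie for nearest, both are
reported in coordinate order.

## Locus extraction and the filter

`extract_loci()` produces three locus classes per genome, on the canonical
linearization:

* **coding**: exon intervals concatenated in genome order, minus-strand
  genes reverse-complemented; of an IR-duplicated gene only the IRb copy
  is used (the copies are identical under exact IR detection);
* **introns**: the gaps between consecutive exon intervals of a compound
  gene, named `gene-intron1`, `gene-intron2`, ...;
* **intergenic spacers**: the sequence between consecutive gene spans,
  named `geneA-geneB` in plus-strand linearized order regardless of the
  genes' own strands; overlapping genes produce no spacer.

Because a plastome and its reverse complement are the same molecule,
genomes are re-oriented before extraction: each genome's gene strands are
compared with the first genome's, and if the majority of shared genes
disagree the genome is flipped and re-rotated.  This makes extraction
invariant under deposition orientation, which the test suite checks
explicitly.  Loci present in fewer than two genomes are dropped with a
message.

The variability filter keeps loci whose aligned length is strictly greater
than 200 bp and which contain at least one polymorphic column.  The length
rule is strict because "greater than" is the natural reading of the
threshold; both thresholds are arguments (`min_len`,
`min_variable_sites`) because reasonable analyses vary them.  A column is
polymorphic only if it carries two or more distinct *unambiguous* bases --
gaps and IUPAC codes never create polymorphism.

Alignment itself is delegated: panels that differ only by substitutions
(the simulator's output) are already aligned, and anything else should be
aligned with a dedicated tool and ingested via `ingest_alignment()`.
Correctness of the downstream statistics is therefore independent of any
aligner's behaviour.

## Diversity statistics

For an alignment of `n` sequences, under the default **complete deletion**
policy every column containing a gap or ambiguity code is removed first,
leaving `L_net` columns; this matches the default behaviour of the
standard polymorphism software that such tables are compared against.  On
the retained columns:

* `S` -- number of segregating (polymorphic) sites;
* `Eta` -- total number of mutations, counting `k - 1` per column with `k`
  alleles (so `Eta >= S`, with equality when all sites are biallelic);
* `h` -- number of distinct haplotypes, and
  `Hd = (n/(n-1)) (1 - sum p_k^2)` the haplotype diversity with
  small-sample correction;
* `Pi = (2/(n(n-1))) sum_{i<j} d_ij / L_net` -- nucleotide diversity per
  site, with `d_ij` the count of differing retained columns;
* `PIC` -- parsimony-informative columns: at least two alleles, each
  carried by at least two sequences.

`pairwise_deletion` is offered as an option: site statistics then treat
non-ACGT cells as missing and each pair's distance is normalized by that
pair's comparable columns.  An alignment whose every column is removed
reports `NA` statistics, never zeros: "no information" and "no variation"
are different statements.  `Pi` is written with five decimals in TSV
output.

The implementation is verified against an independent naive
`O(n^2 L)` reference on hundreds of random alignments (n up to 8, L up to
200, with random gaps and Ns) in the test suite and the acceptance script.

## Hotspot ranking and identity profiles

`rank_hotspots()` sorts loci by decreasing `Pi` within each category
(coding / noncoding), breaking ties lexicographically by name so output is
deterministic.  The number of reported candidates per category is a user
parameter (the `run_pipeline()` preset of 9 coding + 12 noncoding mirrors
the common barcode-screening convention of reporting roughly the top ten
per class); no `Pi` threshold is hardcoded because none generalizes across
panels.

`identity_profile()` produces an mVISTA-style sliding-window percent
identity against a chosen reference row: per window,
`100 * matches / (matches + mismatches)` over columns where neither row has
a gap or ambiguity code; windows without comparable columns are `NA`.  The
defaults -- window 100, step 25 alignment columns -- resolve locus-scale
divergence without excessive noise; both are parameters.

## The sanity tree

`p_distance_matrix()` (complete deletion, `d_ij` = differing / retained
columns) and `nj_tree()` exist so that locus outputs can be smoke-tested
end to end: neighbour joining recovers additive matrices exactly, which
gives a sharp correctness contract, and clade structure planted by the
simulator must come back monophyletic.  Labels are sorted before joining
for deterministic tie-breaking, and negative branch lengths are clamped to
zero.  Maximum-likelihood and Bayesian inference, bootstrap and dating are
deliberately out of scope -- they are cluster-scale jobs for dedicated
tools, not package primitives.

## The synthetic generator

`simulate_panel()` builds an ancestor with exact `IRa = revcomp(IRb)`,
annotates it from a layout covering every structural case (single-copy
genes on both strands, a compound-location case via the junction genes,
IR-duplicated genes with mirrored IRa copies, and genes spanning JLB, JSB
and JSA), then derives each taxon by independent Bernoulli-per-site
substitutions with equal-probability base changes -- a Jukes--Cantor-style
single-branch model.  IR sites are mutated once on IRb and mirrored, so
the IR invariant holds in every taxon.  Optional families add one shared
round of mutations on a clade branch before the taxon branches, making
within-family distances about half of between-family distances.

Defaults: 6 taxa, LSC 8000 bp, IR 2000 bp, SSC 1500 bp, background rate
0.005 substitutions per site per branch.  The region sizes are a
deliberately scaled-down plastome that preserves the real ordering
LSC > IR > SSC and keeps hundreds of seeded replicates cheap; the
background rate is of the order of the per-locus divergence seen across a
family-level plastome panel, and hotspot experiments plant a 10x locus
(0.05) against it.  Under this model the expected per-site difference
between two taxa is `2*mu*(1 - 2*mu/3)`, which the suite checks against
observed `Pi` within three standard errors.

Two technical details keep the ground truth exact.  First, the four
single-copy bases abutting the junctions are excluded from mutation and
the ancestor is adjusted so the repeat cannot extend by chance across a
boundary: without this, roughly one panel in two would have a genome whose
*maximal* repeat is one base longer than constructed, and boundary
recovery would not be exactly testable.  Second, substitutions are the
only mutation type, so the true per-locus alignments are the extracted
sequences themselves.

What the generator does **not** emulate -- and what passing tests
therefore do not show about real data: indels and alignment uncertainty,
rate heterogeneity within a locus, base-composition bias, SSC
orientation flip-flop within a species, pseudogenization at junctions,
and annotation error.  The GenBank parser is likewise a minimal reader for
well-formed organellar records, not a general-purpose one.

## The packaged reference panel

`myrtales_panel()` returns a literature-transcribed summary of 92 Myrtales
plastomes (six families; optionally three Geraniales outgroups) with
region lengths, gene-class counts and GC percentages, used for
desk-checkable range/mean arithmetic:

```{r}
tab <- myrtales_panel()
range_summary(tab, c("genome_size", "lsc_len", "ssc_len", "ir_len"))
```

A number of printed rows do not satisfy
`genome_size = lsc + ssc + 2*ir` (transcribed faithfully; the
`tiling_consistent` column flags them).  They are retained for range
summaries -- the published extremes are themselves computed over the
printed values -- but excluded from any identity-based check.  One flagged
row carries an IR length of 36,747 bp that is inconsistent with its own
genome size by exactly 20 kb; range widths over the printed IR column
(12,846 bp) inherit that value, which is reported as printed, not
reconciled.

## Problem sizes and determinism

Every stochastic check runs under a fixed or derived seed: synthetic
panels are reproducible byte-for-byte from `seed`, `run_pipeline()` logs
its seed and parameters, and reruns produce identical artifacts.  The
shipped verification uses 50 structure/junction panels, 100 hotspot
replicates, 200 oracle alignments, 25 NJ matrices and 250 filter panels --
sizes chosen so the full suite runs in a few minutes on one core while
keeping binomial noise far from the asserted margins.

## Known limitations

* IR detection assumes one dominant inverted repeat; plastomes with
  near-equal secondary repeats are resolved by the tie rule, not by
  biology.
* `max_mismatch > 0` extends boundaries greedily past isolated mismatches;
  it is off by default and the exactness contract applies only to 0.
* The orientation vote in `extract_loci()` needs annotations; FASTA-only
  panels cannot be re-oriented.
* Spacer names use gene symbols verbatim; two genes whose names themselves
  contain `-` (anticodon suffixes) produce spacer names that need care
  when parsed back.
* Family-mean tables published elsewhere may not be reproducible from
  their own per-genome rows; `range_summary()` reports what it computes
  from the table it is given.
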