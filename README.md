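# plastcomp

Comparative analysis of chloroplast genomes (plastomes) for plant
molecular systematics: quadripartite structure detection, IR/SC junction
mapping, homologous-locus extraction, nucleotide-diversity hotspot
ranking, and a fully seeded synthetic plastome generator that gives every
stage exact ground truth.

## Who this is for

Researchers comparing a panel of annotated plastomes -- typically at the
genus-to-order scale -- who want the standard descriptive pipeline
(region lengths and GC, gene census, junction genes, per-locus
variability, barcode candidates) as reproducible, tested R functions
rather than a chain of GUI tools.

## What it computes

A plastome is a circular molecule partitioned as LSC | IRb | SSC | IRa
with IRa the reverse complement of IRb.  `plastcomp`:

* detects the inverted repeat from raw sequence (exact seed-and-extend
  against the reverse complement, circular, rotation-invariant) and
  partitions the genome;
* reports, for each junction JLB/JSB/JSA/JLA, the spanning gene or the
  nearest flanking genes with their distances;
* extracts homologous coding loci, introns and intergenic spacers across
  the panel and applies the aligned-length > 200 bp, >= 1 variable site
  filter;
* computes per-locus diversity statistics under complete deletion:
  segregating sites *S*, total mutations *η* (k−1 per k-allele site),
  haplotype number *h* and diversity
  *Hd = n/(n−1) · (1 − Σ p²)*, nucleotide diversity
  *π = 2/(n(n−1)) · Σ_{i<j} d_ij / L*, and parsimony-informative sites;
* ranks hypervariable barcode candidates by *π* within coding and
  noncoding categories;
* builds mVISTA-style sliding-window identity profiles and a
  p-distance / neighbour-joining sanity tree.

The synthetic generator (`synthetic_panel_spec()` / `simulate_panel()`)
emits GenBank-format panels with known region boundaries, junction genes,
IR-duplicated genes and per-locus substitution rates, reproducible
byte-for-byte from a seed.

## Worked example

Six synthetic taxa with one locus (`matK`) planted at ten times the
background substitution rate:

```r
library(plastcomp)

sp  <- synthetic_panel_spec(n_taxa = 6, seed = 42,
                            per_locus_rate = c(matK = 0.05))
pan <- simulate_panel(sp)

part <- detect_inverted_repeat(pan$records[[1]])
part
#> <quadripartite_partition> 13,500 bp
#>   LSC [0,8000) 8000 bp | IRb [8000,10000) 2000 bp | SSC [10000,11500) 1500 bp | IRa [11500,13500) 2000 bp
#>   canonical origin at input position 0

junction_report(pan$records[[1]], part)
#>   accession junction     gene placement distance overlap_left overlap_right
#> 1     SIM01      JLB    rps19     spans        0          140           139
#> 2     SIM01      JSB     ndhF     spans        0          200           500
#> 3     SIM01      JSA     ycf1     spans        0          450           400
#> 4     SIM01      JLA     rpl2   left_of      200            0             0
#> 5     SIM01      JLA trnH-GUG  right_of       40            0             0

kept <- filter_loci(loci_as_alignments(extract_loci(pan$records)))
div  <- diversity_table(kept)
rank_hotspots(div, top_coding = 3, top_noncoding = 3)$coding
#>   rank name n    L   S Eta h Hd      Pi PIC
#> 1    1 matK 6 1530 413 451 6  1 0.09874  18
#> 2    2 ndhD 6  450  21  21 6  1 0.01556   0
#> 3    3 psbA 6 1062  45  45 6  1 0.01412   0
```

The partition tiles the 13,500 bp genome exactly; `rps19`, `ndhF` and
`ycf1` are correctly reported as spanning their junctions with the
constructed overlaps; and the planted hotspot `matK` ranks first with
*π* ≈ 0.099, an order of magnitude above the background loci -- consistent
with a 0.05 vs 0.005 per-branch rate.

`run_pipeline(run_config(...))` runs all stages on a directory of GenBank
files (or in-memory records) and writes the structure table, junction
table, filtered locus list, diversity table, hotspot rankings, identity
profile, NJ tree and a JSON run log.  A thin CLI over these functions is
installed at `inst/scripts/plastome-compare`.

The package also ships `myrtales_panel()`, a literature-transcribed
summary table of 92 Myrtales plastomes used for desk-checkable range and
mean arithmetic (see the methods vignette for its caveats).

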