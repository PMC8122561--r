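# IR detection, partition invariants, region profiles, census, panel summary

test_that("constructed IR boundaries are recovered exactly", {
  set.seed(201)
  g <- constructed_ir_genome(lsc = 8000, ir = 2000, ssc = 1500)
  rec <- plastome_record("C1", g$sequence)
  part <- detect_inverted_repeat(rec)
  expect_identical(unname(partition_lengths(part)),
                   c(8000L, 2000L, 1500L, 2000L))
  expect_identical(part$offset, 0L)
  expect_identical(part$lsc, c(0L, 8000L))
  expect_identical(part$ira, c(11500L, 13500L))
})

test_that("partition tiling and IR self-complementarity hold on random panels", {
  set.seed(202)
  for (rep in 1:5) {
    g <- constructed_ir_genome(lsc = sample(4000:9000, 1),
                               ir = sample(1200:2500, 1),
                               ssc = sample(800:1800, 1))
    rec <- plastome_record("P1", g$sequence)
    part <- detect_inverted_repeat(rec)
    lens <- partition_lengths(part)
    expect_identical(sum(lens), nchar(g$sequence))
    expect_identical(lens[["irb"]], lens[["ira"]])
    expect_gt(lens[["lsc"]], lens[["ssc"]])
    seq_c <- canonicalize_record(rec, part)$sequence
    irb <- substr(seq_c, part$irb[1] + 1, part$irb[2])
    ira <- substr(seq_c, part$ira[1] + 1, part$ira[2])
    expect_identical(revcomp(irb), ira)
  }
})

test_that("detection is invariant under circular rotation", {
  set.seed(203)
  g <- constructed_ir_genome(lsc = 6000, ir = 1500, ssc = 1000)
  rec <- plastome_record("R0", g$sequence)
  base <- partition_lengths(detect_inverted_repeat(rec))
  for (off in c(1L, 999L, 6000L, 9137L)) {
    rot <- plastome_record("R1", rotate_sequence_str(g$sequence, off))
    expect_identical(partition_lengths(detect_inverted_repeat(rot))[["lsc"]],
                     base[["lsc"]])
    expect_identical(partition_lengths(detect_inverted_repeat(rot))[["ssc"]],
                     base[["ssc"]])
  }
})

test_that("a sequence without a long inverted repeat raises the no-IR error", {
  set.seed(204)
  rec <- plastome_record("N1", random_seq(10000))
  expect_error(detect_inverted_repeat(rec, min_ir_len = 1000), "no-IR")
})

test_that("region GC excludes ambiguity codes and matches direct counting", {
  expect_identical(gc_fraction("GCGC"), 1)
  expect_identical(gc_fraction("ATATN"), 0)
  set.seed(205)
  s <- random_seq(1000)
  v <- strsplit(s, "")[[1]]
  expect_identical(gc_fraction(s), sum(v %in% c("G", "C")) / 1000)
})

test_that("region profiles report LSC, SSC, IR and total on the partition", {
  set.seed(206)
  g <- constructed_ir_genome()
  rec <- plastome_record("G1", g$sequence)
  part <- detect_inverted_repeat(rec)
  prof <- region_profiles(rec, part)
  expect_setequal(prof$region, c("LSC", "SSC", "IR", "total"))
  expect_identical(prof$length[prof$region == "IR"], 2000L)
  expect_identical(prof$length[prof$region == "total"], 13500L)
  lsc_seq <- substr(g$sequence, 1, 8000)
  expect_equal(prof$gc[prof$region == "LSC"], gc_fraction(lsc_seq))
})

test_that("gene census deduplicates IR copies, rps12 and pseudogenes", {
  g <- constructed_ir_genome(lsc = 4000, ir = 1500, ssc = 1000)
  feats <- list(
    gene_feature("geneA", "CDS", "+", c(100L, 700L)),
    gene_feature("geneB", "tRNA", "-", c(900L, 980L)),
    gene_feature("geneC", "CDS", "+", c(5700L, 6200L)),          # SSC
    gene_feature("dupD", "rRNA", "+", c(4200L, 4700L)),          # IRb
    gene_feature("dupD", "rRNA", "-", c(6800L, 7300L)),          # IRa
    gene_feature("rps12", "CDS", "+", c(200L, 300L)),
    gene_feature("rps12", "CDS", "+", c(2000L, 2100L)),
    gene_feature("deadE", "CDS", "+", c(3000L, 3300L), pseudo = TRUE))
  rec <- plastome_record("CEN1", g$sequence, features = feats)
  part <- detect_inverted_repeat(rec)
  cen <- gene_census(rec, part)
  expect_identical(cen$n_total, 5L)
  expect_identical(cen$n_cds, 3L)   # geneA, geneC, rps12
  expect_identical(cen$n_trna, 1L)
  expect_identical(cen$n_rrna, 1L)
  expect_identical(cen$n_ir_duplicated, 1L)
  expect_identical(cen$ir_duplicated, "dupD")

  empty <- plastome_record("CEN2", g$sequence)
  cen0 <- gene_census(empty, part)
  expect_identical(cen0$n_total, 0L)
})

test_that("summarize_panel matches simulator ground truth", {
  sp <- synthetic_panel_spec(n_taxa = 3, seed = 207)
  pan <- simulate_panel(sp)
  tab <- summarize_panel(pan$records)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$accession, sort(tab$accession))
  expect_true(all(tab$lsc_len == sp$lsc_len))
  expect_true(all(tab$ssc_len == sp$ssc_len))
  expect_true(all(tab$ir_len == sp$ir_len))
  expect_true(all(tab$genome_size ==
                    tab$lsc_len + tab$ssc_len + 2L * tab$ir_len))
  expect_true(all(tab$n_rrna == 1L))
})

test_that("range_summary equals a direct scan", {
  set.seed(208)
  tab <- data.frame(a = sample(1:1000, 20), b = runif(20))
  rs <- range_summary(tab)
  expect_equal(rs$min[rs$column == "a"], min(tab$a))
  expect_equal(rs$width[rs$column == "a"], max(tab$a) - min(tab$a))
  expect_equal(rs$mean[rs$column == "b"], mean(tab$b))

  one <- tab[1, , drop = FALSE]
  rs1 <- range_summary(one)
  expect_true(all(rs1$width == 0))
  expect_error(range_summary(tab[0, ]), "empty")
})
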