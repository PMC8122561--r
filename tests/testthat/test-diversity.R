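# nucleotide-diversity statistics, hotspot ranking, identity profiles

test_that("hand-computed example: rows AAAA/AAAT/AATT", {
  aln <- locus_alignment(c(A = "AAAA", B = "AAAT", C = "AATT"), name = "ex")
  st <- diversity_stats(aln)
  # pairwise diffs 1 + 2 + 1 = 4; Pi = (2/(3*2)) * 4 / 4 = 1/3
  expect_equal(st$Pi, 1 / 3, tolerance = 1e-12)
  expect_identical(st$S, 2L)
  expect_identical(st$Eta, 2L)
  expect_identical(st$h, 3L)
  expect_equal(st$Hd, 1)
  expect_identical(st$PIC, 0L)   # no column carries two alleles twice each
})

test_that("identical rows give zero diversity; distinct rows give Hd = 1", {
  aln <- locus_alignment(stats::setNames(rep("ACGTACGT", 5), paste0("T", 1:5)))
  st <- diversity_stats(aln)
  expect_identical(st$S, 0L)
  expect_equal(st$Pi, 0)
  expect_identical(st$h, 1L)
  expect_equal(st$Hd, 0)

  aln2 <- locus_alignment(c(a = "AAAA", b = "CCCC", c = "GGGG", d = "TTTT"))
  st2 <- diversity_stats(aln2)
  expect_identical(st2$h, 4L)
  expect_equal(st2$Hd, 1)
})

test_that("complete deletion removes gap/N columns before all statistics", {
  aln <- locus_alignment(c(a = "A-GTN", b = "ACGTA", c = "ACTTC"), name = "g")
  st <- diversity_stats(aln)
  expect_identical(st$L_net, 3L)          # columns 1, 3, 4 retained
  expect_identical(st$S, 1L)              # only the G/G/T column varies
  # all-gap outcome is NA, not zero
  aln0 <- locus_alignment(c(a = "--", b = "A-", c = "-N"))
  st0 <- diversity_stats(aln0)
  expect_identical(st0$L_net, 0L)
  expect_true(is.na(st0$Pi) && is.na(st0$S) && is.na(st0$Hd))
})

test_that("optimized statistics equal the naive oracle on random alignments", {
  set.seed(501)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    L <- sample(5:200, 1)
    aln <- random_alignment(n, L, p_gap = runif(1, 0, 0.1),
                            p_n = runif(1, 0, 0.05))
    ref <- naive_diversity(aln$rows)
    st <- diversity_stats(aln)
    if (is.null(ref)) {
      expect_identical(st$L_net, 0L)
      next
    }
    expect_identical(st$L_net, ref$L_net)
    expect_identical(st$S, ref$S)
    expect_identical(st$Eta, ref$Eta)
    expect_identical(st$h, ref$h)
    expect_equal(st$Hd, ref$Hd, tolerance = 1e-12)
    expect_equal(st$Pi, ref$Pi, tolerance = 1e-12)
    expect_identical(st$PIC, ref$PIC)
  }
})

test_that("Eta counts k-1 per multi-allelic site and exceeds S when k > 2", {
  aln <- locus_alignment(c(a = "AC", b = "CC", c = "GC", d = "TC"))
  st <- diversity_stats(aln)
  expect_identical(st$S, 1L)
  expect_identical(st$Eta, 3L)
})

test_that("adding a mutated copy of an existing row never decreases S", {
  set.seed(502)
  for (rep in 1:10) {
    aln <- random_alignment(sample(2:5, 1), 60)
    s0 <- diversity_stats(aln)$S
    v <- strsplit(aln$rows[[1]], "")[[1]]
    at <- sample(60, 3)
    v[at] <- sample(BASES, 3, replace = TRUE)
    rows2 <- c(aln$rows, new = paste(v, collapse = ""))
    s1 <- diversity_stats(locus_alignment(rows2))$S
    expect_gte(s1, s0)
  }
})

test_that("pairwise deletion normalizes each pair by its comparable columns", {
  aln <- locus_alignment(c(a = "AAAA", b = "AAT-", c = "A-TA"))
  st <- diversity_stats(aln, gap_policy = "pairwise_deletion")
  # pairs: a-b over 3 cols (1 diff), a-c over 3 cols (1 diff), b-c over 2 (0)
  expect_equal(st$Pi, mean(c(1 / 3, 1 / 3, 0)), tolerance = 1e-12)
})

test_that("hotspot ranking sorts by Pi with lexicographic tie-break per category", {
  stats <- data.frame(
    name = c("b", "a", "c", "z", "y"),
    category = c("coding", "coding", "coding", "noncoding", "noncoding"),
    Pi = c(0.02, 0.02, 0.5, 0.1, 0.3), stringsAsFactors = FALSE)
  hs <- rank_hotspots(stats)
  expect_identical(hs$coding$name, c("c", "a", "b"))
  expect_identical(hs$noncoding$name, c("y", "z"))
  top <- rank_hotspots(stats, top_coding = 1, top_noncoding = 1)
  expect_identical(top$coding$name, "c")
  expect_identical(nrow(top$noncoding), 1L)
})

test_that("a locus simulated at 10x the background rate ranks first", {
  sp <- synthetic_panel_spec(n_taxa = 6, seed = 503,
                             per_locus_rate = c(matK = 0.05))
  pan <- simulate_panel(sp)
  kept <- filter_loci(loci_as_alignments(extract_loci(pan$records)))
  div <- diversity_table(kept)
  expect_identical(div$name[which.max(div$Pi)], "matK")
})

test_that("identity profiles count comparable columns only", {
  rows <- c(ref = strrep("A", 100), q = strrep("A", 100))
  aln <- locus_alignment(rows, name = "win")
  prof <- identity_profile(aln, "ref", window = 100, step = 25)
  expect_true(all(prof$identity == 100))

  v <- strsplit(rows[["q"]], "")[[1]]
  v[50] <- "C"
  aln2 <- locus_alignment(c(ref = rows[["ref"]], q = paste(v, collapse = "")))
  prof2 <- identity_profile(aln2, "ref", window = 100, step = 25)
  expect_equal(prof2$identity[1], 99.0)

  v[60] <- "-"   # gap columns leave the denominator
  aln3 <- locus_alignment(c(ref = rows[["ref"]], q = paste(v, collapse = "")))
  prof3 <- identity_profile(aln3, "ref", window = 100, step = 25)
  expect_equal(prof3$identity[1], 100 * 98 / 99)

  expect_error(identity_profile(aln, "missing"), "reference")
})

test_that("windows tile the alignment with the requested step", {
  set.seed(504)
  aln <- random_alignment(3, 260)
  prof <- identity_profile(aln, "T01", window = 100, step = 25)
  starts <- sort(unique(prof$start))
  expect_equal(starts, seq(0, 160, by = 25))
  expect_true(all(prof$end - prof$start <= 100))
  expect_true(all(prof$identity >= 0 & prof$identity <= 100, na.rm = TRUE))
})
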