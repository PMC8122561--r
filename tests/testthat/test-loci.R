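# homologous-locus extraction, alignment ingest, filtering

two_gene_records <- function(seed = 401) {
  set.seed(seed)
  lapply(c("G1", "G2"), function(acc) {
    g <- constructed_ir_genome(lsc = 5000, ir = 1500, ssc = 1000)
    feats <- list(
      gene_feature("geneA", "CDS", "+", c(1000L, 1600L)),
      gene_feature("geneB", "CDS", "-", c(2100L, 2700L)))
    plastome_record(acc, g$sequence, features = feats)
  })
}

test_that("coding loci and the spacer between two shared genes are extracted", {
  recs <- two_gene_records()
  loci <- extract_loci(recs)
  nm <- vapply(loci, `[[`, "", "name")
  expect_true(all(c("geneA", "geneB", "geneA-geneB") %in% nm))
  ab <- loci[[which(nm == "geneA-geneB")]]
  expect_identical(ab$category, "noncoding")
  expect_identical(unname(nchar(ab$sequences)), c(500L, 500L))
  expect_identical(ab$sequences[["G1"]], substr(recs[[1]]$sequence, 1601, 2100))
  # minus-strand gene is reverse-complemented
  gb <- loci[[which(nm == "geneB")]]
  expect_identical(gb$sequences[["G1"]],
                   revcomp(substr(recs[[1]]$sequence, 2101, 2700)))
})

test_that("loci present in fewer than two genomes are dropped", {
  recs <- two_gene_records(seed = 402)
  recs[[2]]$features <- recs[[2]]$features[1]   # drop geneB from G2
  expect_message(loci <- extract_loci(recs), "dropping")
  nm <- vapply(loci, `[[`, "", "name")
  expect_false("geneB" %in% nm)
  expect_true("geneA" %in% nm)
})

test_that("introns of compound genes become noncoding loci", {
  recs <- lapply(c("I1", "I2"), function(acc) {
    set.seed(403)
    g <- constructed_ir_genome(lsc = 5000, ir = 1500, ssc = 1000)
    plastome_record(acc, g$sequence, features = list(
      gene_feature("clpP", "CDS", "+",
                   rbind(c(1000L, 1200L), c(1500L, 1800L), c(2200L, 2400L)))))
  })
  loci <- extract_loci(recs)
  nm <- vapply(loci, `[[`, "", "name")
  expect_true(all(c("clpP", "clpP-intron1", "clpP-intron2") %in% nm))
  i1 <- loci[[which(nm == "clpP-intron1")]]
  expect_identical(unname(nchar(i1$sequences[1])), 300L)
  cds <- loci[[which(nm == "clpP")]]
  expect_identical(unname(nchar(cds$sequences[1])), 200L + 300L + 200L)
})

test_that("only the IRb copy of an IR-duplicated gene is used", {
  sp <- synthetic_panel_spec(n_taxa = 2, seed = 404)
  pan <- simulate_panel(sp)
  loci <- extract_loci(pan$records)
  nm <- vapply(loci, `[[`, "", "name")
  expect_identical(sum(nm == "rpl2"), 1L)
  rec <- pan$records[[1]]
  irb_copy <- Filter(function(f) f$name == "rpl2" &&
                       f$intervals[1, 1] < sp$lsc_len + sp$ir_len,
                     rec$features)[[1]]
  seq_irb <- substr(rec$sequence, irb_copy$intervals[1, 1] + 1,
                    irb_copy$intervals[1, 2])
  expect_identical(loci[[which(nm == "rpl2")]]$sequences[[rec$accession]],
                   revcomp(seq_irb))  # rpl2 is laid out on the minus strand
})

test_that("spacer extraction is strand-consistent under flip + rotation", {
  sp <- synthetic_panel_spec(n_taxa = 3, seed = 405)
  recs <- simulate_panel(sp)$records
  flipped <- rotate_record(flip_record(recs[[2]]), 4321L)
  a <- extract_loci(recs)
  b <- extract_loci(list(recs[[1]], flipped, recs[[3]]))
  na <- vapply(a, `[[`, "", "name")
  nb <- vapply(b, `[[`, "", "name")
  expect_setequal(na, nb)
  for (i in seq_along(a)) {
    j <- which(nb == na[i])
    expect_identical(a[[i]]$sequences, b[[j]]$sequences)
  }
})

test_that("alignment ingest validates row lengths and round trips", {
  rows <- c(A1 = "ACGTACGTAC", A2 = "ACGTACGTAC", A3 = "ACGTACGTAC")
  aln <- locus_alignment(rows, name = "x")
  expect_identical(aln$L, 10L)
  path <- withr::local_tempfile(fileext = ".fa")
  write_alignment(aln, path)
  back <- ingest_alignment(path, name = "x")
  expect_identical(back$rows, aln$rows)
  expect_identical(back$L, 10L)

  expect_error(locus_alignment(c(A = "ACGT", B = "ACG")), "unequal")
  writeLines(c(">A", "ACGT", ">B", "ACG"), path)
  expect_error(ingest_alignment(path), "unequal")
})

test_that("the length and variability filter applies both rules strictly", {
  set.seed(406)
  short_var <- random_alignment(4, 150)                       # L <= 200
  long_const <- locus_alignment(
    stats::setNames(rep(strrep("ACGT", 63), 3), c("A", "B", "C")))  # 252 bp, 0 var
  rows <- rep(strrep("A", 250), 3)
  rows[2] <- paste0("C", substr(rows[2], 2, 250))
  long_var <- locus_alignment(stats::setNames(rows, c("A", "B", "C")))
  exactly200 <- random_alignment(4, 200)

  kept <- filter_loci(list(short_var, long_const, long_var, exactly200))
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$name, long_var$name)
})

test_that("filter equals brute-force application of both rules on random panels", {
  set.seed(407)
  alns <- lapply(1:40, function(i) {
    n <- sample(2:6, 1)
    L <- sample(150:260, 1)
    base <- sample(BASES, L, replace = TRUE)
    rows <- vapply(seq_len(n), function(k) {
      v <- base
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        at <- sample(L, nmut)
        v[at] <- sample(BASES, nmut, replace = TRUE)
      }
      paste(v, collapse = "")
    }, "")
    names(rows) <- sprintf("T%d", seq_len(n))
    locus_alignment(rows, name = sprintf("L%02d", i))
  })
  kept <- filter_loci(alns)
  brute <- Filter(function(a) {
    m <- do.call(rbind, strsplit(unname(a$rows), ""))
    nvar <- sum(apply(m, 2, function(col) length(unique(col)) >= 2))
    nchar(a$rows[[1]]) > 200 && nvar >= 1
  }, alns)
  expect_identical(vapply(kept, `[[`, "", "name"),
                   vapply(brute, `[[`, "", "name"))
})
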