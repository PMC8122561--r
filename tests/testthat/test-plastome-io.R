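# GenBank / FASTA / panel-table I/O and the shared data model

test_that("GenBank write-then-read round trip preserves sequence and features", {
  sp <- synthetic_panel_spec(n_taxa = 1, seed = 101)
  rec <- simulate_panel(sp)$records[[1]]
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  back <- read_genbank(path)

  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$accession, rec$accession)
  expect_true(back$circular)
  expect_length(back$features, length(rec$features))
  key <- function(f) paste(f$name, f$kind, f$strand,
                           paste(f$intervals, collapse = ","))
  expect_setequal(vapply(back$features, key, ""),
                  vapply(rec$features, key, ""))
})

test_that("read_genbank handles compound, complement and degenerate inputs", {
  gb <- c("LOCUS       test 40 bp DNA circular PLN 01-JAN-2000",
          "ACCESSION   TEST1",
          "FEATURES             Location/Qualifiers",
          "     CDS             join(3..8,15..20)",
          '                     /gene="atpF"',
          "     tRNA            complement(25..31)",
          '                     /gene="trnH-GUG"',
          "     CDS             33..38",
          "     rRNA            1..2",
          '                     /product="small subunit ribosomal RNA"',
          "ORIGIN",
          "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
          "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  expect_warning(rec <- read_genbank(path), "unnamed")  # bare CDS skipped

  expect_identical(nchar(rec$sequence), 40L)
  nm <- vapply(rec$features, `[[`, "", "name")
  expect_setequal(nm, c("atpF", "trnH-GUG", "small_subunit_ribosomal_RNA"))
  atpF <- rec$features[[which(nm == "atpF")]]
  expect_equal(unname(atpF$intervals), rbind(c(2L, 8L), c(14L, 20L)),
               ignore_attr = TRUE)
  trn <- rec$features[[which(nm == "trnH-GUG")]]
  expect_identical(trn$strand, "-")
  expect_equal(unname(trn$intervals)[1, ], c(24L, 31L))
})

test_that("GenBank files without a sequence are a hard error", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       x 10 bp DNA linear", "//"), path)
  expect_error(read_genbank(path), "ORIGIN|sequence")
})

test_that("FASTA panel round trips; duplicates and empty files handled", {
  sp <- synthetic_panel_spec(n_taxa = 2, seed = 102)
  recs <- simulate_panel(sp)$records
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta_panel(recs, path)
  back <- read_fasta_panel(path)
  expect_length(back, 2L)
  expect_identical(back[[1]]$sequence, recs[[1]]$sequence)
  expect_identical(back[[2]]$accession, recs[[2]]$accession)
  expect_identical(back[[1]]$taxon, recs[[1]]$taxon)
  expect_length(back[[1]]$features, 0L)

  writeLines(c(">A t1", "ACGT", ">A t2", "ACGT"), path)
  expect_error(read_fasta_panel(path), "duplicate")

  writeLines(character(), path)
  expect_length(read_fasta_panel(path), 0L)
})

test_that("write_panel_table enforces the tiling identity and formats GC", {
  row <- data.frame(accession = "X1", taxon = "x", family = NA,
                    genome_size = 1000L, lsc_len = 500L, ssc_len = 100L,
                    ir_len = 200L, n_cds = 10L, n_trna = 2L, n_rrna = 1L,
                    gc_total = 0.375, gc_lsc = 0.3, gc_ssc = 0.31,
                    gc_ir = 0.42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel_table(row, path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  expect_match(lines[2], "37\\.50")

  bad <- row
  bad$ir_len <- 150L
  expect_error(write_panel_table(bad, path), "tiling")
})

test_that("coordinates are 0-based half-open internally, 1-based inclusive on disk", {
  rec <- plastome_record("A1", strrep("ACGT", 10), features = list(
    gene_feature("rbcL", "CDS", "+", c(4L, 10L))))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  expect_true(any(grepl("CDS             5..10", readLines(path), fixed = TRUE)))
  expect_equal(unname(read_genbank(path)$features[[1]]$intervals)[1, ],
               c(4L, 10L))
})

test_that("gene symbols are case-normalized with anticodon suffixes kept", {
  expect_identical(normalize_gene_symbol("NdhF"), "ndhF")
  expect_identical(normalize_gene_symbol("trnH-GUG"), "trnH-GUG")
  expect_identical(normalize_gene_symbol("TrnS(GCU)"), "trnS(GCU)")
  expect_identical(normalize_gene_symbol("ycf1"), "ycf1")
})

test_that("feature invariants are enforced", {
  expect_error(gene_feature("x", "CDS", "+", c(5L, 5L)), "start < end")
  expect_error(gene_feature("x", "CDS", "+", rbind(c(0L, 10L), c(5L, 15L))),
               "overlap")
  expect_error(plastome_record("A", ""), "empty")
  expect_error(plastome_record("A", "ACGT", features = list(
    gene_feature("x", "CDS", "+", c(0L, 10L)))), "beyond")
})
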