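# ---------------------------------------------------------------------------
# Homologous-locus extraction across a panel: coding regions (concatenated
# exons), introns, and intergenic spacers; alignment ingest; the
# "> 200 bp aligned, >= 1 variable site" filter.
# ---------------------------------------------------------------------------

#' Extract homologous loci across an annotated panel
#'
#' Per genome, on its canonical linearization:
#' * one coding locus per gene (exon intervals concatenated in genome
#'   order; minus-strand genes reverse-complemented so all genomes share
#'   one orientation); for IR-duplicated genes only the IRb copy is used;
#' * one locus per intron (the gap between consecutive exon intervals of a
#'   compound gene), named `gene-intron1`, `gene-intron2`, ...;
#' * one intergenic spacer between each pair of consecutive gene spans on
#'   the plus-strand linearization (including the wrap-around pair), named
#'   `geneA-geneB` in linearized order; spacers of length <= 0 (overlapping
#'   genes) are skipped.
#'
#' Loci present in fewer than `min_genomes` genomes are dropped with a
#' message.
#'
#' @param records List of annotated [plastome_record]s.
#' @param partition_map Named list of `quadripartite_partition`s keyed by
#'   accession; detected on the fly when `NULL`.
#' @param min_genomes Minimum number of genomes a locus must appear in
#'   (default 2).
#' @param min_ir_len Used when partitions are detected here.
#' @return List of locus sets, each `list(name, category, sequences)` with
#'   `sequences` a named character vector (accession -> sequence) and
#'   `category` `"coding"` or `"noncoding"`.
#' @export
extract_loci <- function(records, partition_map = NULL, min_genomes = 2L,
                         min_ir_len = 1000L) {
  canon <- lapply(records, function(rec) {
    part <- if (is.null(partition_map)) detect_inverted_repeat(rec, min_ir_len)
            else partition_map[[rec$accession]]
    part0 <- part
    part0$offset <- 0L
    list(rec = canonicalize_record(rec, part), part = part0)
  })
  # orient every genome like the first (the reference): a plastome and its
  # reverse complement are the same molecule, so when the majority of
  # shared genes sit on the opposite strand the genome is flipped back
  ref_strand <- gene_strands(canon[[1]]$rec)
  per_genome <- lapply(canon, function(cp) {
    st <- gene_strands(cp$rec)
    shared <- intersect(names(st), names(ref_strand))
    if (length(shared) &&
        sum(st[shared] != ref_strand[shared]) > length(shared) / 2) {
      lsc_len <- cp$part$lsc[2] - cp$part$lsc[1]
      cp$rec <- rotate_record(flip_record(cp$rec),
                              genome_length(cp$rec) - lsc_len)
    }
    extract_loci_one(cp$rec, cp$part)
  })
  acc <- vapply(records, `[[`, "", "accession")

  keys <- unique(unlist(lapply(per_genome, function(g)
    vapply(g, function(l) paste(l$category, l$name, sep = "\r"), ""))))
  out <- list()
  for (key in keys) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    seqs <- character()
    for (i in seq_along(per_genome)) {
      hit <- Filter(function(l) l$name == parts[2] && l$category == parts[1],
                    per_genome[[i]])
      if (length(hit)) seqs[acc[i]] <- hit[[1]]$sequence
    }
    if (length(seqs) < min_genomes) {
      message(sprintf("extract_loci: dropping '%s' (present in %d genome%s)",
                      parts[2], length(seqs), if (length(seqs) == 1) "" else "s"))
      next
    }
    out[[length(out) + 1L]] <- list(name = parts[2], category = parts[1],
                                    sequences = seqs)
  }
  out
}

# strand of each gene name (first non-pseudo feature wins)
gene_strands <- function(record) {
  feats <- Filter(function(f) !f$pseudo, record$features)
  nm <- vapply(feats, `[[`, "", "name")
  st <- vapply(feats, `[[`, "", "strand")
  st[!duplicated(nm)] -> out
  names(out) <- nm[!duplicated(nm)]
  out
}

# loci of a single canonicalized genome
extract_loci_one <- function(record, partition) {
  rec <- canonicalize_record(record, partition)
  feats <- Filter(function(f) !f$pseudo, rec$features)
  if (length(feats) == 0L) return(list())
  nm <- vapply(feats, `[[`, "", "name")
  regions <- vapply(feats, feature_region, "", partition = partition)

  # deduplicate IR copies: for names with copies in both IRs keep the IRb copy
  keep <- rep(TRUE, length(feats))
  for (g in unique(nm)) {
    idx <- which(nm == g)
    if (length(idx) < 2L) next
    if (any(regions[idx] == "IRb") && any(regions[idx] == "IRa"))
      keep[idx[regions[idx] == "IRa"]] <- FALSE
    # any remaining same-name copies (trans-spliced rps12): keep the first
    idx2 <- which(nm == g & keep)
    if (length(idx2) > 1L) keep[idx2[-1]] <- FALSE
  }
  feats <- feats[keep]
  nm <- nm[keep]

  s <- rec$sequence
  n <- nchar(s)
  loci <- list()
  add <- function(name, category, sequence) {
    if (nchar(sequence) > 0L)
      loci[[length(loci) + 1L]] <<- list(name = name, category = category,
                                         sequence = sequence)
  }
  for (f in feats) {
    exons <- vapply(seq_len(nrow(f$intervals)), function(r)
      substr(s, f$intervals[r, 1] + 1L, f$intervals[r, 2]), "")
    cds <- paste(exons, collapse = "")
    if (f$strand == "-") cds <- revcomp(cds)
    add(f$name, "coding", cds)
    if (nrow(f$intervals) > 1L) {
      for (r in seq_len(nrow(f$intervals) - 1L)) {
        a <- f$intervals[r, 2]; b <- f$intervals[r + 1L, 1]
        if (b <= a) next
        intron <- substr(s, a + 1L, b)
        if (f$strand == "-") intron <- revcomp(intron)
        add(sprintf("%s-intron%d", f$name, r), "noncoding", intron)
      }
    }
  }

  # spacers between consecutive gene spans on the plus-strand linearization
  spans <- t(vapply(feats, feature_span, integer(2)))
  o <- order(spans[, 1], spans[, 2])
  spans <- spans[o, , drop = FALSE]
  snm <- nm[o]
  k <- nrow(spans)
  if (k >= 2L) {
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      a <- spans[i, 2]
      b <- if (i == k) spans[j, 1] + n else spans[j, 1]
      if (b <= a) next                      # overlapping/abutting genes
      spacer <- subseq_circular(s, a, b - a)
      add(sprintf("%s-%s", snm[i], snm[j]), "noncoding", spacer)
    }
  }
  loci
}

# ---------------------------------------------------------------------------

#' Build a locus alignment object from equal-length rows
#'
#' @param rows Named character vector (accession -> aligned sequence, gaps
#'   `-`); all rows must have equal length.
#' @param name Locus label.
#' @param category `"coding"` or `"noncoding"`.
#' @return Object of class `locus_alignment` with elements `name`,
#'   `category`, `rows`, `L`.
#' @export
locus_alignment <- function(rows, name = "locus", category = "noncoding") {
  rows <- toupper(rows)
  L <- unique(nchar(rows))
  if (length(L) != 1L)
    stop("locus_alignment: rows have unequal lengths (",
         paste(range(nchar(rows)), collapse = "-"), ")")
  if (is.null(names(rows)) || any(names(rows) == ""))
    stop("locus_alignment: rows must be named by accession")
  structure(list(name = name, category = category, rows = rows,
                 L = as.integer(L)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s (%s): %d sequences x %d columns\n",
              x$name, x$category, length(x$rows), x$L))
  invisible(x)
}

#' Read an aligned FASTA file as a locus alignment
#'
#' @param path Aligned FASTA (equal row lengths; unequal lengths are an
#'   error).
#' @param name Locus label; defaults to the file name without extension.
#' @param category `"coding"` or `"noncoding"`.
#' @return A [locus_alignment()].
#' @export
ingest_alignment <- function(path, name = NULL,
                             category = c("noncoding", "coding")) {
  category <- match.arg(category)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("ingest_alignment: no sequences in ", path)
  rows <- as.character(ss)
  names(rows) <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, "", 1L)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  locus_alignment(rows, name = name, category = category)
}

#' Write a locus alignment (or locus set) as FASTA
#'
#' @param aln A [locus_alignment()] or a locus set from [extract_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  rows <- if (inherits(aln, "locus_alignment")) aln$rows else aln$sequences
  ss <- Biostrings::DNAStringSet(rows)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Convert extracted locus sets to alignments
#'
#' Valid when sequences within each locus have equal length (e.g. panels
#' that diverged by substitutions only); locus sets with unequal lengths
#' are skipped with a message (align them externally and use
#' [ingest_alignment()]).
#'
#' @param locus_sets List from [extract_loci()].
#' @return List of [locus_alignment()]s.
#' @export
loci_as_alignments <- function(locus_sets) {
  out <- list()
  for (ls in locus_sets) {
    if (length(unique(nchar(ls$sequences))) != 1L) {
      message(sprintf("loci_as_alignments: '%s' has unequal lengths; skipped",
                      ls$name))
      next
    }
    out[[length(out) + 1L]] <-
      locus_alignment(ls$sequences, name = ls$name, category = ls$category)
  }
  out
}

#' Filter locus alignments by aligned length and variability
#'
#' Keeps alignments with aligned length strictly greater than `min_len`
#' and at least `min_variable_sites` polymorphic columns (a column is
#' polymorphic when it carries two or more distinct unambiguous bases;
#' gaps and ambiguity codes do not create polymorphism).  Ordering is
#' preserved.
#'
#' @param alignments List of [locus_alignment()]s.
#' @param min_len Length threshold in bp (default 200, strict `>`).
#' @param min_variable_sites Minimum polymorphic columns (default 1).
#' @return The kept sublist.
#' @export
filter_loci <- function(alignments, min_len = 200L, min_variable_sites = 1L) {
  Filter(function(a) {
    a$L > min_len && n_variable_columns(a) >= min_variable_sites
  }, alignments)
}

# number of columns with >= 2 distinct bases among {A,C,G,T}
n_variable_columns <- function(aln) {
  m <- alignment_matrix(aln)
  sum(apply(m, 2L, function(col) {
    b <- col[col %in% c("A", "C", "G", "T")]
    length(unique(b)) >= 2L
  }))
}

# character matrix (rows = sequences) of an alignment
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
}
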