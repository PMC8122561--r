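# ---------------------------------------------------------------------------
# Shared data model: gene features and plastome records.
#
# All coordinates are 0-based half-open internally; human-facing output
# (TSV reports, GenBank emission) is 1-based inclusive.
# ---------------------------------------------------------------------------

#' Construct a gene feature
#'
#' A gene feature is one annotated gene on the linearized genome: a name
#' (conventional plastid symbol, e.g. `"ndhF"` or `"trnH-GUG"`), a kind
#' (`CDS`, `tRNA` or `rRNA`), a strand, and one or more coordinate intervals
#' (compound/joined locations keep one interval per exon segment).
#'
#' @param name Gene symbol.
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param intervals Two-column matrix (or length-2 vector) of 0-based
#'   half-open `[start, end)` pairs, ordered, non-overlapping.
#' @param pseudo Logical; pseudogenes are excluded from the census and locus
#'   extraction.
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(name, kind, strand = "+", intervals, pseudo = FALSE) {
  if (is.null(dim(intervals))) intervals <- matrix(intervals, ncol = 2, byrow = TRUE)
  intervals <- matrix(as.integer(intervals), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
  stopifnot(nrow(intervals) >= 1)
  if (any(intervals[, 1] < 0L) || any(intervals[, 2] <= intervals[, 1]))
    stop("gene_feature: intervals must satisfy 0 <= start < end")
  o <- order(intervals[, 1])
  intervals <- intervals[o, , drop = FALSE]
  if (nrow(intervals) > 1 &&
      any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))
    stop("gene_feature: intervals overlap within one feature")
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA"))
  strand <- match.arg(strand, c("+", "-"))
  structure(list(name = as.character(name), kind = kind, strand = strand,
                 intervals = intervals, pseudo = isTRUE(pseudo),
                 is_duplicate_copy = FALSE),
            class = "gene_feature")
}

#' Construct a plastome record
#'
#' One annotated (possibly unannotated) circular genome: accession, taxon,
#' optional family, the nucleotide sequence and a list of [gene_feature]s.
#'
#' @param accession Identifier, unique within a panel.
#' @param sequence Nucleotide string over `A,C,G,T,N` plus IUPAC codes
#'   (case-insensitive; stored upper case).
#' @param taxon Species name.
#' @param family Optional family name.
#' @param circular Logical, default `TRUE`.
#' @param features List of [gene_feature]s.
#' @return An object of class `plastome_record`.
#' @export
plastome_record <- function(accession, sequence, taxon = accession,
                            family = NA_character_, circular = TRUE,
                            features = list()) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("plastome_record: empty sequence")
  if (grepl("[^ACGTUNRYSWKMBDHV-]", sequence))
    stop("plastome_record: sequence contains non-IUPAC characters")
  n <- nchar(sequence)
  for (f in features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature objects")
    if (any(f$intervals[, 2] > n))
      stop(sprintf("feature '%s' extends beyond the %d bp sequence", f$name, n))
  }
  structure(list(accession = as.character(accession),
                 taxon = as.character(taxon),
                 family = as.character(family),
                 sequence = sequence, circular = isTRUE(circular),
                 features = features),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s (%s)\n  %s bp, %s, %d features\n",
              x$accession, x$taxon, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", length(x$features)))
  invisible(x)
}

#' @export
print.gene_feature <- function(x, ...) {
  loc <- paste(sprintf("[%d,%d)", x$intervals[, 1], x$intervals[, 2]),
               collapse = ",")
  cat(sprintf("<gene_feature> %s %s %s %s\n", x$name, x$kind, x$strand, loc))
  invisible(x)
}

# outermost [start, end) span of a (possibly compound) feature
feature_span <- function(f) c(f$intervals[1, 1], f$intervals[nrow(f$intervals), 2])

genome_length <- function(record) nchar(record$sequence)

# ---------------------------------------------------------------------------
# sequence helpers
# ---------------------------------------------------------------------------

#' Reverse complement of a nucleotide string
#'
#' IUPAC-aware; gaps (`-`) are preserved.
#' @param x Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substring on the circular genome: 0-based start, length len (may wrap)
subseq_circular <- function(sequence, start, len) {
  n <- nchar(sequence)
  stopifnot(len >= 0, len <= n)
  if (len == 0L) return("")
  start <- start %% n
  if (start + len <= n) {
    substr(sequence, start + 1L, start + len)
  } else {
    paste0(substr(sequence, start + 1L, n),
           substr(sequence, 1L, start + len - n))
  }
}

# rotate a sequence so that 0-based position `offset` becomes position 0
rotate_sequence <- function(sequence, offset) {
  n <- nchar(sequence)
  offset <- offset %% n
  if (offset == 0L) return(sequence)
  paste0(substr(sequence, offset + 1L, n), substr(sequence, 1L, offset))
}

#' Rotate a plastome record
#'
#' Rotates the circular genome so that 0-based position `offset` becomes
#' position 0; feature intervals are shifted accordingly and a feature
#' crossing the new origin is split into two intervals.
#'
#' @param record A [plastome_record].
#' @param offset 0-based position that becomes the new origin.
#' @return The rotated [plastome_record].
#' @export
rotate_record <- function(record, offset) {
  n <- genome_length(record)
  offset <- offset %% n
  if (offset == 0L) return(record)
  feats <- lapply(record$features, function(f) {
    iv <- f$intervals
    new <- list()
    for (r in seq_len(nrow(iv))) {
      a <- (iv[r, 1] - offset) %% n
      b <- a + (iv[r, 2] - iv[r, 1])
      if (b <= n) new[[length(new) + 1L]] <- c(a, b)
      else {
        new[[length(new) + 1L]] <- c(a, n)
        new[[length(new) + 1L]] <- c(0L, b - n)
      }
    }
    gene_feature(f$name, f$kind, f$strand, do.call(rbind, new), f$pseudo)
  })
  plastome_record(record$accession, rotate_sequence(record$sequence, offset),
                  taxon = record$taxon, family = record$family,
                  circular = record$circular, features = feats)
}

#' Reverse-complement a plastome record
#'
#' Returns the record on the opposite strand: the sequence is
#' reverse-complemented and every feature interval `[a, b)` becomes
#' `[n - b, n - a)` with its strand flipped.
#'
#' @param record A [plastome_record].
#' @return The flipped [plastome_record].
#' @export
flip_record <- function(record) {
  n <- genome_length(record)
  feats <- lapply(record$features, function(f) {
    iv <- f$intervals
    new <- cbind(n - iv[, 2], n - iv[, 1])
    gene_feature(f$name, f$kind, if (f$strand == "+") "-" else "+",
                 new, f$pseudo)
  })
  plastome_record(record$accession, revcomp(record$sequence),
                  taxon = record$taxon, family = record$family,
                  circular = record$circular, features = feats)
}

#' GC fraction of a sequence
#'
#' `G + C` over `A + C + G + T`; `N` and other ambiguity codes are excluded
#' from both numerator and denominator.
#' @param x Nucleotide string.
#' @return Fraction in `[0, 1]` (`NaN` if no unambiguous base).
#' @export
gc_fraction <- function(x) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  gc <- sum(v == "G" | v == "C")
  at <- sum(v == "A" | v == "T")
  gc / (gc + at)
}
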