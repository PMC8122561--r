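# ---------------------------------------------------------------------------
# Quadripartite structure: inverted-repeat detection, LSC/IRb/SSC/IRa
# partition, per-region profiles, deduplicated gene census, panel summary.
# ---------------------------------------------------------------------------

#' Detect the inverted repeat and partition a plastome
#'
#' Finds the longest pair of disjoint, reverse-complementary segments of the
#' circular sequence (exact match by default) by seed-and-extend against the
#' reverse complement, and partitions the genome into LSC, IRb, SSC and IRa.
#' The linearization is normalized so that the regions appear in the order
#' LSC, IRb, SSC, IRa with the LSC being the longer of the two single-copy
#' regions; junction labels JLB/JSB/JSA/JLA are then well-defined and match
#' conventional plastome maps.
#'
#' The returned partition holds 0-based half-open intervals on the canonical
#' linearization plus `offset`, the 0-based position in the *input* record
#' where the canonical origin (first LSC base) sits.  Use
#' [canonicalize_record()] to rotate a record onto that linearization.
#'
#' @param record A [plastome_record] (assumed circular).
#' @param min_ir_len Minimum acceptable repeat length in bp (default 1000).
#' @param max_mismatch Mismatch budget; the default 0 demands exact
#'   reverse-complementarity.  A positive budget extends each boundary
#'   greedily past up to that many isolated mismatches.
#' @return An object of class `quadripartite_partition` with elements
#'   `lsc`, `irb`, `ssc`, `ira` (integer `[start, end)` pairs), `offset`,
#'   and `genome_length`.
#' @export
detect_inverted_repeat <- function(record, min_ir_len = 1000L, max_mismatch = 0L) {
  s <- record$sequence
  n <- nchar(s)
  if (min_ir_len < 10L) stop("min_ir_len must be at least 10")
  if (2L * min_ir_len >= n)
    stop("no-IR: sequence shorter than two copies of min_ir_len")

  s2 <- paste0(s, s)                       # circular unrolling
  r2 <- revcomp(s2)
  x <- charToRaw(s2)
  y <- charToRaw(r2)
  N2 <- 2L * n

  k <- 24L
  stride <- max(1L, min_ir_len - k + 1L)   # every >=min_ir_len repeat holds a seed
  seed_starts <- seq.int(1L, n, by = stride)

  best_len <- 0L
  cand <- list()
  seen <- character()
  for (i in seed_starts) {
    if (i + k - 1L > N2) next
    seed <- substr(s2, i, i + k - 1L)
    if (grepl("[^ACGT]", seed)) next
    hits <- Biostrings::start(Biostrings::matchPattern(seed, r2))
    for (j in hits) {
      ext <- extend_exact(x, y, i, j, k, N2, n)
      a <- ext[1]; j0 <- ext[2]; len <- ext[3]
      # map the r2 occurrence back to forward coordinates:
      # r2[j0 .. j0+len-1] == revcomp(s2[(N2 - j0 - len + 2) .. (N2 - j0 + 1)])
      b <- N2 - j0 - len + 2L
      p1 <- (a - 1L) %% n                 # 0-based starts on the circle
      p2 <- (b - 1L) %% n
      if (!circ_disjoint(p1, len, p2, len, n)) next
      key <- paste(min(p1, p2), max(p1, p2), len, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (len >= min_ir_len) cand[[length(cand) + 1L]] <- c(p1, p2, len)
    }
  }
  if (length(cand) == 0L)
    stop("no-IR: no inverted repeat of length >= ", min_ir_len, " found")

  m <- do.call(rbind, cand)
  lens <- m[, 3]
  top <- m[lens == max(lens), , drop = FALSE]
  if (nrow(top) > 1) {
    message("detect_inverted_repeat: ", nrow(top),
            " maximal candidates of equal length; choosing smallest start")
    top <- top[order(pmin(top[, 1], top[, 2])), , drop = FALSE]
  }
  p1 <- top[1, 1]; p2 <- top[1, 2]; ir_len <- top[1, 3]

  # the two single-copy gaps between the repeats, going around the circle
  gap_after <- function(from_start, from_len, to_start)
    (to_start - (from_start + from_len)) %% n
  g12 <- gap_after(p1, ir_len, p2)   # gap between end(copy1) and start(copy2)
  g21 <- gap_after(p2, ir_len, p1)
  if (g12 == g21)
    stop("single-copy regions of equal length; cannot orient LSC vs SSC")

  # LSC is the longer gap; IRb is the repeat copy that follows the LSC
  if (g21 > g12) {           # gap from copy2 end to copy1 start is the LSC
    lsc_start <- (p2 + ir_len) %% n
    lsc_len <- g21; ssc_len <- g12
  } else {
    lsc_start <- (p1 + ir_len) %% n
    lsc_len <- g12; ssc_len <- g21
  }
  stopifnot(lsc_len + ssc_len + 2L * ir_len == n)

  partition <- structure(list(
    lsc = c(0L, lsc_len),
    irb = c(lsc_len, lsc_len + ir_len),
    ssc = c(lsc_len + ir_len, lsc_len + ir_len + ssc_len),
    ira = c(lsc_len + ir_len + ssc_len, n),
    offset = as.integer(lsc_start),
    genome_length = as.integer(n)
  ), class = "quadripartite_partition")
  validate_partition(record, partition)
  partition
}

# maximal exact common extension of x[i..] vs y[j..] around a length-k seed,
# capped at n total; block-compares raw vectors
extend_exact <- function(x, y, i, j, k, N2, n) {
  block <- 4096L
  # right
  re <- 0L
  repeat {
    a0 <- i + k + re; b0 <- j + k + re
    if (a0 > N2 || b0 > N2 || k + re >= n) break
    w <- min(block, N2 - a0 + 1L, N2 - b0 + 1L, n - (k + re))
    xa <- x[a0:(a0 + w - 1L)]; yb <- y[b0:(b0 + w - 1L)]
    neq <- which(xa != yb)
    if (length(neq)) { re <- re + neq[1] - 1L; break }
    re <- re + w
  }
  # left
  le <- 0L
  repeat {
    a0 <- i - le - 1L; b0 <- j - le - 1L
    if (a0 < 1L || b0 < 1L || k + re + le >= n) break
    w <- min(block, a0, b0, n - (k + re + le))
    xa <- x[(a0 - w + 1L):a0]; yb <- y[(b0 - w + 1L):b0]
    neq <- which(rev(xa) != rev(yb))
    if (length(neq)) { le <- le + neq[1] - 1L; break }
    le <- le + w
  }
  c(i - le, j - le, min(k + re + le, n))
}

# are the circular intervals [a, a+la) and [b, b+lb) disjoint on Z/n?
circ_disjoint <- function(a, la, b, lb, n) {
  d <- (b - a) %% n
  d >= la && (n - d) >= lb
}

validate_partition <- function(record, partition) {
  n <- partition$genome_length
  lens <- vapply(partition[c("lsc", "irb", "ssc", "ira")],
                 function(iv) iv[2] - iv[1], 0L)
  stopifnot(sum(lens) == n, lens["irb"] == lens["ira"])
  if (!is.null(record)) {
    seq_c <- rotate_sequence(record$sequence, partition$offset)
    irb_s <- substr(seq_c, partition$irb[1] + 1L, partition$irb[2])
    ira_s <- substr(seq_c, partition$ira[1] + 1L, partition$ira[2])
    if (!identical(revcomp(irb_s), ira_s))
      stop("internal error: IRa is not the reverse complement of IRb")
  }
  invisible(partition)
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf(paste0("<quadripartite_partition> %s bp\n",
                     "  LSC [%d,%d) %d bp | IRb [%d,%d) %d bp | ",
                     "SSC [%d,%d) %d bp | IRa [%d,%d) %d bp\n",
                     "  canonical origin at input position %d\n"),
              format(x$genome_length, big.mark = ","),
              x$lsc[1], x$lsc[2], x$lsc[2] - x$lsc[1],
              x$irb[1], x$irb[2], x$irb[2] - x$irb[1],
              x$ssc[1], x$ssc[2], x$ssc[2] - x$ssc[1],
              x$ira[1], x$ira[2], x$ira[2] - x$ira[1],
              x$offset))
  invisible(x)
}

#' Region lengths of a partition
#' @param partition A `quadripartite_partition`.
#' @return Named integer vector `lsc, irb, ssc, ira`.
#' @export
partition_lengths <- function(partition)
  vapply(partition[c("lsc", "irb", "ssc", "ira")],
         function(iv) iv[2] - iv[1], 0L)

#' Rotate a record onto the canonical linearization of its partition
#'
#' The sequence is rotated so that the first LSC base is position 0, and all
#' feature intervals are shifted accordingly (a feature crossing the new
#' origin is split into two intervals).  After canonicalization the
#' partition's intervals index directly into the record.
#'
#' @param record A [plastome_record].
#' @param partition Its `quadripartite_partition`.
#' @return A rotated [plastome_record].
#' @export
canonicalize_record <- function(record, partition) {
  rotate_record(record, partition$offset %% partition$genome_length)
}

# ---------------------------------------------------------------------------

#' Per-region length and GC profiles
#'
#' Four profiles: LSC, SSC, IR (computed on IRb; the two repeats are
#' identical under exact detection) and total.  GC excludes `N` and IUPAC
#' ambiguity codes from numerator and denominator.
#'
#' @param record A [plastome_record].
#' @param partition Its `quadripartite_partition`.
#' @return Data frame with columns `region`, `length`, `gc`.
#' @export
region_profiles <- function(record, partition) {
  seq_c <- canonicalize_record(record, partition)$sequence
  pull <- function(iv) substr(seq_c, iv[1] + 1L, iv[2])
  data.frame(
    region = c("LSC", "SSC", "IR", "total"),
    length = c(partition$lsc[2] - partition$lsc[1],
               partition$ssc[2] - partition$ssc[1],
               partition$irb[2] - partition$irb[1],
               partition$genome_length),
    gc = c(gc_fraction(pull(partition$lsc)),
           gc_fraction(pull(partition$ssc)),
           gc_fraction(pull(partition$irb)),
           gc_fraction(seq_c)),
    stringsAsFactors = FALSE)
}

# region containing a feature, by the circular midpoint of its outer span
feature_region <- function(f, partition, offset_applied = TRUE) {
  sp <- feature_span(f)
  n <- partition$genome_length
  len <- (sp[2] - sp[1]) %% n
  mid <- (sp[1] + len %/% 2L) %% n
  in_iv <- function(iv) mid >= iv[1] && mid < iv[2]
  if (in_iv(partition$lsc)) "LSC"
  else if (in_iv(partition$irb)) "IRb"
  else if (in_iv(partition$ssc)) "SSC"
  else "IRa"
}

#' Deduplicated gene census
#'
#' Counts unique genes by class.  A gene whose name occurs twice with one
#' copy in each inverted repeat is counted once and flagged IR-duplicated;
#' the trans-spliced `rps12` (several features of the same name) is counted
#' once; pseudogenes are excluded.  A gene with more than two copies draws a
#' warning and is still counted once.
#'
#' @param record An annotated [plastome_record].
#' @param partition Its `quadripartite_partition`.
#' @return List with `n_total`, `n_cds`, `n_trna`, `n_rrna`,
#'   `n_ir_duplicated`, and `ir_duplicated` (the gene names).
#' @export
gene_census <- function(record, partition) {
  rec <- canonicalize_record(record, partition)
  feats <- Filter(function(f) !f$pseudo, rec$features)
  if (length(feats) == 0L)
    return(list(n_total = 0L, n_cds = 0L, n_trna = 0L, n_rrna = 0L,
                n_ir_duplicated = 0L, ir_duplicated = character()))
  names_ <- vapply(feats, `[[`, "", "name")
  kinds <- vapply(feats, `[[`, "", "kind")
  regions <- vapply(feats, feature_region, "", partition = partition)
  ir_dup <- character()
  for (nm in unique(names_)) {
    idx <- which(names_ == nm)
    if (length(idx) > 2L)
      warning(sprintf("gene '%s' has %d copies; counted once", nm, length(idx)))
    regs <- regions[idx]
    if (length(idx) >= 2L && any(regs == "IRb") && any(regs == "IRa"))
      ir_dup <- c(ir_dup, nm)
  }
  uniq <- !duplicated(names_)
  list(n_total = sum(uniq),
       n_cds = sum(uniq & kinds == "CDS"),
       n_trna = sum(uniq & kinds == "tRNA"),
       n_rrna = sum(uniq & kinds == "rRNA"),
       n_ir_duplicated = length(ir_dup),
       ir_duplicated = sort(ir_dup))
}

# ---------------------------------------------------------------------------

#' Summarize a panel of plastomes
#'
#' Runs IR detection, region profiling and the gene census on each record
#' and assembles the panel table (one row per accession, sorted by
#' accession).  Per-record failures (e.g. no detectable IR) are logged with
#' a warning and the row omitted.
#'
#' @param records List of annotated [plastome_record]s.
#' @param min_ir_len Passed to [detect_inverted_repeat()].
#' @return Data frame with columns `accession, taxon, family, genome_size,
#'   lsc_len, ssc_len, ir_len, n_cds, n_trna, n_rrna, gc_total, gc_lsc,
#'   gc_ssc, gc_ir` (GC as fractions).
#' @export
summarize_panel <- function(records, min_ir_len = 1000L) {
  if (length(records) == 0L) stop("summarize_panel: empty panel")
  rows <- lapply(records, function(rec) {
    tryCatch({
      part <- detect_inverted_repeat(rec, min_ir_len = min_ir_len)
      prof <- region_profiles(rec, part)
      cen <- gene_census(rec, part)
      lens <- partition_lengths(part)
      data.frame(accession = rec$accession, taxon = rec$taxon,
                 family = rec$family,
                 genome_size = part$genome_length,
                 lsc_len = lens[["lsc"]], ssc_len = lens[["ssc"]],
                 ir_len = lens[["irb"]],
                 n_cds = cen$n_cds, n_trna = cen$n_trna, n_rrna = cen$n_rrna,
                 gc_total = prof$gc[prof$region == "total"],
                 gc_lsc = prof$gc[prof$region == "LSC"],
                 gc_ssc = prof$gc[prof$region == "SSC"],
                 gc_ir = prof$gc[prof$region == "IR"],
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("summarize_panel: skipping %s: %s",
                      rec$accession, conditionMessage(e)))
      NULL
    })
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("summarize_panel: no record could be summarized")
  out <- do.call(rbind, rows)
  out[order(out$accession), , drop = FALSE]
}

#' Per-column range summary of a panel table
#'
#' For every numeric column reports `min`, `max`, `width = max - min` and
#' `mean`.
#'
#' @param table A panel table data frame.
#' @param columns Optional character vector restricting the summary.
#' @return Data frame with one row per column.
#' @export
range_summary <- function(table, columns = NULL) {
  if (nrow(table) == 0L) stop("range_summary: empty table")
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  if (!is.null(columns)) num <- intersect(columns, num)
  do.call(rbind, lapply(num, function(cn) {
    v <- table[[cn]]
    data.frame(column = cn, min = min(v), max = max(v),
               width = max(v) - min(v), mean = mean(v),
               stringsAsFactors = FALSE)
  }))
}
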