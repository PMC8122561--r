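# ---------------------------------------------------------------------------
# FASTA panel and panel-table I/O (Biostrings does the format work).
# ---------------------------------------------------------------------------

#' Read a multi-FASTA file as a panel of unannotated plastome records
#'
#' Headers are parsed as `"accession taxon..."`: the first whitespace token
#' is the accession, the remainder (if any) the taxon name.  Feature lists
#' are empty.  Duplicate accessions are an error.
#'
#' @param path FASTA file, one sequence per genome.
#' @return List of [plastome_record]s in file order (empty list for an
#'   empty file).
#' @export
read_fasta_panel <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) return(list())
  headers <- names(ss)
  acc <- vapply(strsplit(headers, "[[:space:]]+"), `[`, "", 1L)
  if (anyDuplicated(acc))
    stop("read_fasta_panel: duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  taxa <- mapply(function(h, a) {
    t <- trimws(sub("^[^[:space:]]+[[:space:]]*", "", h))
    if (t == "") a else t
  }, headers, acc, USE.NAMES = FALSE)
  lapply(seq_along(ss), function(i)
    plastome_record(accession = acc[i], sequence = as.character(ss[[i]]),
                    taxon = taxa[i]))
}

#' Write plastome records to a FASTA file
#'
#' Headers are `accession taxon`.
#'
#' @param records List of [plastome_record]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_panel <- function(records, path) {
  if (inherits(records, "plastome_record")) records <- list(records)
  ss <- Biostrings::DNAStringSet(vapply(records, function(r) r$sequence, ""))
  names(ss) <- vapply(records, function(r)
    if (identical(r$taxon, r$accession)) r$accession
    else paste(r$accession, r$taxon), "")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write a panel summary table to TSV
#'
#' Fixed column order: `accession, taxon, family, genome_size, lsc_len,
#' ssc_len, ir_len, n_cds, n_trna, n_rrna, gc_total, gc_lsc, gc_ssc, gc_ir`.
#' Lengths are written as integers and GC values as percentages with two
#' decimals.  Every row must satisfy the quadripartite tiling identity
#' `genome_size == lsc_len + ssc_len + 2 * ir_len`; a violating row is
#' refused.
#'
#' @param rows A panel table data frame, as produced by [summarize_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(rows, path) {
  need <- c("accession", "genome_size", "lsc_len", "ssc_len", "ir_len",
            "n_cds", "n_trna", "n_rrna", "gc_total", "gc_lsc", "gc_ssc", "gc_ir")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("write_panel_table: missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- rows$genome_size != rows$lsc_len + rows$ssc_len + 2L * rows$ir_len
  if (any(bad))
    stop("write_panel_table: tiling identity violated for: ",
         paste(rows$accession[bad], collapse = ", "))
  out <- data.frame(
    accession = rows$accession,
    taxon = if ("taxon" %in% names(rows)) rows$taxon else rows$accession,
    family = if ("family" %in% names(rows)) rows$family else NA_character_,
    genome_size = as.integer(rows$genome_size),
    lsc_len = as.integer(rows$lsc_len),
    ssc_len = as.integer(rows$ssc_len),
    ir_len = as.integer(rows$ir_len),
    n_cds = as.integer(rows$n_cds),
    n_trna = as.integer(rows$n_trna),
    n_rrna = as.integer(rows$n_rrna),
    gc_total = sprintf("%.2f", 100 * rows$gc_total),
    gc_lsc = sprintf("%.2f", 100 * rows$gc_lsc),
    gc_ssc = sprintf("%.2f", 100 * rows$gc_ssc),
    gc_ir = sprintf("%.2f", 100 * rows$gc_ir),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
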