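# ---------------------------------------------------------------------------
# Packaged reference panel: published summary characteristics of 92
# Myrtales plastomes (plus three Geraniales outgroups), transcribed from
# the literature.  Used for desk-checkable range/mean arithmetic; rows
# whose printed fields violate the quadripartite tiling identity are
# flagged, kept for range summaries and excluded from identity-based
# checks.
# ---------------------------------------------------------------------------

#' Published Myrtales panel summary (literature-transcribed)
#'
#' Returns the packaged summary table of 92 Myrtales chloroplast genomes
#' (six families) as published: per accession the genome, LSC, SSC and IR
#' lengths, gene-class counts and GC percentages.  Values are reproduced
#' verbatim from the printed source; `tiling_consistent` flags whether a
#' row satisfies `genome_size == lsc_len + ssc_len + 2 * ir_len` (a number
#' of printed rows do not, and are retained as printed).
#'
#' @param include_outgroups Also return the three Geraniales outgroup rows
#'   (default `FALSE`).
#' @return Data frame with columns `taxon, accession, family, genome_size,
#'   lsc_len, ssc_len, ir_len, n_cds, n_trna, n_rrna, gc_total, gc_lsc,
#'   gc_ssc, gc_ir, tiling_consistent` (GC in percent).
#' @export
myrtales_panel <- function(include_outgroups = FALSE) {
  path <- system.file("extdata", "myrtales_panel.tsv", package = "plastcomp",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!include_outgroups)
    tab <- tab[tab$family != "Geraniales_outgroup", , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
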