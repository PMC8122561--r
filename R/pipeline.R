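# ---------------------------------------------------------------------------
# End-to-end pipeline: structure table, junction table, locus extraction +
# filter, diversity table, hotspot ranking, optional NJ tree, and a
# machine-readable run log.  All randomness is funnelled through the single
# seed recorded in the config.
# ---------------------------------------------------------------------------

#' Build a pipeline run configuration
#'
#' @param input Either a character vector of GenBank file paths, or a list
#'   of [plastome_record]s (e.g. from [simulate_panel()]).
#' @param out_dir Output directory (created if needed).
#' @param min_ir_len Minimum IR length for structure detection.
#' @param flank_window Junction search window (bp).
#' @param min_len,min_variable_sites Locus filter thresholds (aligned
#'   length strict `>`, variable-column minimum).
#' @param gap_policy Diversity gap policy.
#' @param window,step Identity-profile parameters (alignment columns).
#' @param top_coding,top_noncoding Hotspot ranking depth per category.
#' @param reference Accession used as identity-profile reference (`NULL`
#'   disables the profile).
#' @param tree Logical; also build the NJ sanity tree from concatenated
#'   filtered loci.
#' @param seed Integer seed recorded in the run log.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, out_dir, min_ir_len = 1000L,
                       flank_window = 1500L, min_len = 200L,
                       min_variable_sites = 1L,
                       gap_policy = "complete_deletion",
                       window = 100L, step = 25L,
                       top_coding = 9L, top_noncoding = 12L,
                       reference = NULL, tree = TRUE, seed = 1L) {
  stopifnot(min_ir_len > 0, flank_window > 0, min_len > 0,
            min_variable_sites >= 0, window > 0, step > 0)
  structure(list(input = input, out_dir = out_dir, min_ir_len = min_ir_len,
                 flank_window = flank_window, min_len = min_len,
                 min_variable_sites = min_variable_sites,
                 gap_policy = gap_policy, window = window, step = step,
                 top_coding = top_coding, top_noncoding = top_noncoding,
                 reference = reference, tree = isTRUE(tree),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the comparative pipeline end to end
#'
#' Reads or receives a panel, then per record: IR detection and the
#' structure row; junction report; then across the panel: locus
#' extraction, the length/variability filter, the diversity table, the
#' hotspot ranking, the optional identity profile and NJ tree.  Failures
#' of one genome are logged and later stages skip that genome.  All
#' artifacts are written to `config$out_dir` as TSV/Newick/JSON; reruns
#' with the same config and seed are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts: `panel_table`,
#'   `junctions`, `kept_loci`, `diversity`, `hotspots`, `identity`,
#'   `newick`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  failures <- character()

  records <- if (is.character(config$input)) {
    if (length(config$input) == 0L) stop("run_pipeline: empty input; supply GenBank files or records")
    lapply(config$input, read_genbank)
  } else config$input
  if (length(records) == 0L) stop("run_pipeline: empty input; supply GenBank files or records")

  partitions <- list()
  ok_records <- list()
  for (rec in records) {
    p <- tryCatch(detect_inverted_repeat(rec, config$min_ir_len),
                  error = function(e) {
                    failures <<- c(failures, sprintf("%s: %s", rec$accession,
                                                     conditionMessage(e)))
                    NULL
                  })
    if (!is.null(p)) {
      partitions[[rec$accession]] <- p
      ok_records[[length(ok_records) + 1L]] <- rec
    }
  }
  if (length(ok_records) == 0L) stop("run_pipeline: no genome passed structure detection")

  panel_table <- summarize_panel(ok_records, config$min_ir_len)
  write_panel_table(panel_table, file.path(config$out_dir, "structure.tsv"))

  junctions <- junction_report_panel(ok_records, partitions,
                                     config$flank_window)
  utils::write.table(junctions, file.path(config$out_dir, "junctions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  kept <- list(); diversity <- NULL; hotspots <- NULL
  identity <- NULL; newick <- NULL
  if (length(ok_records) >= 2L) {
    loci <- extract_loci(ok_records, partitions)
    alns <- loci_as_alignments(loci)
    kept <- filter_loci(alns, config$min_len, config$min_variable_sites)
    writeLines(vapply(kept, `[[`, "", "name"),
               file.path(config$out_dir, "kept_loci.txt"))
    if (length(kept)) {
      diversity <- diversity_table(kept, config$gap_policy)
      write_diversity_table(diversity,
                            file.path(config$out_dir, "diversity.tsv"))
      hotspots <- rank_hotspots(diversity, config$top_coding,
                                config$top_noncoding)
      for (cat in c("coding", "noncoding")) {
        utils::write.table(hotspots[[cat]],
                           file.path(config$out_dir,
                                     paste0("hotspots_", cat, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    # whole-genome "alignment" is only defined without indels
    lens <- vapply(ok_records, function(r) nchar(r$sequence), 0L)
    if (length(unique(lens)) == 1L) {
      rows <- vapply(ok_records, `[[`, "", "sequence")
      names(rows) <- vapply(ok_records, `[[`, "", "accession")
      ga <- locus_alignment(rows, name = "genome", category = "noncoding")
      if (!is.null(config$reference))
        identity <- identity_profile(ga, config$reference,
                                     config$window, config$step)
      if (config$tree && length(ok_records) >= 3L) {
        d <- p_distance_matrix(ga)
        newick <- nj_tree(d, file.path(config$out_dir, "nj.nwk"))
        write_distance_matrix(d, file.path(config$out_dir, "pdist.tsv"))
      }
      if (!is.null(identity))
        utils::write.table(identity,
                           file.path(config$out_dir, "identity.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  log <- list(
    package_version = as.character(utils::packageVersion("plastcomp")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("input", "out_dir"))],
    n_input = length(records), n_analyzed = length(ok_records),
    n_loci_kept = length(kept), failures = failures)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(panel_table = panel_table, junctions = junctions,
                 kept_loci = kept, diversity = diversity,
                 hotspots = hotspots, identity = identity,
                 newick = newick, log = log))
}
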