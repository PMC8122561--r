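# ---------------------------------------------------------------------------
# IR/SC junction-gene mapping: which gene spans or flanks each of the four
# boundaries JLB (LSC/IRb), JSB (IRb/SSC), JSA (SSC/IRa), JLA (IRa/LSC),
# and at what distance.
# ---------------------------------------------------------------------------

#' Report gene placement at the four IR/SC junctions
#'
#' For each junction the report contains the spanning gene if one exists
#' (placement `spans`, distance 0, with the bp of the gene on either side of
#' the boundary), otherwise the nearest gene on each side within
#' `flank_window` bp (placements `left_of` / `right_of`, i.e. the gene lies
#' left/right of the junction, with its distance from the boundary).  When
#' two genes tie for nearest on a side, both are reported in coordinate
#' order.  Distances are measured on the canonical linearization to the
#' outermost endpoint of the (possibly compound) feature.  A junction with
#' no gene within the window yields one row with `gene = NA`.
#'
#' @param record An annotated [plastome_record].
#' @param partition Its `quadripartite_partition` (see
#'   [detect_inverted_repeat()]).
#' @param flank_window Search window in bp on each side (default 1500).
#' @return Data frame with columns `accession, junction, gene, placement,
#'   distance, overlap_left, overlap_right`.
#' @export
junction_report <- function(record, partition, flank_window = 1500L) {
  rec <- canonicalize_record(record, partition)
  n <- partition$genome_length
  junctions <- c(JLB = partition$lsc[2], JSB = partition$irb[2],
                 JSA = partition$ssc[2], JLA = partition$ira[2] %% n)

  feats <- Filter(function(f) !f$pseudo, rec$features)
  spans <- t(vapply(feats, feature_span, integer(2)))
  nm <- vapply(feats, `[[`, "", "name")

  rows <- list()
  for (jn in names(junctions)) {
    J <- junctions[[jn]]
    # circular signed position of feature endpoints relative to J, in
    # (-n/2, n/2]; the window is small so this is unambiguous
    rel <- function(p) {
      d <- (p - J) %% n
      ifelse(d > n %/% 2L, d - n, d)
    }
    got <- FALSE
    if (length(feats)) {
      a <- rel(spans[, 1]); b <- rel(spans[, 2])
      spanning <- which(a < 0 & b > 0)
      if (length(spanning)) {
        if (length(spanning) > 1)           # at most one reported: widest overlap
          spanning <- spanning[which.max(pmin(-a[spanning], b[spanning]))]
        i <- spanning
        rows[[length(rows) + 1L]] <- data.frame(
          accession = rec$accession, junction = jn, gene = nm[i],
          placement = "spans", distance = 0L,
          overlap_left = -a[i], overlap_right = b[i],
          stringsAsFactors = FALSE)
        got <- TRUE
      } else {
        # nearest gene strictly left of J (by its right end) and right of J
        dl <- ifelse(b <= 0, -b, NA_integer_)
        dr <- ifelse(a >= 0, a, NA_integer_)
        for (side in c("left_of", "right_of")) {
          d <- if (side == "left_of") dl else dr
          ok <- which(!is.na(d) & d <= flank_window)
          if (!length(ok)) next
          dmin <- min(d[ok])
          hit <- ok[d[ok] == dmin]
          hit <- hit[order(spans[hit, 1])]
          for (i in hit) {
            rows[[length(rows) + 1L]] <- data.frame(
              accession = rec$accession, junction = jn, gene = nm[i],
              placement = side, distance = as.integer(dmin),
              overlap_left = 0L, overlap_right = 0L,
              stringsAsFactors = FALSE)
          }
          got <- TRUE
        }
      }
    }
    if (!got)
      rows[[length(rows) + 1L]] <- data.frame(
        accession = rec$accession, junction = jn, gene = NA_character_,
        placement = "none", distance = NA_integer_,
        overlap_left = NA_integer_, overlap_right = NA_integer_,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Junction reports for a whole panel
#'
#' @param records List of annotated [plastome_record]s.
#' @param partitions Named list of partitions keyed by accession; detected
#'   on the fly when `NULL`.
#' @param flank_window Passed to [junction_report()].
#' @param min_ir_len Used when partitions are detected here.
#' @return One combined data frame.
#' @export
junction_report_panel <- function(records, partitions = NULL,
                                  flank_window = 1500L, min_ir_len = 1000L) {
  do.call(rbind, lapply(records, function(rec) {
    part <- if (is.null(partitions)) detect_inverted_repeat(rec, min_ir_len)
            else partitions[[rec$accession]]
    junction_report(rec, part, flank_window)
  }))
}
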