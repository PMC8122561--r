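# ---------------------------------------------------------------------------
# Per-locus diversity statistics, hypervariable-region ranking, and sliding
# window percent-identity profiles.
# ---------------------------------------------------------------------------

#' Nucleotide-diversity statistics of one locus alignment
#'
#' Computes, per locus:
#' * `S`  segregating (polymorphic) sites;
#' * `Eta`  total number of mutations (a site with `k` alleles contributes
#'   `k - 1`);
#' * `h`  number of distinct haplotypes and `Hd` haplotype diversity
#'   `(n/(n-1)) (1 - sum p_k^2)`;
#' * `Pi`  nucleotide diversity per site,
#'   `(2 / (n (n-1))) * sum_{i<j} d_ij / L_net`;
#' * `PIC`  parsimony-informative columns (>= 2 alleles each carried by
#'   >= 2 sequences).
#'
#' Under `complete_deletion` (the default) every column containing a gap,
#' `N` or other ambiguity code is removed first and all statistics are
#' computed on the `L_net` retained columns.  Under `pairwise_deletion`
#' site-based statistics (`S`, `Eta`, `PIC`) treat non-ACGT cells as
#' missing, haplotypes are compared on fully resolved columns, and each
#' pairwise distance is normalized by that pair's comparable columns.
#' When no column is retained the statistics are reported as `NA`, not as
#' zeros.
#'
#' @param aln A [locus_alignment()] with `n >= 2` rows.
#' @param gap_policy `"complete_deletion"` or `"pairwise_deletion"`.
#' @return One-row data frame: `name, category, n, L, L_net, S, Eta, h,
#'   Hd, Pi, PIC`.
#' @export
diversity_stats <- function(aln,
                            gap_policy = c("complete_deletion",
                                           "pairwise_deletion")) {
  gap_policy <- match.arg(gap_policy)
  m <- alignment_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("diversity_stats: need at least 2 sequences")
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)

  if (gap_policy == "complete_deletion") {
    keep <- colSums(ok) == n
    m2 <- m[, keep, drop = FALSE]
    L_net <- ncol(m2)
    if (L_net == 0L)
      return(empty_stats(aln, n))
    site <- site_allele_stats(m2, matrix(TRUE, n, L_net))
    haplo <- apply(m2, 1L, paste, collapse = "")
    d <- pair_differences(m2)
    Pi <- (2 / (n * (n - 1))) * sum(d) / L_net
  } else {
    L_net <- sum(colSums(ok) >= 2L)       # columns comparable for >=1 pair
    if (L_net == 0L)
      return(empty_stats(aln, n))
    site <- site_allele_stats(m, ok)
    res <- colSums(ok) == n
    haplo <- apply(m[, res, drop = FALSE], 1L, paste, collapse = "")
    props <- numeric(0)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) next
      props <- c(props, sum(m[i, comp] != m[j, comp]) / sum(comp))
    }
    Pi <- if (length(props)) mean(props) else NA_real_
  }

  tab <- table(haplo)
  h <- length(tab)
  p <- as.numeric(tab) / n
  Hd <- (n / (n - 1)) * (1 - sum(p^2))

  data.frame(name = aln$name, category = aln$category, n = n,
             L = aln$L, L_net = L_net,
             S = site$S, Eta = site$Eta, h = h, Hd = Hd, Pi = Pi,
             PIC = site$PIC, stringsAsFactors = FALSE)
}

empty_stats <- function(aln, n)
  data.frame(name = aln$name, category = aln$category, n = n, L = aln$L,
             L_net = 0L, S = NA_integer_, Eta = NA_integer_, h = NA_integer_,
             Hd = NA_real_, Pi = NA_real_, PIC = NA_integer_,
             stringsAsFactors = FALSE)

# S, Eta, PIC over columns; ok marks cells counted as observed alleles
site_allele_stats <- function(m, ok) {
  S <- 0L; Eta <- 0L; PIC <- 0L
  for (cix in seq_len(ncol(m))) {
    col <- m[ok[, cix], cix]
    if (length(col) < 2L) next
    tab <- table(col)
    k <- length(tab)
    if (k >= 2L) {
      S <- S + 1L
      Eta <- Eta + (k - 1L)
      if (sum(tab >= 2L) >= 2L) PIC <- PIC + 1L
    }
  }
  list(S = S, Eta = Eta, PIC = PIC)
}

# vector of pairwise Hamming distances over the columns of m (all i<j)
pair_differences <- function(m) {
  n <- nrow(m)
  idx <- 1L
  d <- integer(n * (n - 1L) / 2L)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[idx] <- sum(m[i, ] != m[j, ])
    idx <- idx + 1L
  }
  d
}

#' Diversity statistics for a list of alignments
#'
#' @param alignments List of [locus_alignment()]s.
#' @param gap_policy Passed to [diversity_stats()].
#' @return Data frame, one row per locus.
#' @export
diversity_table <- function(alignments,
                            gap_policy = c("complete_deletion",
                                           "pairwise_deletion")) {
  gap_policy <- match.arg(gap_policy)
  do.call(rbind, lapply(alignments, diversity_stats, gap_policy = gap_policy))
}

#' Write a diversity table to TSV
#'
#' Column order mirrors the conventional per-locus variability report:
#' `name, category, n, length, aligned_length, S, Eta, Pi, h, Hd, PIC`;
#' `Pi` and `Hd` to five decimals.
#'
#' @param stats Data frame from [diversity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diversity_table <- function(stats, path) {
  out <- data.frame(name = stats$name, category = stats$category,
                    n = stats$n, length = stats$L_net,
                    aligned_length = stats$L,
                    S = stats$S, Eta = stats$Eta,
                    Pi = sprintf("%.5f", stats$Pi),
                    h = stats$h, Hd = sprintf("%.5f", stats$Hd),
                    PIC = stats$PIC, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Rank hypervariable regions by nucleotide diversity
#'
#' Sorts loci in descending `Pi` (ties broken lexicographically by name)
#' and returns separate coding and noncoding rankings, optionally truncated
#' to the top `k` per category or thresholded on `Pi`.  The selection rule
#' is recorded in the result's `rule` attribute and in the `rank` column.
#'
#' @param stats Data frame from [diversity_table()].
#' @param top_coding,top_noncoding Keep the top `k` per category
#'   (default `Inf`, keep all).
#' @param pi_threshold Keep only loci with `Pi >= pi_threshold`.
#' @return List with data frames `coding` and `noncoding` (columns of
#'   `stats` plus `rank`).
#' @export
rank_hotspots <- function(stats, top_coding = Inf, top_noncoding = Inf,
                          pi_threshold = 0) {
  pick <- function(cat, k) {
    sub <- stats[stats$category == cat & !is.na(stats$Pi) &
                   stats$Pi >= pi_threshold, , drop = FALSE]
    sub <- sub[order(-sub$Pi, sub$name), , drop = FALSE]
    if (is.finite(k)) sub <- utils::head(sub, k)
    if (nrow(sub)) sub$rank <- seq_len(nrow(sub))
    rownames(sub) <- NULL
    sub
  }
  out <- list(coding = pick("coding", top_coding),
              noncoding = pick("noncoding", top_noncoding))
  attr(out, "rule") <- sprintf(
    "descending Pi, ties by name; top_coding=%s top_noncoding=%s pi_threshold=%g",
    top_coding, top_noncoding, pi_threshold)
  out
}

# ---------------------------------------------------------------------------

#' Sliding-window percent identity to a reference row
#'
#' Over windows of `window` alignment columns advanced by `step`, computes
#' for every non-reference row `100 * matches / (matches + mismatches)`,
#' counting only columns where neither row has a gap or ambiguity code.
#' Windows with no comparable column are `NA`.
#'
#' @param aln A [locus_alignment()] (typically a whole-genome alignment).
#' @param reference Accession of the reference row (must be present).
#' @param window Window size in columns (default 100).
#' @param step Step in columns (default 25).
#' @return Data frame with columns `start`, `end` (0-based half-open column
#'   range), `accession`, `identity`.
#' @export
identity_profile <- function(aln, reference, window = 100L, step = 25L) {
  if (!reference %in% names(aln$rows))
    stop("identity_profile: reference '", reference, "' not in alignment")
  m <- alignment_matrix(aln)
  rownames(m) <- names(aln$rows)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  ref <- m[reference, ]
  ref_ok <- ok[which(names(aln$rows) == reference)[1], ]
  others <- setdiff(names(aln$rows), reference)
  starts <- seq.int(0L, max(0L, aln$L - window), by = step)
  if (length(starts) == 0L) starts <- 0L
  rows <- list()
  for (accn in others) {
    q <- m[accn, ]
    q_ok <- ok[which(names(aln$rows) == accn)[1], ]
    comp <- ref_ok & q_ok
    match <- comp & (q == ref)
    cum_c <- cumsum(comp)
    cum_m <- cumsum(match)
    for (st in starts) {
      en <- min(st + window, aln$L)
      nc <- cum_c[en] - if (st > 0) cum_c[st] else 0
      nm <- cum_m[en] - if (st > 0) cum_m[st] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, end = en, accession = accn,
        identity = if (nc > 0) 100 * nm / nc else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}
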