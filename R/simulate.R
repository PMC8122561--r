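# ---------------------------------------------------------------------------
# Synthetic plastome panels with known ground truth: quadripartite layout,
# gene placements (junction-spanning and IR-duplicated genes included), and
# per-locus substitution rates.  Substitutions only -- no indels -- so the
# true alignments are known without running an aligner.
# ---------------------------------------------------------------------------

#' Specification of a synthetic plastome panel
#'
#' Region lengths default to a compact plastome-like layout (LSC 8000 bp,
#' IR 2000 bp, SSC 1500 bp) that preserves the real ordering
#' LSC > IR > SSC while keeping simulation cheap.  Each taxon is derived
#' from a common ancestor by Bernoulli-per-site substitutions at the rate
#' of the locus covering the site (Jukes-Cantor-style equal-probability
#' base changes); IR sites are mutated once on IRb and mirrored into IRa,
#' so the IR identity holds exactly in every taxon.
#'
#' @param n_taxa Number of taxa (default 6).
#' @param lsc_len,ssc_len,ir_len Region lengths in bp.
#' @param background_rate Substitutions per site per taxon branch for any
#'   site not covered by a named rate (default 0.005).
#' @param per_locus_rate Named numeric vector of per-site rates overriding
#'   the background for specific loci (gene names or `geneA-geneB` spacer
#'   names from the layout).
#' @param gene_layout Data frame from [default_gene_layout()]; regenerated
#'   for the given region lengths when `NULL`.
#' @param families Optional named integer vector of clade sizes summing to
#'   `n_taxa`; members of a clade share one extra round of mutations on a
#'   common family branch, making clades monophyletic in expectation.
#' @param seed Integer seed (mandatory; the panel is fully reproducible
#'   from it).
#' @return Object of class `synthetic_panel_spec`.
#' @export
synthetic_panel_spec <- function(n_taxa = 6L, lsc_len = 8000L,
                                 ssc_len = 1500L, ir_len = 2000L,
                                 background_rate = 0.005,
                                 per_locus_rate = NULL,
                                 gene_layout = NULL, families = NULL,
                                 seed) {
  if (missing(seed)) stop("synthetic_panel_spec: seed is mandatory")
  stopifnot(n_taxa >= 1L, lsc_len > ssc_len, ir_len > 0L,
            background_rate >= 0, background_rate <= 0.5)
  if (!is.null(per_locus_rate)) {
    stopifnot(!is.null(names(per_locus_rate)),
              all(per_locus_rate >= 0), all(per_locus_rate <= 0.5))
  }
  if (is.null(gene_layout))
    gene_layout <- default_gene_layout(lsc_len, ssc_len, ir_len)
  validate_layout(gene_layout, lsc_len, ssc_len, ir_len)
  if (!is.null(families)) {
    stopifnot(!is.null(names(families)), sum(families) == n_taxa)
  }
  structure(list(n_taxa = as.integer(n_taxa), lsc_len = as.integer(lsc_len),
                 ssc_len = as.integer(ssc_len), ir_len = as.integer(ir_len),
                 background_rate = background_rate,
                 per_locus_rate = per_locus_rate,
                 gene_layout = gene_layout, families = families,
                 seed = as.integer(seed)),
            class = "synthetic_panel_spec")
}

#' Default gene layout for a synthetic plastome
#'
#' A compact cast of real plastid genes covering every structural case the
#' pipeline must handle: LSC genes on both strands (`trnH-GUG`, `psbA`,
#' `matK`, `atpA`, `rbcL`), a gene spanning the LSC/IRb junction
#' (`rps19`), IR-duplicated genes (`rpl2`, `rrn16`), a gene spanning
#' IRb/SSC (`ndhF`), an SSC gene (`ndhD`) and a gene spanning SSC/IRa
#' (`ycf1`).  Offsets are relative to the containing region's start (genes
#' spanning a junction have offsets that run past the region end).
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bp.
#' @return Data frame with columns `name, kind, region, offset, length,
#'   strand, spans_junction, ir_duplicated`.
#' @export
default_gene_layout <- function(lsc_len = 8000L, ssc_len = 1500L,
                                ir_len = 2000L) {
  L <- lsc_len; S <- ssc_len; I <- ir_len
  f <- function(x) as.integer(round(x))
  layout <- rbind(
    data.frame(name = "trnH-GUG", kind = "tRNA", region = "LSC",
               offset = f(0.005 * L), length = 75L, strand = "-",
               spans_junction = FALSE, ir_duplicated = FALSE),
    data.frame(name = "psbA", kind = "CDS", region = "LSC",
               offset = f(0.025 * L), length = 1062L, strand = "-",
               spans_junction = FALSE, ir_duplicated = FALSE),
    data.frame(name = "matK", kind = "CDS", region = "LSC",
               offset = f(0.20 * L), length = 1530L, strand = "+",
               spans_junction = FALSE, ir_duplicated = FALSE),
    data.frame(name = "atpA", kind = "CDS", region = "LSC",
               offset = f(0.425 * L), length = 1524L, strand = "+",
               spans_junction = FALSE, ir_duplicated = FALSE),
    data.frame(name = "rbcL", kind = "CDS", region = "LSC",
               offset = f(0.65 * L), length = 1428L, strand = "+",
               spans_junction = FALSE, ir_duplicated = FALSE),
    data.frame(name = "rps19", kind = "CDS", region = "LSC",
               offset = L - 140L, length = 279L, strand = "+",
               spans_junction = TRUE, ir_duplicated = FALSE),
    data.frame(name = "rpl2", kind = "CDS", region = "IRb",
               offset = f(0.10 * I), length = 750L, strand = "-",
               spans_junction = FALSE, ir_duplicated = TRUE),
    data.frame(name = "rrn16", kind = "rRNA", region = "IRb",
               offset = f(0.50 * I), length = 500L, strand = "+",
               spans_junction = FALSE, ir_duplicated = TRUE),
    data.frame(name = "ndhF", kind = "CDS", region = "IRb",
               offset = I - 200L, length = 700L, strand = "-",
               spans_junction = TRUE, ir_duplicated = FALSE),
    data.frame(name = "ndhD", kind = "CDS", region = "SSC",
               offset = f(0.37 * S), length = 450L, strand = "-",
               spans_junction = FALSE, ir_duplicated = FALSE),
    data.frame(name = "ycf1", kind = "CDS", region = "SSC",
               offset = S - 450L, length = 850L, strand = "+",
               spans_junction = TRUE, ir_duplicated = FALSE))
  layout$name <- as.character(layout$name)
  layout
}

# genome-coordinate [start, end) of a layout row
layout_span <- function(row, lsc_len, ssc_len, ir_len) {
  base <- switch(row$region,
                 LSC = 0L, IRb = lsc_len,
                 SSC = lsc_len + ir_len,
                 IRa = lsc_len + ir_len + ssc_len)
  c(base + row$offset, base + row$offset + row$length)
}

validate_layout <- function(layout, lsc_len, ssc_len, ir_len) {
  n <- lsc_len + ssc_len + 2L * ir_len
  region_len <- c(LSC = lsc_len, IRb = ir_len, SSC = ssc_len, IRa = ir_len)
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    sp <- layout_span(row, lsc_len, ssc_len, ir_len)
    if (row$offset < 0L || sp[2] > n)
      stop("layout overflow: gene '", row$name, "' does not fit the genome")
    if (!row$spans_junction && row$offset + row$length > region_len[[row$region]])
      stop("layout overflow: gene '", row$name,
           "' exceeds its region but is not marked junction-spanning")
    if (row$ir_duplicated && row$region != "IRb")
      stop("layout: IR-duplicated gene '", row$name, "' must be laid out in IRb")
  }
  invisible(layout)
}

# ---------------------------------------------------------------------------

#' Simulate a plastome panel with known ground truth
#'
#' Builds a random ancestor genome with `IRa = revcomp(IRb)` exactly,
#' annotates it from the layout (IR-duplicated genes get a mirrored IRa
#' copy on the opposite strand), then derives each taxon by seeded
#' per-site substitutions.  The four single-copy bases abutting the
#' junctions are held fixed so that the maximal inverted repeat of every
#' derived genome is exactly the constructed one.
#'
#' @param spec A [synthetic_panel_spec()].
#' @param out_dir Optional directory; when given, each record is also
#'   written there as `<accession>.gb`.
#' @return List with `records` (list of [plastome_record]s), and `truth`:
#'   `partition` (the constructed `quadripartite_partition`),
#'   `rates` (named per-locus rate vector covering genes and spacers),
#'   `clade_map` (accession -> family), `layout`, and `spec`.
#' @export
simulate_panel <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  set.seed(spec$seed)
  L <- spec$lsc_len; S <- spec$ssc_len; I <- spec$ir_len
  n <- L + S + 2L * I
  bases <- c("A", "C", "G", "T")

  core <- sample(bases, L + I + S, replace = TRUE)   # LSC | IRb | SSC
  # break the repeat at both boundaries so detection recovers exactly the
  # constructed IR: last-LSC vs comp(first-LSC), first-SSC vs comp(last-SSC)
  while (core[L] == comp_base(core[1L]))
    core[L] <- sample(setdiff(bases, core[L]), 1L)
  while (core[L + I + 1L] == comp_base(core[L + I + S]))
    core[L + I + 1L] <- sample(setdiff(bases, core[L + I + 1L]), 1L)
  frozen <- c(1L, L, L + I + 1L, L + I + S)          # 1-based core positions

  partition <- structure(list(
    lsc = c(0L, L), irb = c(L, L + I), ssc = c(L + I, L + I + S),
    ira = c(L + I + S, n), offset = 0L, genome_length = n),
    class = "quadripartite_partition")

  features <- layout_features(spec$gene_layout, L, S, I)
  rate_info <- site_rates(spec, features, L, S, I)

  # family branches, then taxon branches
  fams <- spec$families
  if (is.null(fams)) fams <- stats::setNames(spec$n_taxa, NA_character_)
  records <- list()
  clade_map <- character()
  t_ix <- 0L
  for (fi in seq_along(fams)) {
    fam_name <- names(fams)[fi]
    fam_core <- if (is.na(fam_name)) core else
      mutate_core(core, rate_info$rate, frozen)
    for (k in seq_len(fams[[fi]])) {
      t_ix <- t_ix + 1L
      acc <- sprintf("SIM%02d", t_ix)
      taxon_core <- mutate_core(fam_core, rate_info$rate, frozen)
      genome <- c(taxon_core,
                  rev(chartr_vec(taxon_core[(L + 1L):(L + I)])))
      rec <- plastome_record(
        accession = acc, sequence = paste(genome, collapse = ""),
        taxon = sprintf("Synthetic taxon %02d", t_ix),
        family = if (is.na(fam_name)) NA_character_ else fam_name,
        circular = TRUE, features = features)
      records[[t_ix]] <- rec
      clade_map[acc] <- if (is.na(fam_name)) NA_character_ else fam_name
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rec in records)
      write_genbank(rec, file.path(out_dir, paste0(rec$accession, ".gb")))
  }
  list(records = records,
       truth = list(partition = partition, rates = rate_info$per_locus,
                    clade_map = clade_map, layout = spec$gene_layout,
                    spec = spec))
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
chartr_vec <- function(v) c(A = "T", C = "G", G = "C", T = "A")[v]

# annotate genome features from the layout (adds mirrored IRa copies)
layout_features <- function(layout, L, S, I) {
  irb_start <- L; ira_start <- L + I + S
  feats <- list()
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    sp <- layout_span(row, L, S, I)
    feats[[length(feats) + 1L]] <-
      gene_feature(row$name, row$kind, row$strand, c(sp[1], sp[2]))
    if (row$ir_duplicated) {
      u <- sp[1] - irb_start; v <- sp[2] - irb_start   # IRb-relative
      mir <- c(ira_start + I - v, ira_start + I - u)
      feats[[length(feats) + 1L]] <-
        gene_feature(row$name, row$kind,
                     if (row$strand == "+") "-" else "+", mir)
    }
  }
  feats
}

# per-site rate vector over the mutable core (LSC|IRb|SSC) plus the
# per-locus truth map (genes and spacers)
site_rates <- function(spec, features, L, S, I) {
  core_len <- L + I + S
  rate <- rep(spec$background_rate, core_len)
  locus_rate <- function(nm) {
    r <- spec$per_locus_rate[nm]
    if (is.null(r) || is.na(r)) spec$background_rate else unname(r)
  }
  per_locus <- character(0)
  rates_out <- numeric(0)

  lay <- spec$gene_layout
  for (i in seq_len(nrow(lay))) {
    row <- lay[i, ]
    sp <- layout_span(row, L, S, I)
    r <- locus_rate(row$name)
    idx <- (sp[1] + 1L):min(sp[2], core_len)          # IRa tails mirror IRb
    rate[idx] <- r
    rates_out[row$name] <- r
  }
  # spacers between consecutive gene spans (incl. wrap), as extract_loci
  # names them; IR-duplicated mirror copies included to match extraction
  feats <- features
  spans <- t(vapply(feats, feature_span, integer(2)))
  nm <- vapply(feats, `[[`, "", "name")
  o <- order(spans[, 1], spans[, 2])
  spans <- spans[o, , drop = FALSE]; nm <- nm[o]
  k <- nrow(spans)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    a <- spans[i, 2]
    b <- if (i == k) spans[j, 1] + (core_len + I) else spans[j, 1]
    if (b <= a) next
    spacer <- sprintf("%s-%s", nm[i], nm[j])
    r <- locus_rate(spacer)
    idx <- (a + 1L):b
    idx <- idx[idx <= core_len]
    if (length(idx)) rate[idx] <- r
    rates_out[spacer] <- r
  }
  list(rate = rate, per_locus = rates_out)
}

# one branch of per-site substitutions over the core, frozen sites skipped
mutate_core <- function(core, rate, frozen) {
  hit <- which(stats::runif(length(core)) < rate)
  hit <- setdiff(hit, frozen)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    core[hit] <- vapply(core[hit], function(b)
      sample(setdiff(bases, b), 1L), "")
  }
  core
}
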