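# ---------------------------------------------------------------------------
# GenBank flat-file reading and writing.
#
# A deliberately small parser covering the subset of the format that
# annotated organellar genomes use: LOCUS / DEFINITION / ACCESSION / VERSION /
# ORGANISM headers, a FEATURES table with gene / CDS / tRNA / rRNA keys
# (simple, complement(), join() and order() locations, possibly spanning
# continuation lines), /gene, /product and /pseudo qualifiers, and an ORIGIN
# sequence block.  Other feature keys (misc_feature, repeat_region, source,
# ...) are ignored: the gene census counts only the three gene classes.
# ---------------------------------------------------------------------------

#' Read a GenBank flat file into a plastome record
#'
#' Coordinates are converted from GenBank's 1-based inclusive convention to
#' the package-internal 0-based half-open convention.  Compound `join()`
#' locations are preserved as multiple intervals.  Features carrying no
#' `/gene` qualifier are named from their `/product` when possible, otherwise
#' skipped with a warning.  An unparseable location also produces a warning
#' and the feature is skipped; a missing sequence is a hard error.
#'
#' @param path Path to a GenBank flat file containing a single record.
#' @return A [plastome_record].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("read_genbank: empty file: ", path)

  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("read_genbank: no LOCUS line in ", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "[[:space:]]+")[[1]]
  circular <- any(tolower(locus) == "circular")
  locus_name <- if (length(locus) >= 2) locus[2] else NA_character_

  grab1 <- function(key) {
    i <- grep(paste0("^", key), lines)
    if (length(i) == 0L) return(NA_character_)
    trimws(sub(paste0("^", key, "[[:space:]]*"), "", lines[i[1]]))
  }
  accession <- grab1("VERSION")
  if (is.na(accession) || accession == "")
    accession <- grab1("ACCESSION")
  if (is.na(accession) || accession == "") accession <- locus_name
  accession <- strsplit(accession, "[[:space:]]+")[[1]][1]
  organism <- grab1("[[:space:]]{2}ORGANISM")
  if (is.na(organism)) organism <- accession

  # --- sequence ---
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("read_genbank: record has no ORIGIN sequence block")
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > ori[1]][1] else length(lines) + 1L
  if (is.na(end)) end <- length(lines) + 1L
  seq_lines <- lines[seq.int(ori[1] + 1L, end - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("read_genbank: record has an empty sequence")

  # --- features ---
  feat_i <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_i)) {
    block <- lines[seq.int(feat_i[1] + 1L, ori[1] - 1L)]
    # feature key lines have the key starting at column 6
    key_at <- grep("^ {1,8}[A-Za-z0-9_'-]+ {1,}\\S", block)
    key_at <- key_at[!grepl("^ {10,}", block[key_at])]
    if (length(key_at)) {
      bounds <- c(key_at, length(block) + 1L)
      for (k in seq_along(key_at)) {
        chunk <- block[seq.int(bounds[k], bounds[k + 1L] - 1L)]
        key <- sub("^ +(\\S+).*", "\\1", chunk[1])
        if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
        f <- parse_genbank_feature(key, chunk)
        if (!is.null(f)) features <- c(features, list(f))
      }
    }
  }
  features <- collapse_gene_keys(features)
  plastome_record(accession = accession, sequence = sequence,
                  taxon = organism, circular = circular, features = features)
}

# parse one feature chunk (key line + continuations) into a gene_feature
parse_genbank_feature <- function(key, chunk) {
  txt <- paste(trimws(chunk), collapse = "\n")
  # location: everything after the key up to the first qualifier line
  qual_start <- grep("^ */", trimws(chunk))
  loc_lines <- if (length(qual_start)) chunk[seq_len(qual_start[1] - 1L)] else chunk
  loc <- gsub("[[:space:]]", "", sub("^ +\\S+ +", "", paste(loc_lines, collapse = "")))
  iv <- tryCatch(parse_genbank_location(loc), error = function(e) NULL)
  if (is.null(iv)) {
    warning(sprintf("skipping %s feature with unparseable location '%s'", key, loc))
    return(NULL)
  }
  qual <- function(q) {
    m <- regmatches(txt, regexec(sprintf('/%s="?([^"\n]*)"?', q), txt))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  name <- qual("gene")
  if (is.na(name) || name == "") {
    prod <- qual("product")
    if (!is.na(prod) && prod != "") {
      name <- gsub("[[:space:]]+", "_", prod)
    } else {
      warning(sprintf("skipping unnamed %s feature at %s", key, loc))
      return(NULL)
    }
  }
  pseudo <- grepl("/pseudo(\\b|$)", txt) || grepl("/pseudogene=", txt)
  kind <- if (key == "gene") infer_kind(name) else key
  f <- gene_feature(name = normalize_gene_symbol(name), kind = kind,
                    strand = attr(iv, "strand"), intervals = iv, pseudo = pseudo)
  attr(f, "gb_key") <- key
  f
}

# "join(complement(10..20),30..40)" etc. -> 0-based half-open matrix,
# strand in attr.  Partial markers (<, >) are stripped.
parse_genbank_location <- function(loc) {
  strand <- "+"
  x <- loc
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
  # complement() may also wrap the inner pieces
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  iv <- t(vapply(parts, function(p) {
    if (grepl("^complement\\(", p)) {
      strand <<- "-"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    p <- gsub("[<>]", "", p)
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      ab <- c(as.integer(p), as.integer(p))
    } else stop("bad location piece: ", p)
    c(ab[1] - 1L, ab[2])
  }, integer(2)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  attr(iv, "strand") <- strand
  iv
}

# a bare `gene` key duplicates its typed CDS/tRNA/rRNA feature in most
# files; keep the typed feature, and keep a gene-key feature only when no
# typed feature of the same name overlaps its span (the typed copy carries
# the exact exon structure)
collapse_gene_keys <- function(features) {
  if (length(features) == 0L) return(features)
  key_of <- vapply(features, function(f) attr(f, "gb_key") %||% f$kind, "")
  typed <- features[key_of != "gene"]
  bare <- features[key_of == "gene"]
  keep_bare <- vapply(bare, function(g) {
    gs <- feature_span(g)
    !any(vapply(typed, function(t) {
      if (t$name != g$name) return(FALSE)
      ts <- feature_span(t)
      ts[1] < gs[2] && gs[1] < ts[2]
    }, TRUE))
  }, TRUE)
  c(typed, bare[keep_bare])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_kind <- function(name) {
  if (grepl("^trn", name, ignore.case = TRUE)) "tRNA"
  else if (grepl("^rrn", name, ignore.case = TRUE)) "rRNA"
  else "CDS"
}

#' Normalize a plastid gene symbol
#'
#' Junction and locus matching across genomes is name-based, so symbols are
#' case-normalized to the conventional plastid form: lower-case prefix with
#' the capitalization pattern of known symbols (`ndhF`, `trnH-GUG`, `ycf1`,
#' `rrn16`, ...).  Anticodon suffixes such as `-GUG` are kept verbatim.
#'
#' @param name Raw gene symbol.
#' @return Normalized symbol.
#' @export
normalize_gene_symbol <- function(name) {
  name <- trimws(name)
  # split an anticodon / copy suffix off: trnH-GUG, trnS(GCU) -> keep verbatim
  m <- regexec("^([A-Za-z0-9]+)([-(].*)?$", name)[[1]]
  if (m[1] == -1) return(name)
  base <- regmatches(name, regexec("^([A-Za-z0-9]+)", name))[[1]][2]
  suffix <- substr(name, nchar(base) + 1L, nchar(name))
  # conventional plastid style: 3-letter lower-case class prefix + upper tail
  base2 <- sub("^((?i)atp|(?i)ndh|(?i)pet|(?i)psa|(?i)psb|(?i)rbc|(?i)rpl|(?i)rps|(?i)rpo|(?i)trn|(?i)rrn|(?i)ycf|(?i)inf|(?i)mat|(?i)ccs|(?i)cem|(?i)clp|(?i)acc)",
               "\\L\\1", base, perl = TRUE)
  paste0(base2, suffix)
}

# ---------------------------------------------------------------------------

#' Write a plastome record as a GenBank flat file
#'
#' Emits the minimal subset read back by [read_genbank]: LOCUS, DEFINITION,
#' ACCESSION/VERSION, ORGANISM, one typed feature (CDS/tRNA/rRNA) per gene
#' feature with a `/gene` qualifier (1-based inclusive, `join()` and
#' `complement()` as needed), and the ORIGIN block.  A write-then-read round
#' trip reproduces the record's sequence and feature intervals exactly.
#'
#' @param record A [plastome_record].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  n <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  locus_name <- gsub("[[:space:]]", "_", record$accession)
  w("LOCUS       %-17s %d bp    DNA     %s PLN 01-JAN-2000",
    locus_name, n, if (record$circular) "circular" else "linear")
  w("DEFINITION  %s chloroplast genome.", record$taxon)
  w("ACCESSION   %s", sub("\\.\\d+$", "", record$accession))
  w("VERSION     %s", record$accession)
  w("SOURCE      %s", record$taxon)
  w("  ORGANISM  %s", record$taxon)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", n)
  w("                     /organism=\"%s\"", record$taxon)
  for (f in record$features) {
    loc <- paste(sprintf("%d..%d", f$intervals[, 1] + 1L, f$intervals[, 2]),
                 collapse = ",")
    if (nrow(f$intervals) > 1) loc <- sprintf("join(%s)", loc)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    w("     %-15s %s", f$kind, loc)
    w("                     /gene=\"%s\"", f$name)
    if (f$pseudo) w("                     /pseudo")
  }
  w("ORIGIN")
  for (i in seq(1L, n, by = 60L)) {
    chunk <- substr(record$sequence, i, min(i + 59L, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    w("%9d %s", i, tolower(paste(blocks, collapse = " ")))
  }
  writeLines("//", con)
  invisible(path)
}
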