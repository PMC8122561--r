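# Independent reference implementations and small builders used across the
# suite.  These are deliberately naive (explicit loops, no shared code with
# the package internals) so they can serve as oracles.

BASES <- c("A", "C", "G", "T")

# naive O(n^2 L) diversity statistics under complete deletion
naive_diversity <- function(rows) {
  m <- do.call(rbind, strsplit(unname(rows), ""))
  n <- nrow(m)
  keep <- logical(ncol(m))
  for (cix in seq_len(ncol(m))) keep[cix] <- all(m[, cix] %in% BASES)
  m <- m[, keep, drop = FALSE]
  L_net <- ncol(m)
  if (L_net == 0L) return(NULL)
  S <- 0L; Eta <- 0L; PIC <- 0L
  for (cix in seq_len(L_net)) {
    alleles <- table(m[, cix])
    if (length(alleles) >= 2L) {
      S <- S + 1L
      Eta <- Eta + length(alleles) - 1L
      if (sum(alleles >= 2L) >= 2L) PIC <- PIC + 1L
    }
  }
  total_diff <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dd <- 0L
    for (cix in seq_len(L_net)) if (m[i, cix] != m[j, cix]) dd <- dd + 1L
    total_diff <- total_diff + dd
  }
  Pi <- (2 / (n * (n - 1))) * total_diff / L_net
  haplo <- apply(m, 1, paste, collapse = "")
  counts <- table(haplo)
  h <- length(counts)
  Hd <- (n / (n - 1)) * (1 - sum((as.numeric(counts) / n)^2))
  list(L_net = L_net, S = S, Eta = Eta, h = h, Hd = Hd, Pi = Pi, PIC = PIC)
}

# random alignment with optional gaps/Ns
random_alignment <- function(n, L, p_gap = 0, p_n = 0, name = "locus",
                             category = "noncoding") {
  rows <- vapply(seq_len(n), function(i) {
    v <- sample(BASES, L, replace = TRUE)
    if (p_gap > 0) v[runif(L) < p_gap] <- "-"
    if (p_n > 0) v[runif(L) < p_n] <- "N"
    paste(v, collapse = "")
  }, "")
  names(rows) <- sprintf("T%02d", seq_len(n))
  locus_alignment(rows, name = name, category = category)
}

# random sequence as a string
random_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

# rotate a circular sequence string so 0-based position off becomes first
rotate_sequence_str <- function(s, off) {
  off <- off %% nchar(s)
  if (off == 0) return(s)
  paste0(substr(s, off + 1, nchar(s)), substr(s, 1, off))
}

# genome assembled as LSC | R | SSC | revcomp(R), with the repeat broken at
# both boundaries so the constructed IR is maximal
constructed_ir_genome <- function(lsc = 8000, ir = 2000, ssc = 1500) {
  repeat {
    lsc_s <- random_seq(lsc); ir_s <- random_seq(ir); ssc_s <- random_seq(ssc)
    g <- paste0(lsc_s, ir_s, ssc_s, revcomp(ir_s))
    ok1 <- substr(g, lsc, lsc) != revcomp(substr(g, 1, 1))
    ok2 <- substr(g, lsc + ir + 1, lsc + ir + 1) !=
      revcomp(substr(g, lsc + ir + ssc, lsc + ir + ssc))
    if (ok1 && ok2) return(list(sequence = g, lsc = lsc, ir = ir, ssc = ssc))
  }
}
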