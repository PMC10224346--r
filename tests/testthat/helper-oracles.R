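# Independent oracles, written separately from the package implementations.

# codon table via base-4 indexing into the classic 64-letter string
# (TTT, TTC, TTG, ... ordering with T=0, C=1, A=2, G=3)
oracle_translate <- function(cds) {
  aa64 <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  idx <- c(T = 0L, C = 1L, A = 2L, G = 3L)
  ch <- strsplit(toupper(cds), "")[[1L]]
  n <- length(ch) %/% 3L
  out <- character(0)
  for (k in seq_len(n)) {
    b <- ch[(3L * (k - 1L) + 1L):(3L * k)]
    aa <- substr(aa64, idx[[b[1L]]] * 16L + idx[[b[2L]]] * 4L + idx[[b[3L]]] + 1L,
                 idx[[b[1L]]] * 16L + idx[[b[2L]]] * 4L + idx[[b[3L]]] + 1L)
    if (aa == "*") return(out)
    out <- c(out, aa)
  }
  out
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(s), "")[[1L]]]), collapse = "")
}

# brute-force six-frame ORF scan: every ATG paired with its first in-frame
# stop; coordinates on the forward strand, 1-based inclusive of the stop
oracle_orfs <- function(seq, min_len_aa) {
  L <- nchar(seq)
  res <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (start in 1:(L - 5L)) {
      if (substr(s, start, start + 2L) != "ATG") next
      frame_ok <- FALSE
      p <- start + 3L
      while (p + 2L <= L) {
        cod <- substr(s, p, p + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) { frame_ok <- TRUE; break }
        p <- p + 3L
      }
      if (!frame_ok) next
      len_aa <- (p - start) / 3L
      if (len_aa < min_len_aa) next
      b <- start; e <- p + 2L
      if (strand == "-") { fb <- L - e + 1L; fe <- L - b + 1L } else { fb <- b; fe <- e }
      res <- rbind(res, data.frame(start = fb, end = fe, strand = strand,
                                   stringsAsFactors = FALSE))
    }
  }
  res <- res[order(res$start, res$strand, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exhaustive position-by-position motif count
oracle_motifs <- function(protein) {
  ch <- strsplit(protein, "")[[1L]]
  n <- length(ch)
  counts <- c(CC = 0L, CXC = 0L, CXXC = 0L)
  for (i in seq_len(n)) {
    if (i + 1L <= n && ch[i] == "C" && ch[i + 1L] == "C")
      counts["CC"] <- counts["CC"] + 1L
    if (i + 2L <= n && ch[i] == "C" && ch[i + 1L] != "C" && ch[i + 2L] == "C")
      counts["CXC"] <- counts["CXC"] + 1L
    if (i + 3L <= n && ch[i] == "C" && ch[i + 1L] != "C" &&
        ch[i + 2L] != "C" && ch[i + 3L] == "C")
      counts["CXXC"] <- counts["CXXC"] + 1L
  }
  counts
}

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# canonical split string matching tree_splits()
canon_split <- function(set, all_labels) {
  anchor <- sort(all_labels)[1L]
  if (anchor %in% set) set <- setdiff(all_labels, set)
  paste(sort(set), collapse = "|")
}
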