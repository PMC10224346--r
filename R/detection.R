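#' Reverse complement of a nucleotide string
#' @param s Nucleotide string over `ACGTN`.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan all six reading frames for open reading frames
#'
#' An ORF runs from an ATG to the next in-frame stop (TAA, TAG or TGA),
#' inclusive of the stop codon.  Every ATG opens an ORF, so ORFs sharing a
#' stop are all reported.  Coordinates are 1-based inclusive on the forward
#' strand of the contig regardless of ORF strand.
#'
#' @param contig An `mt_seq` nucleotide record.
#' @param min_len_aa Minimum protein length (stop excluded) to report.
#' @return A data frame with columns `start`, `end`, `strand`, `protein`,
#'   ordered by `start` then `strand`.
#' @export
find_orfs <- function(contig, min_len_aa = 20L) {
  stopifnot(inherits(contig, "mt_seq"), contig$moltype == "nucleotide",
            min_len_aa >= 1L)
  s <- contig$residues
  L <- nchar(s)
  n_frac <- sum(strsplit(s, "")[[1L]] == "N") / L
  if (n_frac > 0.5) stop("low-complexity contig: '", contig$id, "' is >50% N")
  out <- list()
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      n_codon <- (L - frame) %/% 3L
      if (n_codon < 2L) next
      starts_nt <- frame + 3L * (seq_len(n_codon) - 1L) + 1L
      codons <- substring(seqs, starts_nt, starts_nt + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% c("TAA", "TAG", "TGA"))
      if (!length(atg) || !length(stp)) next
      # first stop at or after each ATG (the ATG itself is never a stop)
      idx <- findInterval(atg, stp) + 1L
      ok <- idx <= length(stp)
      atg <- atg[ok]; idx <- idx[ok]
      stop_codon_i <- stp[idx]
      len_aa <- stop_codon_i - atg
      keep <- len_aa >= min_len_aa
      if (!any(keep)) next
      atg <- atg[keep]; stop_codon_i <- stop_codon_i[keep]
      b <- frame + 3L * (atg - 1L) + 1L          # ORF begin in seqs coords
      e <- frame + 3L * stop_codon_i             # end of stop codon
      prot <- vapply(seq_along(atg), function(i) {
        translate_cds(substr(seqs, b[i], e[i]), warn = FALSE)$protein
      }, "")
      if (strand == "-") {
        fb <- L - e + 1L; fe <- L - b + 1L
      } else {
        fb <- b; fe <- e
      }
      out[[length(out) + 1L]] <- data.frame(
        start = fb, end = fe, strand = strand, protein = prot,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count cysteine motifs in a protein
#'
#' Counts left-to-right, overlap-allowed occurrences of the three canonical
#' metal-binding cysteine arrangements Cys-Cys, Cys-X-Cys and Cys-X-X-Cys,
#' where X is any residue other than cysteine.
#'
#' @param protein An `mt_seq` protein record or a plain residue string.
#' @return Named integer vector with elements `CC`, `CXC`, `CXXC`.
#' @export
count_cys_motifs <- function(protein) {
  s <- if (inherits(protein, "mt_seq")) protein$residues else toupper(protein)
  ch <- strsplit(s, "")[[1L]]
  cys <- ch == "C"
  n <- length(cys)
  cc <- if (n >= 2L) sum(cys[-n] & cys[-1L]) else 0L
  cxc <- if (n >= 3L) sum(cys[1:(n - 2L)] & !cys[2:(n - 1L)] & cys[3:n]) else 0L
  cxxc <- if (n >= 4L) {
    sum(cys[1:(n - 3L)] & !cys[2:(n - 2L)] & !cys[3:(n - 1L)] & cys[4:n])
  } else 0L
  c(CC = as.integer(cc), CXC = as.integer(cxc), CXXC = as.integer(cxxc))
}

# logical vector marking cysteines that take part in >=1 CC/CXC/CXXC motif
.cys_in_motifs <- function(cys) {
  n <- length(cys)
  part <- logical(n)
  mark <- function(i, j) if (cys[i] && cys[j] && all(!cys[seq(i + 1L, length.out = j - i - 1L)])) {
    part[c(i, j)] <<- TRUE
  }
  for (i in seq_len(n)) {
    for (j in (i + 1L):min(i + 3L, n)) {
      if (j > n || j <= i) next
      mark(i, j)
    }
  }
  part
}

#' Structural profile of a candidate metallothionein protein
#'
#' Mammalian MTs are 61-68 aa, >30% cysteine, with the cysteines arranged in
#' CC/CXC/CXXC motifs and partitioned into an N-terminal beta domain (9 Cys,
#' 3 metal cations) and a C-terminal alpha domain (11 Cys, 4 cations).  The
#' profile records the measurements this grammar constrains; the domain
#' split is placed at the position best matching the 9/11 stoichiometry.
#'
#' @inheritParams count_cys_motifs
#' @return A list with `length_aa`, `cys_count`, `cys_fraction`,
#'   `motif_counts`, `beta_cys`, `alpha_cys`, `linker_index` (last residue
#'   of the beta segment).
#' @export
mt_protein_profile <- function(protein) {
  s <- if (inherits(protein, "mt_seq")) protein$residues else toupper(protein)
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  cys <- ch == "C"
  total <- sum(cys)
  cum <- cumsum(cys)
  splits <- seq_len(max(n - 1L, 1L))
  dev <- abs(cum[splits] - 9L) + abs((total - cum[splits]) - 11L)
  k <- splits[which.min(dev)]
  list(length_aa = n, cys_count = as.integer(total),
       cys_fraction = total / n,
       motif_counts = count_cys_motifs(s),
       beta_cys = as.integer(cum[k]), alpha_cys = as.integer(total - cum[k]),
       linker_index = as.integer(k))
}

#' Default weights and thresholds for MT-likeness scoring
#' @param weights Named weights for the four score components.
#' @param threshold Pass threshold on the weighted mean.
#' @param length_peak Protein lengths scoring 1 (inclusive).
#' @param length_halo Lengths at which the linear decay reaches 0.
#' @param domain_tol Allowed deviation (per domain) from the 9/11 split.
#' @return A list of scoring parameters.
#' @export
mt_score_config <- function(weights = c(length = 1, cys_fraction = 1,
                                        motif = 1, domain_layout = 1),
                            threshold = 0.75,
                            length_peak = c(61L, 68L),
                            length_halo = c(57L, 72L),
                            domain_tol = 1L) {
  list(weights = weights, threshold = threshold,
       length_peak = length_peak, length_halo = length_halo,
       domain_tol = domain_tol)
}

#' Score a protein for metallothionein likeness
#'
#' Four components in `[0,1]`: `length` peaks at 1 on 61-68 aa and decays
#' linearly to 0 at the halo bounds; `cys_fraction` is 1 when the cysteine
#' fraction exceeds 0.30 and `fraction/0.30` otherwise; `motif` is the
#' fraction of cysteines participating in at least one CC/CXC/CXXC motif;
#' `domain_layout` is 1 when some split yields 9 beta and 11 alpha cysteines
#' (within `domain_tol` each) and degrades with the closest achievable
#' split's residual deviation.  The total is the weighted mean.
#'
#' @inheritParams count_cys_motifs
#' @param config Parameters from [mt_score_config()].
#' @return An `mt_score`: list with `total`, `components`, `pass`.
#' @export
score_mt_protein <- function(protein, config = mt_score_config()) {
  if (inherits(protein, "mt_seq")) {
    if (protein$moltype != "protein") stop("score_mt_protein expects a protein sequence")
    s <- protein$residues
  } else {
    s <- toupper(protein)
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX*]+$", s)) {
      stop("score_mt_protein expects a protein sequence")
    }
  }
  if (nchar(s) < 20L) stop("protein shorter than 20 aa")
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  cys <- ch == "C"
  total_cys <- sum(cys)

  pk <- config$length_peak; halo <- config$length_halo
  comp_length <- if (n >= pk[1L] && n <= pk[2L]) 1 else if (n < pk[1L]) {
    max(0, (n - halo[1L]) / (pk[1L] - halo[1L]))
  } else {
    max(0, (halo[2L] - n) / (halo[2L] - pk[2L]))
  }

  frac <- total_cys / n
  comp_frac <- if (frac > 0.30) 1 else frac / 0.30

  comp_motif <- if (total_cys == 0L) 0 else sum(.cys_in_motifs(cys)) / total_cys

  tol <- config$domain_tol
  if (total_cys == 0L) {
    comp_domain <- 0
  } else {
    cum <- cumsum(cys)
    splits <- seq_len(max(n - 1L, 1L))
    resid <- pmax(0L, abs(cum[splits] - 9L) - tol) +
      pmax(0L, abs((total_cys - cum[splits]) - 11L) - tol)
    comp_domain <- max(0, 1 - min(resid) / 4)
  }

  comps <- c(length = comp_length, cys_fraction = comp_frac,
             motif = comp_motif, domain_layout = comp_domain)
  w <- config$weights[names(comps)]
  total <- sum(w * comps) / sum(w)
  structure(list(total = total, components = comps,
                 pass = total >= config$threshold),
            class = "mt_score")
}

#' @export
print.mt_score <- function(x, ...) {
  cat(sprintf("<mt_score> total %.3f (%s) [%s]\n", x$total,
              if (x$pass) "pass" else "fail",
              paste(sprintf("%s %.2f", names(x$components), x$components),
                    collapse = ", ")))
  invisible(x)
}

.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) character() else substring(s, seq_len(n - k + 1L), k:n)
}

#' Nominate candidate MT loci by seeded similarity search
#'
#' Exact k-mer seeds between each reference coding sequence (both
#' orientations) and the contig are clustered when closer than `chain_gap`
#' (the default accommodates MT introns), clusters with at least `min_seeds`
#' seeds become windows padded by `flank`, and overlapping windows from
#' different references are merged with the best-supported reference
#' recorded.
#'
#' @param contig An `mt_seq` nucleotide record.
#' @param refs List of `mt_seq` nucleotide reference CDS records.
#' @param k Seed length.
#' @param min_seeds Minimum seeds to keep a cluster.
#' @param chain_gap Maximum gap (bp) between chained seeds.
#' @param flank Window padding (bp).
#' @return Data frame with columns `contig_id`, `start`, `end`, `strand`,
#'   `best_ref_id`, `seed_count`, sorted by descending `seed_count`.
#' @export
find_candidate_loci <- function(contig, refs, k = 11L, min_seeds = 5L,
                                chain_gap = 10000L, flank = 2000L) {
  stopifnot(inherits(contig, "mt_seq"), length(refs) >= 1L)
  if (inherits(refs, "mt_seq")) refs <- list(refs)
  ref_len <- vapply(refs, function(r) nchar(r$residues), 1L)
  if (any(k > ref_len)) {
    stop("seed length k = ", k, " exceeds a reference length (",
         min(ref_len), ")")
  }
  ckmers <- .kmers(contig$residues, k)
  cpos <- seq_along(ckmers)
  windows <- list()
  for (r in refs) {
    for (strand in c("+", "-")) {
      rs <- if (strand == "+") r$residues else revcomp(r$residues)
      hit <- cpos[ckmers %in% unique(.kmers(rs, k))]
      if (length(hit) < min_seeds) next
      grp <- cumsum(c(1L, diff(hit) > chain_gap))
      for (g in split(hit, grp)) {
        if (length(g) < min_seeds) next
        windows[[length(windows) + 1L]] <- data.frame(
          start = max(1L, min(g) - flank),
          end = min(nchar(contig$residues), max(g) + k - 1L + flank),
          strand = strand, best_ref_id = r$id, seed_count = length(g),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(windows)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      best_ref_id = character(), seed_count = integer(),
                      stringsAsFactors = FALSE))
  }
  w <- do.call(rbind, windows)
  w <- w[order(w$start, w$end), , drop = FALSE]
  merged <- w[1L, , drop = FALSE]
  if (nrow(w) > 1L) {
    for (i in 2:nrow(w)) {
      j <- nrow(merged)
      if (w$start[i] <= merged$end[j]) {
        merged$end[j] <- max(merged$end[j], w$end[i])
        if (w$seed_count[i] > merged$seed_count[j]) {
          merged$seed_count[j] <- w$seed_count[i]
          merged$best_ref_id[j] <- w$best_ref_id[i]
          merged$strand[j] <- w$strand[i]
        }
      } else {
        merged <- rbind(merged, w[i, , drop = FALSE])
      }
    }
  }
  merged$contig_id <- contig$id
  merged <- merged[order(-merged$seed_count, merged$start),
                   c("contig_id", "start", "end", "strand",
                     "best_ref_id", "seed_count")]
  rownames(merged) <- NULL
  merged
}
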