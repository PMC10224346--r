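#' Translate a coding sequence with the standard genetic code
#'
#' Translation stops at the first stop codon, which is not included in the
#' returned protein.  A length not divisible by three is tolerated: the
#' trailing 1-2 bases are ignored with a warning.
#'
#' @param cds Nucleotide string, length >= 3.
#' @param warn Emit the partial-codon warning.
#' @return A list with `protein` (string) and `hit_stop` (logical: whether a
#'   stop codon was reached).
#' @export
translate_cds <- function(cds, warn = TRUE) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  if (nchar(cds) %% 3L != 0L && warn) {
    warning("CDS length ", nchar(cds), " is not a codon multiple; trailing ",
            nchar(cds) %% 3L, " base(s) ignored")
  }
  n_codon <- nchar(cds) %/% 3L
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(cds, starts, starts + 2L)
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  aas[is.na(aas)] <- "X"   # codons containing N
  stop_at <- which(aas == "*")
  if (length(stop_at)) {
    list(protein = paste(aas[seq_len(stop_at[1L] - 1L)], collapse = ""),
         hit_stop = TRUE)
  } else {
    list(protein = paste(aas, collapse = ""), hit_stop = FALSE)
  }
}

#' Default parameters for spliced alignment
#'
#' @param match,mismatch,gap Per-column scores (gap is linear).
#' @param intron_penalty Flat penalty for opening one intron.
#' @param min_intron,max_intron Allowed intron lengths (bp); the default
#'   range covers all published cetacean MT introns with wide margins.
#' @param gc_ag_allowed Accept the minor GC..AG donor dialect.
#' @param gc_penalty Extra penalty for a GC donor.
#' @param min_identity Below this alignment identity no model is returned.
#' @return Parameter list.
#' @export
splice_params <- function(match = 2, mismatch = -2, gap = -4,
                          intron_penalty = -10,
                          min_intron = 60L, max_intron = 50000L,
                          gc_ag_allowed = FALSE, gc_penalty = -4,
                          min_identity = 0.8) {
  list(match = match, mismatch = mismatch, gap = gap,
       intron_penalty = intron_penalty, min_intron = min_intron,
       max_intron = max_intron, gc_ag_allowed = gc_ag_allowed,
       gc_penalty = gc_penalty, min_identity = min_identity)
}

#' Spliced alignment of a reference CDS against a genomic window
#'
#' Dynamic-programming alignment in which the reference CDS must be covered
#' end to end while long window-only gaps are scored as introns at a flat
#' penalty, but only when they begin with the spliceosomal donor GT
#' (optionally GC) and end with the acceptor AG.  Both window orientations
#' are tried and the higher-scoring one kept (forward on ties).  Ties within
#' the DP resolve to the alignment with the earliest window coordinate and
#' the fewest introns.
#'
#' @param ref_cds An `mt_seq` nucleotide record holding a complete CDS
#'   (ATG through stop).
#' @param window An `mt_seq` nucleotide record (a candidate locus window).
#' @param params From [splice_params()].
#' @param offset Added to all reported window coordinates, for windows cut
#'   out of a larger contig (`offset = window_start - 1`).
#' @param contig_id Contig name to record; defaults to the window id.
#' @return A `spliced_alignment`: list with `ref_id`, `contig_id`, `strand`,
#'   `blocks` (data frame `ref_start`, `ref_end`, `ctg_start`, `ctg_end`, in
#'   gene order, contig-forward 1-based coordinates), `introns` (data frame
#'   `ctg_start`, `ctg_end`, `donor`, `acceptor`), `identity`, `score`, and
#'   the window itself.
#' @export
spliced_align <- function(ref_cds, window, params = splice_params(),
                          offset = 0L, contig_id = NULL) {
  stopifnot(inherits(ref_cds, "mt_seq"), inherits(window, "mt_seq"),
            ref_cds$moltype == "nucleotide", window$moltype == "nucleotide")
  if (is.null(contig_id)) contig_id <- window$id
  n <- nchar(window$residues)
  run <- function(ws) {
    .splice_align_core(ref_cds$residues, ws,
                       params$match, params$mismatch, params$gap,
                       params$intron_penalty,
                       as.integer(params$min_intron),
                       as.integer(params$max_intron),
                       isTRUE(params$gc_ag_allowed), params$gc_penalty)
  }
  fwd <- run(window$residues)
  rev <- run(revcomp(window$residues))
  strand <- if (rev$score > fwd$score) "-" else "+"
  aln <- if (strand == "+") fwd else rev
  if (aln$identity < params$min_identity || nrow(aln$blocks) == 0L) {
    stop("no spliced model: best identity ",
         sprintf("%.3f", aln$identity), " for ", ref_cds$id,
         " on ", contig_id)
  }
  to_fwd <- function(st, en) {
    if (strand == "+") cbind(st, en) else cbind(n - en + 1L, n - st + 1L)
  }
  b <- aln$blocks
  bc <- to_fwd(b[, 3L], b[, 4L])
  blocks <- data.frame(ref_start = b[, 1L], ref_end = b[, 2L],
                       ctg_start = bc[, 1L] + offset, ctg_end = bc[, 2L] + offset)
  if (nrow(aln$introns) > 0L) {
    ic <- to_fwd(aln$introns[, 1L], aln$introns[, 2L])
    introns <- data.frame(ctg_start = ic[, 1L] + offset, ctg_end = ic[, 2L] + offset,
                          donor = as.character(aln$donors),
                          acceptor = as.character(aln$acceptors))
  } else {
    introns <- data.frame(ctg_start = integer(), ctg_end = integer(),
                          donor = character(), acceptor = character())
  }
  structure(list(ref_id = ref_cds$id, contig_id = contig_id, strand = strand,
                 blocks = blocks, introns = introns,
                 identity = aln$identity, score = aln$score,
                 matches = aln$matches, columns = aln$columns,
                 aligned_ref = aln$aligned_ref,
                 window = window, offset = as.integer(offset),
                 ref_len = nchar(ref_cds$residues)),
            class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("<spliced_alignment %s ~ %s(%s)> %d block(s), %d intron(s), identity %.3f, score %.1f\n",
              x$ref_id, x$contig_id, x$strand, nrow(x$blocks),
              nrow(x$introns), x$identity, x$score))
  invisible(x)
}

#' Turn a spliced alignment into a gene model
#'
#' Exon intervals are the alignment's block window-intervals; the spliced
#' CDS is extracted from the window (reverse-complemented on the minus
#' strand), translated, and flagged.  The reference must be covered to at
#' least `min_ref_coverage`, otherwise the model is rejected as partial.
#'
#' @param aln A `spliced_alignment`.
#' @param gene_id Identifier for the new model.
#' @param isoform,copy_label Labels to carry, see [mt_gene_model()].
#' @param min_ref_coverage Minimum fraction of reference positions inside
#'   aligned blocks.
#' @return An `mt_gene_model`.
#' @export
alignment_to_gene_model <- function(aln, gene_id = paste0(aln$contig_id, "_gene"),
                                    isoform = "unknown",
                                    copy_label = NA_character_,
                                    min_ref_coverage = 0.95) {
  stopifnot(inherits(aln, "spliced_alignment"))
  cov <- aln$aligned_ref / aln$ref_len
  if (cov < min_ref_coverage) {
    stop("partial model: reference coverage ", sprintf("%.2f", cov),
         " below ", min_ref_coverage)
  }
  exons <- data.frame(start = aln$blocks$ctg_start, end = aln$blocks$ctg_end)
  contig_like <- mt_seq(aln$contig_id, aln$window$residues)
  # exon coordinates are contig-based; rebase onto the window for extraction
  local_exons <- data.frame(start = exons$start - aln$offset,
                            end = exons$end - aln$offset)
  m <- build_gene_model(gene_id, contig_like, aln$strand, local_exons,
                        isoform = isoform, copy_label = copy_label)
  m$exons$start <- m$exons$start + aln$offset
  m$exons$end <- m$exons$end + aln$offset
  m
}

#' Validate a gene model against the metallothionein grammar
#'
#' Checks, each reported as a named diagnostic rather than an error: ATG
#' start; TAA/TAG stop (TGA is a warning-level diagnostic that does not fail
#' the model); no internal stop; protein passes [score_mt_protein()]; exon
#' count 1 or 3; and, for three-exon models, exon lengths inside the
#' published envelopes (exon I 28-31 bp, exon II 66 bp with 81 tolerated,
#' exon III 92 or 104-107 bp).
#'
#' @param model An `mt_gene_model` with sequence fields filled.
#' @param score_config Passed to [score_mt_protein()].
#' @return A list with `pass` (logical) and `diagnostics` (character vector
#'   of failed checks; `warnings` holds non-fatal notes such as a TGA stop).
#' @export
validate_gene_model <- function(model, score_config = mt_score_config()) {
  stopifnot(inherits(model, "mt_gene_model"))
  if (is.na(model$cds) || is.na(model$protein)) {
    stop("model has no CDS/protein; derive them with build_gene_model()")
  }
  diag <- character(); warns <- character()
  if (model$start_codon != "ATG") diag <- c(diag, "start codon is not ATG")
  if (model$stop_codon == "TGA") {
    warns <- c(warns, "TGA stop codon (expected TAA/TAG)")
  } else if (!model$stop_codon %in% c("TAA", "TAG")) {
    diag <- c(diag, "no stop codon at CDS end")
  }
  if ("internal_stop" %in% model$flags) diag <- c(diag, "internal stop codon")
  sc <- try(score_mt_protein(model$protein, score_config), silent = TRUE)
  if (inherits(sc, "try-error") || !sc$pass) {
    diag <- c(diag, "protein fails MT-likeness score")
  }
  n_ex <- nrow(model$exons)
  if (!n_ex %in% c(1L, 3L)) diag <- c(diag, "atypical exon count")
  if (n_ex == 3L) {
    len <- abs(model$exons$end - model$exons$start) + 1L
    if (!(len[1L] >= 28L && len[1L] <= 31L)) {
      diag <- c(diag, "exon I length outside envelope")
    }
    if (!len[2L] %in% c(66L, 81L)) diag <- c(diag, "exon II length outside envelope")
    if (!(len[3L] == 92L || (len[3L] >= 104L && len[3L] <= 107L))) {
      diag <- c(diag, "exon III length outside envelope")
    }
  }
  list(pass = length(diag) == 0L, diagnostics = diag, warnings = warns)
}
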