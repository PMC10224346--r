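#' Construct a metallothionein gene model
#'
#' An annotation of one MT gene on a contig: 1-3 exon intervals (1-based
#' inclusive, including the stop codon in the last exon), the spliced CDS,
#' its translation, and validation flags.  Most callers should not build one
#' by hand but obtain it from [alignment_to_gene_model()],
#' [build_gene_model()] or the simulator.
#'
#' @param gene_id,contig_id Identifier strings.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with integer columns `start`, `end`, ordered
#'   5' to 3' along the gene.
#' @param isoform One of `"Mt1"`, `"Mt2"`, `"Mt3"`, `"Mt4"`, `"unknown"`.
#' @param copy_label Optional tandem-copy letter (`"a"`, `"b"`, `"c"`) for
#'   duplicated Mt1 genes; `NA` otherwise.
#' @param cds,protein,start_codon,stop_codon Derived sequence fields; may be
#'   `NA` when the model was read back from coordinates alone.
#' @param flags Character vector drawn from `non_ATG_start`, `TGA_stop`,
#'   `internal_stop`, `exon_count_atypical`.
#' @return An object of class `mt_gene_model`.
#' @export
mt_gene_model <- function(gene_id, contig_id, strand, exons,
                          isoform = "unknown", copy_label = NA_character_,
                          cds = NA_character_, protein = NA_character_,
                          start_codon = NA_character_, stop_codon = NA_character_,
                          flags = character()) {
  stopifnot(strand %in% c("+", "-"),
            isoform %in% c("Mt1", "Mt2", "Mt3", "Mt4", "unknown"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            nrow(exons) >= 1L)
  exons <- data.frame(start = as.integer(exons$start), end = as.integer(exons$end))
  if (any(exons$end < exons$start)) stop("exon with end < start")
  ord <- if (strand == "+") order(exons$start) else order(-exons$start)
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L) {
    fwd <- exons[order(exons$start), ]
    if (any(fwd$start[-1L] <= fwd$end[-nrow(fwd)])) stop("overlapping exons")
  }
  structure(list(gene_id = gene_id, contig_id = contig_id, strand = strand,
                 exons = exons, isoform = isoform, copy_label = copy_label,
                 intron_free = nrow(exons) == 1L,
                 cds = cds, protein = protein,
                 start_codon = start_codon, stop_codon = stop_codon,
                 flags = sort(unique(flags))),
            class = "mt_gene_model")
}

#' @export
print.mt_gene_model <- function(x, ...) {
  cat(sprintf("<mt_gene_model %s> %s on %s(%s), exons [%s]%s%s\n",
              x$gene_id,
              if (is.na(x$copy_label)) x$isoform else paste0(x$isoform, x$copy_label),
              x$contig_id, x$strand,
              paste(sprintf("%d-%d", x$exons$start, x$exons$end), collapse = ", "),
              if (x$intron_free) ", intron-free" else "",
              if (length(x$flags)) paste0(", flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Genomic span of a gene model (ATG through stop codon, inclusive)
#' @param model An `mt_gene_model`.
#' @return Integer vector `c(start, end)` in contig coordinates.
#' @export
gene_span <- function(model) {
  c(min(model$exons$start), max(model$exons$end))
}

#' Derive the sequence fields of a gene model from its contig
#'
#' Given exon coordinates on a contig, extracts and splices the CDS
#' (reverse-complementing on the minus strand), translates it, and sets
#' validation flags (`non_ATG_start`, `TGA_stop`, `internal_stop`,
#' `exon_count_atypical`).
#'
#' @inheritParams mt_gene_model
#' @param contig An `mt_seq` nucleotide record the exons lie on.
#' @return An `mt_gene_model` with `cds`, `protein` and codon fields filled.
#' @export
build_gene_model <- function(gene_id, contig, strand, exons,
                             isoform = "unknown", copy_label = NA_character_) {
  stopifnot(inherits(contig, "mt_seq"), contig$moltype == "nucleotide")
  L <- nchar(contig$residues)
  if (any(exons$start < 1L) || any(exons$end > L)) {
    stop("exon interval outside contig '", contig$id, "'")
  }
  fwd <- exons[order(exons$start), , drop = FALSE]
  pieces <- substring(contig$residues, fwd$start, fwd$end)
  cds <- paste(pieces, collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  start_codon <- substr(cds, 1L, 3L)
  stop_codon <- substr(cds, nchar(cds) - 2L, nchar(cds))
  tr <- translate_cds(cds, warn = FALSE)
  flags <- character()
  if (start_codon != "ATG") flags <- c(flags, "non_ATG_start")
  if (stop_codon == "TGA") flags <- c(flags, "TGA_stop")
  n_codon <- nchar(cds) %/% 3L
  # translation stops at the first stop codon; a stop before the final codon
  # (or none at all) marks a broken reading frame
  if (nchar(tr$protein) < n_codon - 1L || !tr$hit_stop || nchar(cds) %% 3L != 0L) {
    flags <- c(flags, "internal_stop")
  }
  if (!nrow(exons) %in% c(1L, 3L)) flags <- c(flags, "exon_count_atypical")
  mt_gene_model(gene_id, contig$id, strand, exons,
                isoform = isoform, copy_label = copy_label,
                cds = cds, protein = tr$protein,
                start_codon = start_codon, stop_codon = stop_codon,
                flags = flags)
}
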