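#' Write gene models to GFF3
#'
#' Emits one `gene` feature, one `mRNA` child and one `exon` child per exon
#' for every model, with the isoform label (and copy letter, flags) carried
#' in the attributes column.  Coordinates are 1-based inclusive as GFF3
#' requires.  Round-trips through [read_gff3_models()].
#'
#' @param models A list of `mt_gene_model` objects (or a single one).
#' @param path Output path.
#' @param contig_lengths Optional named integer vector of contig lengths; if
#'   given, exon intervals outside the contig raise an error.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(models, path, contig_lengths = NULL) {
  if (inherits(models, "mt_gene_model")) models <- list(models)
  stopifnot(length(models) >= 1L)
  rows <- lapply(models, function(m) {
    span <- gene_span(m)
    if (!is.null(contig_lengths)) {
      L <- contig_lengths[[m$contig_id]]
      if (is.null(L) || is.na(L)) stop("no length given for contig ", m$contig_id)
      if (span[1L] < 1L || span[2L] > L) {
        stop("gene ", m$gene_id, " outside contig ", m$contig_id, " bounds")
      }
    }
    fwd <- m$exons[order(m$exons$start), , drop = FALSE]
    gid <- m$gene_id
    mid <- paste0(gid, ".t1")
    data.frame(
      seqnames = m$contig_id,
      start = c(span[1L], span[1L], fwd$start),
      end = c(span[2L], span[2L], fwd$end),
      strand = m$strand,
      type = c("gene", "mRNA", rep("exon", nrow(fwd))),
      ID = c(gid, mid, paste0(mid, ".exon", seq_len(nrow(fwd)))),
      Parent = c(NA_character_, gid, rep(mid, nrow(fwd))),
      isoform = m$isoform,
      copy_label = if (is.na(m$copy_label)) NA_character_ else m$copy_label,
      flags = if (length(m$flags)) paste(m$flags, collapse = ",") else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$isoform <- df$isoform
  S4Vectors::mcols(gr)$copy_label <- df$copy_label
  S4Vectors::mcols(gr)$flags <- df$flags
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models back from a GFF3 file
#'
#' Reconstructs `mt_gene_model` objects written by [write_gff3()].  Sequence
#' fields (CDS, protein, codons, flags) are re-derived when the matching
#' contigs are supplied; otherwise only the coordinate and label fields are
#' filled.
#'
#' @param path A GFF3 file.
#' @param contigs Optional list of `mt_seq` nucleotide records covering the
#'   contigs named in the file.
#' @return A list of `mt_gene_model` objects in file order.
#' @export
read_gff3_models <- function(path, contigs = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  is_gene <- mc$type == "gene"
  if (!any(is_gene)) stop("no gene features in ", path)
  contig_by_id <- NULL
  if (!is.null(contigs)) {
    if (inherits(contigs, "mt_seq")) contigs <- list(contigs)
    contig_by_id <- setNames(contigs, vapply(contigs, `[[`, "", "id"))
  }
  unlist_chr <- function(x) {
    if (is.null(x)) NA_character_ else {
      v <- as.character(unlist(x))
      if (length(v)) v[1L] else NA_character_
    }
  }
  models <- lapply(which(is_gene), function(i) {
    gid <- unlist_chr(mc$ID[i])
    mrna <- which(mc$type == "mRNA" &
                    vapply(mc$Parent, function(p) gid %in% as.character(p), TRUE))
    if (length(mrna) != 1L) stop("gene ", gid, " without a single mRNA child")
    mid <- unlist_chr(mc$ID[mrna])
    ex <- which(mc$type == "exon" &
                  vapply(mc$Parent, function(p) mid %in% as.character(p), TRUE))
    if (!length(ex)) stop("mRNA ", mid, " has no exons")
    exons <- data.frame(start = BiocGenerics::start(gr)[ex],
                        end = BiocGenerics::end(gr)[ex])
    strand <- as.character(BiocGenerics::strand(gr)[i])
    if (!strand %in% c("+", "-")) strand <- "+"
    contig_id <- as.character(GenomicRanges::seqnames(gr)[i])
    iso <- unlist_chr(mc$isoform[i])
    if (is.na(iso)) iso <- "unknown"
    copy <- unlist_chr(mc$copy_label[i])
    if (!is.null(contig_by_id) && contig_id %in% names(contig_by_id)) {
      build_gene_model(gid, contig_by_id[[contig_id]], strand, exons,
                       isoform = iso, copy_label = copy)
    } else {
      flags <- unlist_chr(mc$flags[i])
      flags <- if (is.na(flags)) character() else strsplit(flags, ",")[[1L]]
      mt_gene_model(gid, contig_id, strand, exons, isoform = iso,
                    copy_label = copy, flags = flags)
    }
  })
  models
}
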