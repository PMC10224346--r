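#' Pipeline configuration
#'
#' @param contigs List of `mt_seq` nucleotide records to mine, or a FASTA
#'   path.
#' @param refs Reference CDS records (list of `mt_seq` or FASTA path);
#'   defaults to the synthetic exemplar set from [mt_reference_set()].
#' @param out_dir Optional output directory for GFF3/TSV/Newick reports.
#' @param seed Seed for the bootstrap resampling.
#' @param k,min_seeds,chain_gap,flank Seeded-search parameters, see
#'   [find_candidate_loci()].
#' @param splice Spliced-alignment parameters from [splice_params()].  The
#'   pipeline default caps intron length at 2000 bp: comfortably above the
#'   published cetacean MT intron envelope (173-1671 bp) yet below the
#'   smallest published intergenic region (2064 bp), so a jump across an IGR
#'   can never be scored as an intron.
#' @param score MT-likeness scoring parameters from [mt_score_config()].
#' @param bootstrap_replicates Replicates for branch support (0 disables).
#' @param max_genes_per_window Cap on masked re-alignments per reference and
#'   window.
#' @return A `run_config` list.
#' @export
run_config <- function(contigs, refs = mt_reference_set(), out_dir = NULL,
                       seed = 1L, k = 11L, min_seeds = 5L,
                       chain_gap = 10000L, flank = 2000L,
                       splice = splice_params(max_intron = 2000L),
                       score = mt_score_config(),
                       bootstrap_replicates = 100L,
                       max_genes_per_window = 4L) {
  if (is.character(contigs)) contigs <- read_fasta(contigs)
  if (is.character(refs)) refs <- read_fasta(refs)
  if (inherits(contigs, "mt_seq")) contigs <- list(contigs)
  if (inherits(refs, "mt_seq")) refs <- list(refs)
  structure(list(contigs = contigs, refs = refs, out_dir = out_dir,
                 seed = as.integer(seed), k = k, min_seeds = min_seeds,
                 chain_gap = chain_gap, flank = flank, splice = splice,
                 score = score, bootstrap_replicates = bootstrap_replicates,
                 max_genes_per_window = max_genes_per_window),
            class = "run_config")
}

# mine one candidate window with one reference, masking each recovered gene
# and re-aligning until no further spliced model is found
.mine_window <- function(contig, win_start, win_end, ref, cfg) {
  found <- list()
  win_seq <- substring(contig$residues, win_start, win_end)
  for (it in seq_len(cfg$max_genes_per_window)) {
    win <- try(mt_seq(paste0(contig$id, "_w"), win_seq), silent = TRUE)
    if (inherits(win, "try-error")) break
    aln <- try(suppressWarnings(
      spliced_align(ref, win, cfg$splice, offset = win_start - 1L,
                    contig_id = contig$id)), silent = TRUE)
    if (inherits(aln, "try-error")) break
    model <- try(alignment_to_gene_model(aln), silent = TRUE)
    if (inherits(model, "try-error")) break
    # re-derive sequence fields from the true contig
    model <- build_gene_model(model$gene_id, contig, model$strand, model$exons)
    found[[length(found) + 1L]] <- list(model = model, ref_id = ref$id,
                                        identity = aln$identity,
                                        score = aln$score)
    span <- gene_span(model) - (win_start - 1L)
    span[1L] <- max(1L, span[1L]); span[2L] <- min(nchar(win_seq), span[2L])
    substr(win_seq, span[1L], span[2L]) <- paste(
      rep("N", span[2L] - span[1L] + 1L), collapse = "")
  }
  found
}

# greedy resolution of overlapping candidate models: best identity first
.dedup_models <- function(cands) {
  if (!length(cands)) return(cands)
  ord <- order(-vapply(cands, `[[`, 0.0, "identity"),
               -vapply(cands, `[[`, 0.0, "score"))
  cands <- cands[ord]
  kept <- list()
  for (cd in cands) {
    sp <- gene_span(cd$model)
    clash <- any(vapply(kept, function(k2) {
      sp2 <- gene_span(k2$model)
      sp[1L] <= sp2[2L] && sp2[1L] <= sp[2L]
    }, TRUE))
    if (!clash) kept[[length(kept) + 1L]] <- cd
  }
  kept
}

#' Run the full mining pipeline
#'
#' Per contig: seeded candidate search, spliced alignment of every reference
#' against every window (with masking, so tandem copies are all found),
#' overlap resolution, grammar validation, isoform classification, cluster
#' ordering and IGR computation.  Across contigs: a K2P distance matrix and
#' NJ tree with bootstrap support over all validated coding sequences.
#' Writes GFF3/TSV/Newick reports when `out_dir` is set; reruns with the
#' same config are byte-identical.
#'
#' @param cfg A [run_config()].
#' @return An `mt_run_report` list: `loci`, `genes` (data frame), `models`,
#'   `clusters`, `igrs`, `tree`, `support`, `n_validated`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!length(cfg$contigs)) stop("empty input: no contigs")
  loci_all <- list(); clusters <- list(); models_all <- list()
  gene_rows <- list()
  for (contig in cfg$contigs) {
    loci <- find_candidate_loci(contig, cfg$refs, k = cfg$k,
                                min_seeds = cfg$min_seeds,
                                chain_gap = cfg$chain_gap, flank = cfg$flank)
    loci_all[[length(loci_all) + 1L]] <- loci
    cands <- list()
    if (nrow(loci)) {
      for (w in seq_len(nrow(loci))) {
        for (ref in cfg$refs) {
          cands <- c(cands, .mine_window(contig, loci$start[w], loci$end[w],
                                         ref, cfg))
        }
      }
    }
    kept <- .dedup_models(cands)
    if (!length(kept)) next
    starts <- vapply(kept, function(k2) gene_span(k2$model)[1L], 1L)
    kept <- kept[order(starts)]
    contig_models <- list()
    for (i in seq_along(kept)) {
      m <- kept[[i]]$model
      m$gene_id <- sprintf("%s_g%d", contig$id, i)
      val <- validate_gene_model(m, cfg$score)
      call <- classify_isoform(m, cfg$refs)
      m$isoform <- call$isoform
      contig_models[[i]] <- m
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = m$gene_id, contig_id = m$contig_id,
        start = gene_span(m)[1L], end = gene_span(m)[2L],
        strand = m$strand, n_exons = nrow(m$exons),
        exon_lengths = paste(abs(m$exons$end - m$exons$start) + 1L,
                             collapse = ","),
        isoform = call$isoform, confidence = call$confidence,
        valid = val$pass,
        diagnostics = paste(val$diagnostics, collapse = "; "),
        best_ref = kept[[i]]$ref_id, identity = kept[[i]]$identity,
        stringsAsFactors = FALSE)
    }
    valid_models <- Filter(function(m) {
      validate_gene_model(m, cfg$score)$pass
    }, contig_models)
    # relabel Mt1 copies and compute IGRs on validated full models
    if (length(valid_models)) {
      clusters[[contig$id]] <- order_genes(valid_models)
    }
    models_all <- c(models_all, contig_models)
  }
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               n_exons = integer(), exon_lengths = character(),
               isoform = character(), confidence = character(),
               valid = logical(), diagnostics = character(),
               best_ref = character(), identity = numeric(),
               stringsAsFactors = FALSE)
  igrs <- do.call(rbind, c(lapply(names(clusters), function(cid) {
    df <- clusters[[cid]]$igrs
    if (nrow(df)) cbind(contig_id = cid, df) else NULL
  }), list(make.row.names = FALSE)))
  if (is.null(igrs)) igrs <- data.frame(contig_id = character(),
                                        upstream = character(),
                                        downstream = character(),
                                        upstream_label = character(),
                                        downstream_label = character(),
                                        length = integer())
  valid_all <- Filter(function(m) !is.na(m$cds), models_all)
  valid_all <- valid_all[vapply(valid_all, function(m) {
    validate_gene_model(m, cfg$score)$pass
  }, TRUE)]
  tree <- NULL; support <- NULL
  if (length(valid_all) >= 3L) {
    lens <- vapply(valid_all, function(m) nchar(m$cds), 1L)
    seqs <- setNames(substr(vapply(valid_all, `[[`, "", "cds"), 1L, min(lens)),
                     vapply(valid_all, `[[`, "", "gene_id"))
    tr <- try(suppressWarnings({
      if (cfg$bootstrap_replicates > 0L) {
        bootstrap_support(seqs, cfg$bootstrap_replicates, cfg$seed)
      } else {
        list(tree = nj_tree(k2p_matrix(seqs)), support = NULL)
      }
    }), silent = TRUE)
    if (!inherits(tr, "try-error")) { tree <- tr$tree; support <- tr$support }
  }
  report <- structure(list(loci = do.call(rbind, loci_all), genes = genes,
                           models = models_all, clusters = clusters,
                           igrs = igrs, tree = tree, support = support,
                           n_validated = length(valid_all),
                           seed = cfg$seed),
                      class = "mt_run_report")
  if (!is.null(cfg$out_dir)) .write_report(report, cfg)
  report
}

#' @export
print.mt_run_report <- function(x, ...) {
  cat(sprintf("<mt_run_report> %d gene model(s) (%d validated) on %d cluster(s)\n",
              nrow(x$genes), x$n_validated, length(x$clusters)))
  for (cl in x$clusters) cat("  ", cl$contig_id, ": ", cl$architecture_string, "\n", sep = "")
  invisible(x)
}

.report_header <- function(seed) {
  ver <- as.character(utils::packageVersion("cetamt"))
  sprintf("# cetamt %s | seed %d", ver, seed)
}

.write_report <- function(report, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .report_header(cfg$seed)
  valid <- Filter(function(m) validate_gene_model(m, cfg$score)$pass,
                  report$models)
  if (length(valid)) {
    write_gff3(valid, file.path(cfg$out_dir, "genes.gff3"))
  }
  gf <- file.path(cfg$out_dir, "genes.tsv")
  writeLines(hdr, gf)
  suppressWarnings(write.table(report$genes, gf, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  igf <- file.path(cfg$out_dir, "igrs.tsv")
  writeLines(hdr, igf)
  suppressWarnings(write.table(report$igrs, igf, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  if (!is.null(report$tree)) {
    tf <- file.path(cfg$out_dir, "tree.nwk")
    writeLines(c(hdr, ape::write.tree(report$tree)), tf)
  }
  invisible(NULL)
}

#' Summarize a run (or a packaged fixture) as a published-style IGR table
#'
#' One row per contig with the IGR length for each adjacent gene pair,
#' followed by recomputed `Average ± SD` and `Min–Max` footer rows.  In
#' fixture mode (`report = NULL`), summarizes the packaged per-species IGR
#' transcription instead, reproducing the published summary rows.
#'
#' @param report An `mt_run_report`, or `NULL` for fixture mode.
#' @return A data frame; the last two rows are the summary footers.
#' @export
summarize_run <- function(report = NULL) {
  canon <- c("Mt4-Mt3", "Mt3-Mt2", "Mt2-Mt1a", "Mt2-Mt1", "Mt1a-Mt1b", "Mt1b-Mt1c")
  if (is.null(report)) {
    tab <- load_fixture_table("igr_lengths")
    rows <- tab$data["species"]
    cols <- setdiff(names(tab$data), "species")
    cells_by_col <- tab$cells
    values <- tab$data[cols]
  } else {
    ig <- report$igrs
    if (!nrow(ig)) {
      return(data.frame(species = character()))
    }
    ig$pair <- paste(ig$upstream_label, ig$downstream_label, sep = "-")
    cols <- intersect(canon, unique(ig$pair))
    cols <- c(cols, setdiff(unique(ig$pair), canon))
    species <- unique(ig$contig_id)
    values <- as.data.frame(matrix("", length(species), length(cols)),
                            stringsAsFactors = FALSE)
    names(values) <- cols
    for (r in seq_len(nrow(ig))) {
      values[match(ig$contig_id[r], species), ig$pair[r]] <-
        as.character(ig$length[r])
    }
    rows <- data.frame(species = species, stringsAsFactors = FALSE)
    cells_by_col <- lapply(values, function(col) lapply(col, parse_length_cell))
  }
  footer_avg <- vapply(cols, function(cn) {
    st <- try(summarize_lengths(cells_by_col[[cn]]), silent = TRUE)
    if (inherits(st, "try-error")) "" else
      sprintf("%.2f ± %s", st$mean,
              if (is.na(st$sd)) "NA" else sprintf("%.2f", st$sd))
  }, "")
  footer_mm <- vapply(cols, function(cn) {
    st <- try(summarize_lengths(cells_by_col[[cn]]), silent = TRUE)
    if (inherits(st, "try-error")) "" else sprintf("%g–%g", st$min, st$max)
  }, "")
  out <- cbind(rows, values, stringsAsFactors = FALSE)
  footer <- function(label, vals) {
    row <- c(list(label), as.list(unname(vals)))
    names(row) <- names(out)
    as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- rbind(out, footer("Average ± SD (bp)", footer_avg),
               footer("Min–Max (bp)", footer_mm))
  rownames(out) <- NULL
  out
}
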