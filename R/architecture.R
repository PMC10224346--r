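#' Order gene models along a contig into a cluster architecture
#'
#' Genes are sorted by start coordinate.  Tandem Mt1 copies are labeled
#' `a`, `b`, `c` running outward from the copy nearest Mt2 (the cluster's
#' fixed partner), falling back to coordinate order when no Mt2 model is
#' present; a single Mt1 keeps no copy suffix.  Mixed-orientation clusters
#' are kept but flagged with a warning, since published cetacean MT clusters
#' are co-oriented.
#'
#' @param models List of `mt_gene_model` objects on one contig.
#' @return An `mt_cluster`: list with `contig_id`, `genes` (ordered list),
#'   `igrs` (data frame from [compute_igrs()]) and `architecture_string`.
#' @export
order_genes <- function(models) {
  if (inherits(models, "mt_gene_model")) models <- list(models)
  stopifnot(length(models) >= 1L)
  contigs <- unique(vapply(models, `[[`, "", "contig_id"))
  if (length(contigs) != 1L) stop("models span multiple contigs: ",
                                  paste(contigs, collapse = ", "))
  spans <- t(vapply(models, gene_span, integer(2)))
  ord <- order(spans[, 1L], spans[, 2L])
  models <- models[ord]; spans <- spans[ord, , drop = FALSE]
  if (nrow(spans) > 1L &&
      any(spans[-1L, 1L] <= spans[-nrow(spans), 2L])) {
    stop("inconsistent models: overlapping gene spans on ", contigs)
  }
  if (length(unique(vapply(models, `[[`, "", "strand"))) > 1L) {
    warning("mixed gene orientations in cluster on ", contigs)
  }
  iso <- vapply(models, `[[`, "", "isoform")
  mt1 <- which(iso == "Mt1")
  if (length(mt1) == 1L) {
    models[[mt1]]$copy_label <- NA_character_
  } else if (length(mt1) > 1L) {
    mt2 <- which(iso == "Mt2")
    if (length(mt2)) {
      anchor <- mean(spans[mt2, 1L])
      prox <- order(abs(spans[mt1, 1L] - anchor))
    } else {
      prox <- seq_along(mt1)
    }
    for (i in seq_along(prox)) {
      models[[mt1[prox[i]]]]$copy_label <- letters[i]
    }
  }
  labels <- vapply(models, function(m) {
    if (is.na(m$copy_label)) m$isoform else paste0(m$isoform, m$copy_label)
  }, "")
  arch <- structure(list(contig_id = contigs, genes = models, igrs = NULL,
                         architecture_string = paste(labels, collapse = "-")),
                    class = "mt_cluster")
  arch$igrs <- compute_igrs(arch)
  arch
}

#' @export
print.mt_cluster <- function(x, ...) {
  cat(sprintf("<mt_cluster %s> %s (%d genes)\n", x$contig_id,
              x$architecture_string, length(x$genes)))
  if (nrow(x$igrs)) {
    cat(paste(sprintf("  IGR %s-%s: %d bp", x$igrs$upstream_label,
                      x$igrs$downstream_label, x$igrs$length), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Intergenic region lengths of a cluster
#'
#' The IGR between two consecutive genes counts the bases strictly between
#' their spans, each span running from the ATG through the stop codon
#' inclusive; adjacent genes with no gap give an IGR of 0.  Computed on
#' genomic coordinates irrespective of strand.
#'
#' @param arch An `mt_cluster` from [order_genes()], or a list of ordered,
#'   non-overlapping `mt_gene_model`s.
#' @return Data frame with columns `upstream`, `downstream` (gene ids),
#'   `upstream_label`, `downstream_label` (isoform+copy) and `length` (bp).
#' @export
compute_igrs <- function(arch) {
  genes <- if (inherits(arch, "mt_cluster")) arch$genes else arch
  n <- length(genes)
  lab <- function(m) if (is.na(m$copy_label)) m$isoform else paste0(m$isoform, m$copy_label)
  if (n < 2L) {
    return(data.frame(upstream = character(), downstream = character(),
                      upstream_label = character(), downstream_label = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  spans <- t(vapply(genes, gene_span, integer(2)))
  if (any(spans[-1L, 1L] <= spans[-n, 2L])) stop("inconsistent models: overlap")
  data.frame(
    upstream = vapply(genes[-n], `[[`, "", "gene_id"),
    downstream = vapply(genes[-1L], `[[`, "", "gene_id"),
    upstream_label = vapply(genes[-n], lab, ""),
    downstream_label = vapply(genes[-1L], lab, ""),
    length = spans[-1L, 1L] - spans[-n, 2L] - 1L,
    stringsAsFactors = FALSE)
}

.resolve_cells <- function(cells, range_policy = c("low", "high", "midpoint", "exclude"),
                           copy = "a") {
  range_policy <- match.arg(range_policy)
  vals <- vapply(cells, function(cl) {
    stopifnot(inherits(cl, "length_cell"))
    if (!is.null(cl$multi)) {
      # unlabeled single values count as copy "a"; labeled cells contribute
      # the requested copy or nothing
      v <- cl$multi[copy]
      return(if (is.na(v)) NA_real_ else as.numeric(v))
    }
    if (!is.null(cl$range_high)) {
      return(switch(range_policy,
                    low = as.numeric(cl$value),
                    high = as.numeric(cl$range_high),
                    midpoint = (cl$value + cl$range_high) / 2,
                    exclude = NA_real_))
    }
    if (is.na(cl$value)) NA_real_ else as.numeric(cl$value)
  }, 0.0)
  vals[!is.na(vals)]
}

#' Summarize a column of length cells
#'
#' Reproduces the published tables' summary rows: arithmetic mean, sample
#' (n-1) standard deviation, minimum and maximum over the resolved values.
#' Missing cells are skipped, approximate cells are used numerically, range
#' cells resolve per `range_policy`, and per-copy cells contribute the
#' requested tandem copy (unlabeled values count as copy "a").
#'
#' @param cells List of `length_cell` objects (one fixture-table column).
#' @param range_policy `"low"` (default), `"high"`, `"midpoint"` or
#'   `"exclude"`.
#' @param copy Tandem-copy letter for per-copy cells.
#' @return A `summary_stats`: list with `n`, `mean`, `sd` (NA when n < 2),
#'   `min`, `max`.
#' @export
summarize_lengths <- function(cells, range_policy = "low", copy = "a") {
  vals <- .resolve_cells(cells, range_policy, copy)
  if (!length(vals)) stop("all cells missing")
  structure(list(n = length(vals), mean = mean(vals),
                 sd = if (length(vals) >= 2L) sd(vals) else NA_real_,
                 min = min(vals), max = max(vals)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> n=%d  %.2f ± %s  (min %g, max %g)\n",
              x$n, x$mean, if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd),
              x$min, x$max))
  invisible(x)
}

.modal_value <- function(vals) {
  if (!length(vals)) return(NA_real_)
  tab <- table(vals)
  as.numeric(names(tab)[which.max(tab)])
}

#' Summary statistics for the packaged exon and intron tables
#'
#' For each of the 12 exon columns and 8 intron columns of the packaged
#' fixtures, computes [summarize_lengths()] plus the modal value.  Per-copy
#' Mt1 intron cells contribute the configured copy (default `"a"`, matching
#' the per-copy sub-columns of the published summary row).
#'
#' @param copy Tandem-copy letter for per-copy intron cells.
#' @param range_policy Passed to [summarize_lengths()].
#' @return Data frame with one row per (table, column): `table`, `column`,
#'   `n`, `mean`, `sd`, `min`, `max`, `mode`.
#' @export
summarize_exon_intron_tables <- function(copy = "a", range_policy = "low") {
  rows <- list()
  for (tab_name in c("exon_lengths", "intron_lengths")) {
    tab <- load_fixture_table(tab_name)
    for (col in names(tab$cells)) {
      vals <- .resolve_cells(tab$cells[[col]], range_policy, copy)
      if (!length(vals)) next
      st <- summarize_lengths(tab$cells[[col]], range_policy, copy)
      rows[[length(rows) + 1L]] <- data.frame(
        table = tab_name, column = col, n = st$n, mean = st$mean,
        sd = st$sd, min = st$min, max = st$max, mode = .modal_value(vals),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
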