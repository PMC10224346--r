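#' Classify a gene model into one of the four MT isoforms
#'
#' Combines up to three lines of evidence: (i) a third-exon length of
#' 104-107 bp is the Mt3 signature (other isoforms share 92 bp); (ii) the
#' nearest reference CDS by K2P distance after pairwise alignment; (iii)
#' optionally, the smallest NJ clade containing the model — if all
#' references inside it share one isoform, that isoform gets a vote.  The
#' majority of available votes wins; a tie or no usable evidence yields
#' `unknown`.  Intron-free models carry no exon-length evidence and are
#' classified by distance (and clade) only.
#'
#' @param model A validated `mt_gene_model` with its CDS filled.
#' @param refs List of labeled reference CDS `mt_seq` records (at least one
#'   per isoform for meaningful calls).
#' @param ref_isoforms Character vector of isoform labels, one per
#'   reference; defaults to the leading `Mt[1-4]` token of each ref id.
#' @param use_tree Include the NJ clade evidence (needs >= 3 references).
#' @return An `isoform_call`: list with `gene_id`, `isoform`, `evidence`
#'   (named list), `confidence` (`high`, `medium`, `low`).
#' @export
classify_isoform <- function(model, refs, ref_isoforms = NULL, use_tree = TRUE) {
  stopifnot(inherits(model, "mt_gene_model"), length(refs) >= 1L)
  if (inherits(refs, "mt_seq")) refs <- list(refs)
  ids <- vapply(refs, `[[`, "", "id")
  if (is.null(ref_isoforms)) {
    ref_isoforms <- sub("^(Mt[1-4]).*$", "\\1", ids)
  }
  if (!all(ref_isoforms %in% c("Mt1", "Mt2", "Mt3", "Mt4"))) {
    stop("reference isoforms must be Mt1-Mt4 (pass ref_isoforms explicitly)")
  }
  call_unknown <- function(evidence) {
    structure(list(gene_id = model$gene_id, isoform = "unknown",
                   evidence = evidence, confidence = "low"),
              class = "isoform_call")
  }
  evidence <- list()
  votes <- character()

  if (!model$intron_free && nrow(model$exons) == 3L) {
    e3 <- abs(model$exons$end[3L] - model$exons$start[3L]) + 1L
    evidence$exon3_length <- e3
    if (e3 >= 104L && e3 <= 107L) votes <- c(votes, "Mt3")
  }

  dists <- vapply(seq_along(refs), function(i) {
    out <- try({
      ap <- align_cds_pair(model$cds, refs[[i]]$residues)
      pairwise_k2p(ap[["a"]], ap[["b"]])
    }, silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  }, 0.0)
  if (all(is.na(dists))) return(call_unknown(evidence))
  grp <- tapply(dists, ref_isoforms, min, na.rm = TRUE)
  grp <- grp[is.finite(grp)]
  best <- sort(grp)
  evidence$nearest_reference <- names(best)[1L]
  evidence$nearest_distance <- unname(best[1L])
  if (length(best) == 1L || best[2L] - best[1L] > 1e-9) {
    votes <- c(votes, names(best)[1L])
  }

  if (use_tree && length(refs) >= 3L) {
    seqs <- c(list(mt_seq("query__", model$cds)), refs)
    # put everything on common coordinates against the first reference
    base <- seqs[[2L]]
    aligned <- vapply(seqs, function(s) {
      if (nchar(s$residues) == nchar(base$residues)) s$residues
      else {
        ap <- align_cds_pair(base$residues, s$residues)
        # keep only columns where the base has no gap, for a shared frame
        keep <- strsplit(ap[["a"]], "")[[1L]] != "-"
        paste(strsplit(ap[["b"]], "")[[1L]][keep], collapse = "")
      }
    }, "")
    names(aligned) <- c("query__", ids)
    tr <- try(suppressWarnings(nj_tree(k2p_matrix(aligned))), silent = TRUE)
    if (!inherits(tr, "try-error")) {
      clade_iso <- .smallest_clade_isoform(tr, "query__", ids, ref_isoforms)
      if (!is.na(clade_iso)) {
        evidence$clade <- clade_iso
        votes <- c(votes, clade_iso)
      }
    }
  }

  if (!length(votes)) return(call_unknown(evidence))
  tab <- sort(table(votes), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) return(call_unknown(evidence))
  isoform <- names(tab)[1L]
  conf <- if (tab[1L] >= 2L) "high" else "medium"
  structure(list(gene_id = model$gene_id, isoform = isoform,
                 evidence = evidence, confidence = conf),
            class = "isoform_call")
}

# isoform shared by all references in the smallest clade containing `query`,
# or NA when the clade is mixed / the tree is uninformative
.smallest_clade_isoform <- function(tree, query, ref_ids, ref_isoforms) {
  tips <- tree$tip.label
  if (!query %in% tips) return(NA_character_)
  parts <- ape::prop.part(tree)
  iso_of <- setNames(ref_isoforms, ref_ids)
  sides <- list()
  for (p in parts) {
    set <- tips[p]
    sides <- c(sides, list(set), list(setdiff(tips, set)))
  }
  sizes <- lengths(sides)
  keep <- vapply(sides, function(s) {
    query %in% s && length(intersect(s, ref_ids)) >= 1L
  }, TRUE) & sizes < length(tips)
  if (!any(keep)) return(NA_character_)
  sides <- sides[keep]
  side <- sides[[order(lengths(sides))[1L]]]
  isos <- unique(iso_of[intersect(side, ref_ids)])
  if (length(isos) == 1L) isos else NA_character_
}

#' @export
print.isoform_call <- function(x, ...) {
  cat(sprintf("<isoform_call %s> %s (%s)\n", x$gene_id, x$isoform, x$confidence))
  invisible(x)
}
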