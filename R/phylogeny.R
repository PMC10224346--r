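# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.seq_chars <- function(x) {
  s <- if (inherits(x, "mt_seq")) x$residues else toupper(x)
  strsplit(s, "")[[1L]]
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' With P the proportion of transitions (A<->G, C<->T) and Q the proportion
#' of transversions over the included sites,
#' `d = -(1/2) ln((1 - 2P - Q) sqrt(1 - 2Q))`.  Sites carrying `N` or a gap
#' in either sequence are excluded pairwise.
#'
#' @param a,b Equal-length aligned nucleotide strings or `mt_seq` records
#'   (gaps as `-`).
#' @return The K2P distance (non-negative scalar).
#' @export
pairwise_k2p <- function(a, b) {
  ca <- .seq_chars(a); cb <- .seq_chars(b)
  if (length(ca) != length(cb)) stop("sequences must be aligned to equal length")
  ida <- if (inherits(a, "mt_seq")) a$id else "a"
  idb <- if (inherits(b, "mt_seq")) b$id else "b"
  .k2p_chars(ca, cb, ida, idb)
}

.k2p_chars <- function(ca, cb, ida = "a", idb = "b") {
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable sites")
  diff <- ca != cb
  purine <- c("A", "G")
  transition <- diff & ((ca %in% purine) == (cb %in% purine))
  P <- sum(transition) / length(ca)
  Q <- sum(diff & !transition) / length(ca)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("saturated pair: ", ida, " vs ", idb,
         " (P = ", sprintf("%.3f", P), ", Q = ", sprintf("%.3f", Q), ")")
  }
  max(0, -0.5 * log(w1 * sqrt(w2)))
}

.k2p_matrix_chars <- function(chars) {
  labels <- rownames(chars)
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- .k2p_chars(chars[i, ], chars[j, ],
                                       labels[i], labels[j])
    }
  }
  d
}

#' K2P distance matrix for a set of aligned sequences
#'
#' @param seqs Named character vector of equal-length aligned sequences, or
#'   a list of `mt_seq` records.
#' @return A symmetric labeled numeric matrix with zero diagonal.
#' @export
k2p_matrix <- function(seqs) {
  if (is.list(seqs)) {
    labels <- vapply(seqs, `[[`, "", "id")
    seqs <- setNames(vapply(seqs, `[[`, "", "residues"), labels)
  }
  labels <- names(seqs)
  if (is.null(labels) || any(!nzchar(labels))) stop("sequences must be named")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must be aligned to equal length")
  }
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(chars) <- labels
  .k2p_matrix_chars(chars)
}

#' Global pairwise alignment of two coding sequences
#'
#' Needleman-Wunsch with affine gaps (match +1, mismatch -1, gap open 5,
#' gap extend 1) via [Biostrings::pairwiseAlignment()]; used to put two
#' equal-structure CDSs on common coordinates before a K2P distance.
#'
#' @param a,b Nucleotide strings or `mt_seq` records.
#' @return Named character vector of the two gapped sequences.
#' @export
align_cds_pair <- function(a, b) {
  sa <- if (inherits(a, "mt_seq")) a$residues else toupper(a)
  sb <- if (inherits(b, "mt_seq")) b$residues else toupper(b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 1)
  c(a = as.character(Biostrings::alignedPattern(aln)),
    b = as.character(Biostrings::alignedSubject(aln)))
}

.fmt_len <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration on the Q-criterion.  Ties in the
#' Q-criterion are broken by the lexicographically smallest pair of cluster
#' keys (a cluster's key is its smallest leaf label), making the result
#' deterministic.  Negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param d Symmetric labeled distance matrix with at least 3 labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d)
  if (is.null(labels) || nrow(d) < 3L) stop("need a labeled matrix with n >= 3")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  nwk <- labels
  key <- labels
  D <- d
  clamped <- FALSE
  cl <- function(x) { if (x < 0) clamped <<- TRUE; max(0, x) }
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pk <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[ij[1L]], key[ij[2L]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pk)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- cl(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- cl(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], .fmt_len(li), nwk[j], .fmt_len(lj))
    new_key <- min(key[i], key[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    D <- D2
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    rownames(D) <- colnames(D) <- key
  }
  l1 <- cl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- cl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- cl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  text <- sprintf("(%s:%s,%s:%s,%s:%s);",
                  nwk[1L], .fmt_len(l1), nwk[2L], .fmt_len(l2), nwk[3L], .fmt_len(l3))
  if (clamped) warning("negative branch length(s) clamped to 0")
  ape::read.tree(text = text)
}

#' Internal bipartitions of an unrooted tree
#'
#' One canonical string per non-trivial split: the tip set not containing
#' the alphabetically first label, sorted and joined with `|`.
#'
#' @param tree An `ape::phylo`.
#' @return Character vector of canonical split strings (possibly empty).
#' @export
tree_splits <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1L]
  parts <- ape::prop.part(tree)
  out <- character()
  for (p in parts) {
    set <- tips[p]
    if (length(set) < 2L || length(set) > length(tips) - 2L) next
    if (anchor %in% set) set <- setdiff(tips, set)
    if (length(set) < 2L) next
    out <- c(out, paste(sort(set), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for a K2P neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' per replicate, and reports, for each internal bipartition of the
#' point-estimate tree, the percentage of replicates containing it (rounded
#' down to an integer).  Supports are attached as node labels.
#'
#' @param seqs Named equal-length aligned sequences (character vector or
#'   list of `mt_seq`).
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed RNG seed controlling the resampling.
#' @return A list with `tree` (the point-estimate `phylo`, node labels set
#'   to supports) and `support` (named integer vector keyed by canonical
#'   split string).
#' @export
bootstrap_support <- function(seqs, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1L)
  if (is.list(seqs)) {
    seqs <- setNames(vapply(seqs, `[[`, "", "residues"),
                     vapply(seqs, `[[`, "", "id"))
  }
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(chars) <- names(seqs)
  ncol_aln <- ncol(chars)
  if (ncol_aln < 2L) stop("alignment has fewer than 2 columns")
  point <- nj_tree(.k2p_matrix_chars(chars))
  splits0 <- tree_splits(point)
  counts <- setNames(integer(length(splits0)), splits0)
  .with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      bt <- try(suppressWarnings(
        nj_tree(.k2p_matrix_chars(chars[, cols, drop = FALSE]))), silent = TRUE)
      if (inherits(bt, "try-error")) next
      bs <- tree_splits(bt)
      hit <- splits0 %in% bs
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- as.integer(floor(100 * counts / replicates))
  names(support) <- splits0
  # attach supports as node labels on the point tree
  tips <- point$tip.label
  anchor <- sort(tips)[1L]
  parts <- ape::prop.part(point)
  labs <- character(point$Nnode)
  for (k in seq_along(parts)) {
    set <- tips[parts[[k]]]
    if (length(set) < 2L || length(set) > length(tips) - 2L) next
    if (anchor %in% set) set <- setdiff(tips, set)
    if (length(set) < 2L) next
    keyk <- paste(sort(set), collapse = "|")
    if (keyk %in% names(support)) labs[k] <- as.character(support[[keyk]])
  }
  point$node.label <- labs
  list(tree = point, support = support)
}
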