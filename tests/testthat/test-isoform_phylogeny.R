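test_that("K2P matches its closed form and rejects saturation", {
  expect_equal(pairwise_k2p("ACGTACGT", "ACGTACGT"), 0)
  # one transition + one transversion over 10 sites: P = Q = 0.1
  a <- "AAAAAAAAAA"; b <- "GACAAAAAAA"
  expect_equal(pairwise_k2p(a, b), -0.5 * log(0.7) - 0.25 * log(0.8))
  # five transitions over 10 sites: P = 0.5, Q = 0 saturates the log
  expect_error(pairwise_k2p("AAAAAAAAAA", "GGGGGAAAAA"), "saturated")
  # sites with N or gaps are excluded pairwise
  expect_equal(pairwise_k2p("AANAAAAAA-", "GACAAAAAAT"),
               pairwise_k2p("AAAAAAAA", "GAAAAAAA"))
  expect_error(pairwise_k2p("AAA", "AAAA"), "equal length")
})

test_that("K2P is symmetric and increases with the transition proportion", {
  set.seed(4)
  base <- strsplit(random_dna_str(300), "")[[1L]]
  for (i in 1:5) {
    other <- base
    k <- sample(300, 25)
    other[k] <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
    d1 <- pairwise_k2p(paste(base, collapse = ""), paste(other, collapse = ""))
    expect_equal(d1, pairwise_k2p(paste(other, collapse = ""),
                                  paste(base, collapse = "")))
    expect_gte(d1, 0)
  }
  # monotone in P at fixed Q = 0
  swap_ts <- function(x, n) {  # n A->G transitions
    ch <- rep("A", 50); ch[seq_len(n)] <- "G"; paste(ch, collapse = "")
  }
  ds <- vapply(1:10, function(n) pairwise_k2p(strrep("A", 50), swap_ts(NULL, n)), 0)
  expect_true(all(diff(ds) > 0))
})

test_that("K2P agrees with an independent reference implementation", {
  set.seed(12)
  for (i in 1:5) {
    base <- sample(c("a", "c", "g", "t"), 200, replace = TRUE)
    other <- base
    k <- sample(200, 18)
    other[k] <- sample(c("a", "c", "g", "t"), 18, replace = TRUE)
    bin <- ape::as.DNAbin(rbind(x = base, y = other))
    want <- as.numeric(ape::dist.dna(bin, model = "K80"))
    got <- pairwise_k2p(paste(base, collapse = ""),
                        paste(other, collapse = ""))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("NJ solves the three-taxon tree in closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # three-point formulas: a = (dAB + dAC - dBC)/2 etc.
  br <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(br[c("A", "B", "C")]), c(2, 3, 7))
  expect_error(nj_tree(d[1:2, 1:2]), "n >= 3")
})

test_that("NJ reconstructs additive matrices exactly for n = 4..8", {
  for (n in 4:8) {
    set.seed(100 + n)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    tr$tip.label <- sort(tr$tip.label)
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    my <- nj_tree(D)
    # topology identical to the generating tree and to ape's NJ
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), my)), 0)
    expect_equal(as.numeric(ape::dist.topo(ape::nj(D), my)), 0)
    # branch lengths recovered: path lengths reproduce the input matrix
    expect_equal(ape::cophenetic.phylo(my)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("bootstrap gives 100 to a split every informative column supports", {
  cols_informative <- 8L; cols_constant <- 32L
  mk <- function(informative, constant) {
    paste(c(rep(informative, cols_informative),
            rep(constant, cols_constant)), collapse = "")
  }
  seqs <- c(t1 = mk("A", "A"), t2 = mk("A", "A"),
            t3 = mk("G", "A"), t4 = mk("G", "A"))
  bs <- bootstrap_support(seqs, replicates = 50L, seed = 7L)
  key <- canon_split(c("t3", "t4"), names(seqs))
  expect_equal(unname(bs$support[key]), 100L)
  expect_true(all(bs$support >= 0L & bs$support <= 100L))
  expect_error(bootstrap_support(c(a = "A", b = "A", c = "A"), 10, 1),
               "2 columns")
})

test_that("bootstrap support is seed-stable and bounded on noisy alignments", {
  set.seed(5)
  base <- strsplit(random_dna_str(120), "")[[1L]]
  seqs <- vapply(1:5, function(i) {
    ch <- base
    k <- sample(120, 6)
    ch[k] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- paste0("s", 1:5)
  b1 <- bootstrap_support(seqs, 30, seed = 11)
  b2 <- bootstrap_support(seqs, 30, seed = 11)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))
})

test_that("the four isoform groups are monophyletic with strong support", {
  aln <- simulate_isoform_alignment(5, seed = 1)
  bs <- suppressWarnings(bootstrap_support(aln, replicates = 100L, seed = 2L))
  splits <- tree_splits(bs$tree)
  for (iso in c("Mt1", "Mt2", "Mt3", "Mt4")) {
    key <- canon_split(paste0(iso, "_", 1:5), names(aln))
    expect_true(key %in% splits, label = paste(iso, "monophyletic"))
    expect_gte(bs$support[[key]], 95L)
  }
})

test_that("isoform classification combines exon III, distance and clade", {
  refs <- mt_reference_set()
  ts <- simulate_cluster_genome(sim_config(seed = 21))
  for (truth in ts$annotations) {
    call <- classify_isoform(truth, refs)
    expect_equal(call$isoform, truth$isoform)
    expect_equal(call$confidence, "high")
  }
  # intron-free copy: no exon evidence; distance alone gives medium
  cfg <- sim_config(seed = 33)
  g <- local({ set.seed(33); simulate_gene("Mt1", cfg, intron_free = TRUE) })
  contig <- mt_seq("c", paste0(random_dna_str(200, seed = 2), g$sequence,
                               random_dna_str(200, seed = 3)))
  m <- build_gene_model("g_free", contig, "+", g$exons + 200L, isoform = "unknown")
  call <- classify_isoform(m, refs, use_tree = FALSE)
  expect_equal(call$isoform, "Mt1")
  expect_equal(call$confidence, "medium")

  # equidistant references and a 92 bp exon III give unknown/low
  amb_refs <- list(mt_seq("Mt1_same", refs[[1]]$residues),
                   mt_seq("Mt2_same", refs[[1]]$residues))
  truth1 <- ts$annotations[[which(vapply(ts$annotations, `[[`, "", "isoform") == "Mt1")]]
  call2 <- classify_isoform(truth1, amb_refs,
                            ref_isoforms = c("Mt1", "Mt2"), use_tree = FALSE)
  expect_equal(call2$isoform, "unknown")
  expect_equal(call2$confidence, "low")
})

test_that("classification survives 2% point-mutation noise", {
  refs <- mt_reference_set()
  correct <- 0L; total <- 0L
  for (seed in c(51, 52)) {
    ts <- simulate_cluster_genome(sim_config(seed = seed, mutation_rate = 0.02))
    for (truth in ts$annotations) {
      total <- total + 1L
      call <- classify_isoform(truth, refs, use_tree = FALSE)
      if (call$isoform == truth$isoform) correct <- correct + 1L
    }
  }
  expect_gte(correct / total, 0.95)
})
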