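test_that("translate_cds follows the standard code and stop conventions", {
  expect_equal(translate_cds("ATGTGTTAA")$protein, "MC")
  expect_true(translate_cds("ATGTGTTAA")$hit_stop)
  expect_equal(translate_cds("ATGTGT")$protein, "MC")
  expect_false(translate_cds("ATGTGT")$hit_stop)
  expect_warning(translate_cds("ATGTGTA"), "codon multiple")
  set.seed(23)
  cds <- random_dna_str(900)
  expect_equal(translate_cds(cds, warn = FALSE)$protein,
               paste(oracle_translate(cds), collapse = ""))
})

test_that("spliced alignment recovers an exact intronless copy", {
  ref <- mt_reference_set()[[2]]
  win <- mt_seq("w", paste0(random_dna_str(300, seed = 3), ref$residues,
                            random_dna_str(300, seed = 4)))
  aln <- spliced_align(ref, win)
  expect_equal(nrow(aln$blocks), 1L)
  expect_equal(nrow(aln$introns), 0L)
  expect_equal(aln$identity, 1.0)
  expect_equal(aln$blocks$ctg_start, 301L)
  expect_equal(aln$blocks$ctg_end, 300L + nchar(ref$residues))
})

test_that("a GT..AG insert is recovered as an intron, GC..AG only if allowed", {
  # a G-free reference and an A/C-only intron interior leave the insert's
  # donor and acceptor as the only splice signals in play
  set.seed(8)
  ref <- mt_seq("refX", paste(sample(c("A", "C", "T"), 186, replace = TRUE),
                              collapse = ""))
  mk <- function(donor) {
    interior <- paste(sample(c("A", "C"), 96, replace = TRUE), collapse = "")
    insert <- paste0(donor, interior, "AG")
    flank <- function(seed) {
      set.seed(seed)
      paste(sample(c("A", "C", "T"), 200, replace = TRUE), collapse = "")
    }
    mt_seq("w", paste0(flank(9), substr(ref$residues, 1, 94), insert,
                       substr(ref$residues, 95, nchar(ref$residues)),
                       flank(10)))
  }
  aln <- spliced_align(ref, mk("GT"))
  expect_equal(nrow(aln$blocks), 2L)
  expect_equal(nrow(aln$introns), 1L)
  expect_equal(aln$introns$ctg_start, 295L)   # 200 flank + 94 exon + 1
  expect_equal(aln$introns$ctg_end, 294L + 100L)
  expect_equal(aln$introns$donor, "GT")
  expect_equal(aln$identity, 1.0)

  expect_error(spliced_align(ref, mk("GC")), "no spliced model")
  aln_gc <- spliced_align(ref, mk("GC"),
                          params = splice_params(gc_ag_allowed = TRUE))
  expect_equal(nrow(aln_gc$introns), 1L)
  expect_equal(aln_gc$introns$donor, "GC")
})

test_that("alignment score is invariant to unrelated flanks, coordinates shift", {
  ref <- mt_reference_set()[[3]]
  sim <- simulate_gene("Mt3", sim_config(seed = 77))
  core <- mt_seq("w0", sim$sequence)
  pad <- 500L
  padded <- mt_seq("w1", paste0(random_dna_str(pad, seed = 12), sim$sequence,
                                random_dna_str(pad, seed = 13)))
  a0 <- spliced_align(ref, core)
  a1 <- spliced_align(ref, padded)
  expect_equal(a1$score, a0$score)
  expect_equal(a1$blocks$ctg_start, a0$blocks$ctg_start + pad)
  expect_equal(a1$blocks$ctg_end, a0$blocks$ctg_end + pad)
})

test_that("models inherit exon structure, CDS splicing and flags", {
  ref <- mt_reference_set()[[2]]
  win <- mt_seq("w", paste0(random_dna_str(100, seed = 20), ref$residues,
                            random_dna_str(100, seed = 21)))
  m <- alignment_to_gene_model(spliced_align(ref, win))
  expect_true(m$intron_free)
  expect_equal(nchar(m$cds), nchar(ref$residues))
  expect_equal(m$cds, ref$residues)
  expect_equal(m$start_codon, "ATG")
  expect_equal(sum(abs(m$exons$end - m$exons$start) + 1L), nchar(m$cds))
  expect_equal(translate_cds(m$cds, warn = FALSE)$protein, m$protein)

  # an internal stop introduced into the copy is flagged
  mut <- ref$residues
  substr(mut, 61, 63) <- "TAA"
  win2 <- mt_seq("w2", paste0(random_dna_str(100, seed = 22), mut,
                              random_dna_str(100, seed = 23)))
  m2 <- alignment_to_gene_model(spliced_align(ref, win2))
  expect_true("internal_stop" %in% m2$flags)

  # a window missing the reference tail aligns well enough but covers <95%
  win3 <- mt_seq("w3", paste0(random_dna_str(100, seed = 24),
                              substr(ref$residues, 1, 166)))
  expect_error(alignment_to_gene_model(spliced_align(ref, win3)), "partial")
})

test_that("simulated three-exon genes recover their boundaries exactly", {
  cfg <- sim_config(seed = 5)
  refs <- mt_reference_set()
  names(refs) <- vapply(refs, `[[`, "", "id")
  ts <- simulate_cluster_genome(cfg)
  for (truth in ts$annotations) {
    ref <- refs[[paste0(truth$isoform, "_ref")]]
    sp <- gene_span(truth)
    win <- mt_seq("w", substring(ts$contig$residues,
                                 max(1, sp[1] - 500), sp[2] + 500))
    aln <- spliced_align(ref, win, params = splice_params(max_intron = 2000L),
                         offset = max(1, sp[1] - 500) - 1L,
                         contig_id = ts$contig$id)
    m <- alignment_to_gene_model(aln)
    expect_equal(m$exons, truth$exons)
  }
})

test_that("validation enforces the published exon-length envelopes", {
  ts <- simulate_cluster_genome(sim_config(seed = 8))
  for (truth in ts$annotations) {
    v <- validate_gene_model(truth)
    expect_true(v$pass)
    expect_length(v$diagnostics, 0L)
  }
  contig <- mt_seq("c", random_dna_str(2000, seed = 30))
  bad <- mt_gene_model("g", "c", "+",
                       data.frame(start = c(1, 200, 500),
                                  end = c(28, 259, 591)))
  bad$cds <- "ATGTGTTAA"; bad$protein <- "MC"
  bad$start_codon <- "ATG"; bad$stop_codon <- "TAA"
  v <- validate_gene_model(bad)
  expect_false(v$pass)
  expect_true(any(grepl("exon II length", v$diagnostics)))

  # Mt3-style 31/66/107 exon lengths sit inside the envelope
  cfg <- sim_config(seed = 41)
  g <- local({ set.seed(41); simulate_gene("Mt3", cfg) })
  lens <- g$exons$end - g$exons$start + 1L
  expect_equal(lens[2], 66L)
  expect_true(lens[1] == 31L && lens[3] %in% c(104L, 107L))
})
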