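test_that("simulated proteins obey the MT grammar for 100 seeds", {
  for (seed in 1:100) {
    iso <- c("Mt1", "Mt2", "Mt3", "Mt4")[(seed %% 4L) + 1L]
    p <- simulate_mt_protein(iso, seed = seed)
    prof <- mt_protein_profile(p)
    expect_equal(prof$cys_count, 20L)
    expect_equal(prof$beta_cys, 9L)
    expect_equal(prof$alpha_cys, 11L)
    expect_true(prof$length_aa >= 61L && prof$length_aa <= 68L)
    expect_true(score_mt_protein(p)$pass)
  }
  expect_identical(simulate_mt_protein("Mt2", seed = 1),
                   simulate_mt_protein("Mt2", seed = 1))
})

test_that("reverse translation is the left inverse of translation", {
  set.seed(6)
  p <- simulate_mt_protein("Mt1")
  cds <- reverse_translate(p, "TAG")
  expect_equal(nchar(cds), 3L * nchar(p) + 3L)
  expect_equal(translate_cds(cds)$protein, p)
})

test_that("grammar-preserving divergence keeps cysteines and the frame", {
  set.seed(8)
  anc <- reverse_translate(simulate_mt_protein("Mt1"), "TAA")
  der <- derive_cds(anc, 0.1)
  expect_equal(nchar(der), nchar(anc))
  expect_true(der != anc)
  pa <- translate_cds(anc)$protein; pd <- translate_cds(der)$protein
  expect_equal(nchar(pd), nchar(pa))
  expect_identical(gregexpr("C", pd)[[1]], gregexpr("C", pa)[[1]])
  expect_equal(substr(der, 1, 3), "ATG")
  expect_equal(substr(der, nchar(der) - 2, nchar(der)), "TAA")
})

test_that("simulated genes respect the published exon and intron envelopes", {
  cfg <- sim_config(seed = 1)
  set.seed(2)
  for (i in 1:10) {
    g3 <- simulate_gene("Mt3", cfg)
    lens <- g3$exons$end - g3$exons$start + 1L
    expect_equal(lens[1:2], c(31L, 66L))
    expect_true(lens[3] %in% 104:107)
    g2 <- simulate_gene("Mt2", cfg)
    i1 <- g2$introns$end[1] - g2$introns$start[1] + 1L
    expect_true(i1 >= 291L && i1 <= 297L)
    for (g in list(g3, g2)) {
      for (r in seq_len(nrow(g$introns))) {
        intr <- substr(g$sequence, g$introns$start[r], g$introns$end[r])
        expect_equal(substr(intr, 1, 2), "GT")
        expect_equal(substr(intr, nchar(intr) - 1, nchar(intr)), "AG")
      }
    }
  }
})

test_that("cluster simulation is fully deterministic under (config, seed)", {
  a <- simulate_cluster_genome(sim_config(seed = 19))
  b <- simulate_cluster_genome(sim_config(seed = 19))
  expect_identical(a$contig$residues, b$contig$residues)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$igr_draws, b$igr_draws)
  c2 <- simulate_cluster_genome(sim_config(seed = 20, species_id = "sp2"))
  expect_false(identical(a$contig$residues, c2$contig$residues))
  expect_identical(order_genes(a$annotations)$architecture_string,
                   order_genes(c2$annotations)$architecture_string)
})

test_that("draws stay inside the configured ranges across many seeds", {
  igr_rng <- list("Mt4-Mt3" = c(19583L, 36109L), "Mt3-Mt2" = c(7129L, 7571L),
                  "Mt2-Mt1a" = c(2064L, 5310L))
  for (seed in seq(1, 99, by = 2)) {   # 50 seeds
    ts <- simulate_cluster_genome(sim_config(seed = seed))
    for (key in names(ts$igr_draws)) {
      rng <- igr_rng[[key]]
      expect_true(ts$igr_draws[[key]] >= rng[1] && ts$igr_draws[[key]] <= rng[2],
                  label = sprintf("IGR %s within range (seed %d)", key, seed))
    }
    for (m in ts$annotations) {
      if (m$intron_free) next
      ex <- m$exons[order(m$exons$start), ]
      intron_lens <- ex$start[-1] - ex$end[-3] - 1L
      rng <- switch(m$isoform,
                    Mt1 = rbind(c(577, 612), c(344, 356)),
                    Mt2 = rbind(c(291, 297), c(205, 283)),
                    Mt3 = rbind(c(173, 181), c(803, 1098)),
                    Mt4 = rbind(c(1171, 1671), c(520, 1041)))
      expect_true(all(intron_lens >= rng[, 1] & intron_lens <= rng[, 2]),
                  label = sprintf("%s introns in range (seed %d)",
                                  m$isoform, seed))
    }
  }
})

test_that("mutation noise never moves truth coordinates", {
  clean <- simulate_cluster_genome(sim_config(seed = 25))
  noisy <- simulate_cluster_genome(sim_config(seed = 25, mutation_rate = 0.02))
  expect_false(identical(clean$contig$residues, noisy$contig$residues))
  for (i in seq_along(clean$annotations)) {
    expect_identical(clean$annotations[[i]]$exons, noisy$annotations[[i]]$exons)
  }
  # splice dinucleotides and terminal codons are protected
  for (m in noisy$annotations) {
    expect_equal(m$start_codon, "ATG")
    expect_true(m$stop_codon %in% c("TAA", "TAG"))
  }
})

test_that("an intron-free Mt1 copy is emitted outside the cluster on request", {
  ts <- simulate_cluster_genome(sim_config(seed = 13, intron_free_mt1_prob = 1))
  free <- Filter(function(m) m$intron_free, ts$annotations)
  expect_length(free, 1L)
  expect_equal(free[[1]]$isoform, "Mt1")
  cluster_end <- max(vapply(Filter(function(m) !m$intron_free, ts$annotations),
                            function(m) gene_span(m)[2], 1L))
  expect_gt(gene_span(free[[1]])[1], cluster_end)
  expect_true(validate_gene_model(free[[1]])$pass)
})

test_that("truth sets round-trip through FASTA + GFF3 files byte-identically", {
  ts <- simulate_cluster_genome(sim_config(seed = 3))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_truth_set(ts, d1)
  p2 <- write_truth_set(simulate_cluster_genome(sim_config(seed = 3)), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  back <- read_gff3_models(p1[["gff3"]], contigs = list(ts$contig))
  got <- back[order(vapply(back, function(m) gene_span(m)[1], 1L))]
  want <- ts$annotations[order(vapply(ts$annotations,
                                      function(m) gene_span(m)[1], 1L))]
  for (i in seq_along(want)) {
    expect_equal(got[[i]]$exons, want[[i]]$exons)
    expect_equal(got[[i]]$cds, want[[i]]$cds)
  }
})
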