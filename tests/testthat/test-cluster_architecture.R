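make_models <- function(spans, isoforms, contig = "c") {
  lapply(seq_along(isoforms), function(i) {
    mt_gene_model(paste0("g", i), contig, "+",
                  data.frame(start = spans[[i]][1], end = spans[[i]][2]),
                  isoform = isoforms[i])
  })
}

test_that("gene ordering is permutation-invariant and labels Mt1 copies", {
  spans <- list(c(1, 189), c(25000, 25200), c(33000, 33190), c(38000, 38190),
                c(41200, 41390))
  models <- make_models(spans, c("Mt4", "Mt3", "Mt2", "Mt1", "Mt1"))
  arch <- order_genes(models)
  expect_equal(arch$architecture_string, "Mt4-Mt3-Mt2-Mt1a-Mt1b")
  set.seed(2)
  for (i in 1:5) {
    shuffled <- order_genes(sample(models))
    expect_equal(shuffled$architecture_string, arch$architecture_string)
    expect_equal(shuffled$igrs, arch$igrs)
  }
  # a single Mt1 carries no copy suffix
  solo <- order_genes(make_models(spans[1:4], c("Mt4", "Mt3", "Mt2", "Mt1")))
  expect_equal(solo$architecture_string, "Mt4-Mt3-Mt2-Mt1")
  # overlap is an error
  bad <- make_models(list(c(1, 200), c(150, 400)), c("Mt4", "Mt3"))
  expect_error(order_genes(bad), "inconsistent models")
})

test_that("Mt1 copy letters run outward from the Mt2-proximal copy", {
  spans <- list(c(1000, 1190), c(5000, 5190), c(9000, 9190))
  models <- make_models(spans, c("Mt1", "Mt1", "Mt2"))
  arch <- order_genes(models)
  # Mt2 sits rightmost: the copy at 5000 (nearer Mt2) is "a"
  expect_equal(arch$architecture_string, "Mt1b-Mt1a-Mt2")
})

test_that("IGR lengths count bases strictly between gene spans", {
  ig <- compute_igrs(make_models(list(c(1, 100), c(201, 300)), c("Mt4", "Mt3")))
  expect_equal(ig$length, 100L)
  ig0 <- compute_igrs(make_models(list(c(1, 100), c(101, 200)), c("Mt4", "Mt3")))
  expect_equal(ig0$length, 0L)
})

test_that("a cluster spaced by the Inia geoffrensis IGRs returns them", {
  igrs <- c(19583L, 7232L, 5310L, 3084L)
  lens <- c(4500L, 1200L, 700L, 1100L, 1100L)
  starts <- integer(5); starts[1] <- 1000L
  for (i in 2:5) starts[i] <- starts[i - 1] + lens[i - 1] + igrs[i - 1]
  spans <- lapply(1:5, function(i) c(starts[i], starts[i] + lens[i] - 1L))
  arch <- order_genes(make_models(spans, c("Mt4", "Mt3", "Mt2", "Mt1", "Mt1")))
  expect_equal(arch$igrs$length, igrs)
})

test_that("cluster span equals gene lengths plus IGRs", {
  ts <- simulate_cluster_genome(sim_config(seed = 14))
  arch <- order_genes(ts$annotations)
  spans <- t(vapply(arch$genes, gene_span, integer(2)))
  total <- max(spans[, 2]) - min(spans[, 1]) + 1L
  expect_equal(total,
               sum(spans[, 2] - spans[, 1] + 1L) + sum(arch$igrs$length))
  expect_equal(unname(arch$igrs$length), unname(as.integer(ts$igr_draws)))
})

test_that("summarize_lengths implements mean/sample-SD/min/max with policies", {
  cells <- lapply(c("1", "2", "3"), parse_length_cell)
  st <- summarize_lengths(cells)
  expect_equal(c(st$mean, st$sd, st$min, st$max), c(2, 1, 1, 3))
  expect_error(summarize_lengths(list(parse_length_cell(""))), "missing")

  rng <- lapply(c("10-20", "30"), parse_length_cell)
  expect_equal(summarize_lengths(rng, range_policy = "low")$mean, 20)
  expect_equal(summarize_lengths(rng, range_policy = "high")$mean, 25)
  expect_equal(summarize_lengths(rng, range_policy = "midpoint")$mean, 22.5)
  expect_equal(summarize_lengths(rng, range_policy = "exclude")$n, 1L)

  multi <- lapply(c("611(a)-578(b)", "600"), parse_length_cell)
  expect_equal(summarize_lengths(multi, copy = "a")$mean, 605.5)
  expect_equal(summarize_lengths(multi, copy = "b")$n, 2L)
  expect_equal(summarize_lengths(multi, copy = "b")$mean, 589)
  expect_equal(summarize_lengths(multi, copy = "c")$n, 1L)
})

test_that("summary mean is translation-equivariant, sd translation-invariant", {
  set.seed(9)
  vals <- sample(100:999, 12)
  cells <- lapply(as.character(vals), parse_length_cell)
  shift <- lapply(as.character(vals + 500L), parse_length_cell)
  perm <- lapply(as.character(sample(vals)), parse_length_cell)
  s0 <- summarize_lengths(cells)
  expect_equal(summarize_lengths(shift)$mean, s0$mean + 500)
  expect_equal(summarize_lengths(shift)$sd, s0$sd)
  expect_equal(summarize_lengths(perm)$mean, s0$mean)
  expect_equal(summarize_lengths(perm)$sd, s0$sd)
})

test_that("exon and intron fixture summaries match the published envelopes", {
  rep <- summarize_exon_intron_tables()
  row <- function(tab, col) rep[rep$table == tab & rep$column == col, ]
  m <- row("exon_lengths", "Mt1_ExonII")
  expect_equal(c(m$mode, m$min, m$max), c(66, 66, 66))
  e3 <- row("exon_lengths", "Mt3_ExonIII")
  expect_equal(c(e3$min, e3$max), c(104, 107))
  i4 <- row("intron_lengths", "Mt4_IntronI")
  expect_equal(c(i4$min, i4$max), c(1171, 1671))
  # per-copy policy: copy (a) of the Mt1 intron I column spans 577-612
  i1 <- row("intron_lengths", "Mt1_IntronI")
  expect_equal(c(i1$min, i1$max), c(577, 612))
})
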