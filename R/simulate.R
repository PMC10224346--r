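.MT_FILLER <- c("K", "S", "G", "A", "T", "E", "D", "P", "Q", "N")

# protein lengths implied by the canonical exon lengths (CDS includes stop):
# Mt1/Mt2 28+66+92=186 -> 61 aa; Mt4 31+66+92=189 -> 62 aa;
# Mt3 31+66+107=204 -> 67 aa
.MT_EXONS <- list(Mt1 = c(28L, 66L, 92L), Mt2 = c(28L, 66L, 92L),
                  Mt3 = c(31L, 66L, 107L), Mt4 = c(31L, 66L, 92L))

.MT_INTRON_RANGES <- list(
  Mt1 = list(c(577L, 612L), c(344L, 356L)),
  Mt2 = list(c(291L, 297L), c(205L, 283L)),
  Mt3 = list(c(173L, 181L), c(803L, 1098L)),
  Mt4 = list(c(1171L, 1671L), c(520L, 1041L)))

.MT_IGR_RANGES <- list(
  "Mt4-Mt3" = c(19583L, 36109L), "Mt3-Mt2" = c(7129L, 7571L),
  "Mt2-Mt1a" = c(2064L, 5310L), "Mt2-Mt1" = c(2064L, 5310L),
  "Mt1a-Mt1b" = c(2729L, 3214L), "Mt1b-Mt1c" = c(3088L, 3926L))

.draw_range <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

# lay out cysteine motif blocks inside a segment of given width, separated by
# random filler; every cysteine sits in a CC/CXC/CXXC motif by construction
.cys_segment <- function(blocks, width) {
  pieces <- lapply(blocks, function(b) {
    ch <- strsplit(b, "")[[1L]]
    ch[ch == "X"] <- sample(.MT_FILLER, sum(ch == "X"), replace = TRUE)
    paste(ch, collapse = "")
  })
  used <- sum(nchar(unlist(pieces)))
  pad <- width - used
  if (pad < length(blocks) + 1L) stop("segment too short for motif blocks")
  gaps <- tabulate(sample.int(length(blocks) + 1L, pad, replace = TRUE),
                   nbins = length(blocks) + 1L)
  out <- character()
  for (i in seq_along(pieces)) {
    out <- c(out, paste(sample(.MT_FILLER, gaps[i], replace = TRUE), collapse = ""),
             pieces[[i]])
  }
  out <- c(out, paste(sample(.MT_FILLER, gaps[length(gaps)], replace = TRUE),
                      collapse = ""))
  paste(out, collapse = "")
}

#' Simulate a grammar-conforming metallothionein protein
#'
#' Builds a protein of the isoform's canonical length (61 aa for Mt1/Mt2,
#' 62 for Mt4, 67 for Mt3) with exactly 20 cysteines: 9 in the N-terminal
#' beta segment and 11 in the C-terminal alpha segment, all arranged in
#' CC/CXC/CXXC motifs, with non-cysteine residues drawn from an
#' MT-plausible alphabet (K/S/G/A/T/E/D/P/Q/N).  Deterministic under a
#' fixed seed, and always passes [score_mt_protein()].
#'
#' @param isoform One of `"Mt1"`, `"Mt2"`, `"Mt3"`, `"Mt4"`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A protein string.
#' @export
simulate_mt_protein <- function(isoform = c("Mt1", "Mt2", "Mt3", "Mt4"),
                                seed = NULL) {
  isoform <- match.arg(isoform)
  if (!is.null(seed)) return(.with_seed(seed, simulate_mt_protein(isoform)))
  exons <- .MT_EXONS[[isoform]]
  len_aa <- sum(exons) / 3L - 1L
  beta_len <- (exons[1L] + exons[2L]) %/% 3L   # exons I+II encode beta
  beta_blocks <- c("CXC", "CC", "CCC", "CC")          # 9 cysteines
  alpha_blocks <- c("CXXC", "CC", "CXC", "CCC", "CC") # 11 cysteines
  beta <- .cys_segment(beta_blocks, beta_len - 1L)    # minus leading M
  alpha <- .cys_segment(alpha_blocks, len_aa - beta_len)
  paste0("M", beta, alpha)
}

.SYN_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Reverse-translate a protein with uniform synonymous codons
#'
#' @param protein Protein string (no stop character).
#' @param stop_codon Appended stop codon, `"TAA"` or `"TAG"` (`NULL` for
#'   none).
#' @return A nucleotide CDS string.
#' @export
reverse_translate <- function(protein, stop_codon = "TAA") {
  aas <- strsplit(toupper(protein), "")[[1L]]
  codons <- vapply(aas, function(a) {
    cand <- .SYN_CODONS[[a]]
    if (is.null(cand)) stop("cannot reverse-translate residue '", a, "'")
    if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }, "")
  paste0(paste(codons, collapse = ""), if (is.null(stop_codon)) "" else stop_codon)
}

#' Derive a descendant CDS under purifying selection
#'
#' Applies random point substitutions at the given per-site rate while
#' preserving the MT grammar exactly: start and stop codons are untouched,
#' no substitution may create or destroy a cysteine codon or create a stop.
#' Within cysteine codons only the synonymous TGT/TGC exchange is allowed.
#'
#' @param cds A CDS string (ATG through stop, length a codon multiple).
#' @param rate Per-site substitution proposal rate.
#' @return The derived CDS, same length.
#' @export
derive_cds <- function(cds, rate) {
  cds <- toupper(cds)
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  ch <- strsplit(cds, "")[[1L]]
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  hit <- which(runif(n) < rate)
  hit <- hit[hit > 3L & hit <= n - 3L]
  for (pos in hit) {
    codon_i <- (pos - 1L) %/% 3L
    cstart <- codon_i * 3L + 1L
    old_codon <- paste(ch[cstart:(cstart + 2L)], collapse = "")
    old_aa <- gc[[old_codon]]
    new_base <- sample(setdiff(bases, ch[pos]), 1L)
    new <- ch[cstart:(cstart + 2L)]
    new[pos - cstart + 1L] <- new_base
    new_codon <- paste(new, collapse = "")
    new_aa <- gc[[new_codon]]
    ok <- new_aa != "*" &&
      ((old_aa == "C") == (new_aa == "C")) &&
      (old_aa != "C" || new_aa == "C")
    if (ok) ch[pos] <- new_base
  }
  paste(ch, collapse = "")
}

# one root MT CDS; isoform ancestors descend from it (Mt4 and Mt3 carry 1
# and 6 extra filler codons inserted near the C terminus) so that between-
# isoform distances are large but unsaturated
.mt_ancestors <- function(ancestor_seed = 424243L, isoform_divergence = 0.12) {
  .with_seed(ancestor_seed, {
    root_prot <- simulate_mt_protein("Mt1")
    root <- reverse_translate(root_prot, "TAA")
    insert_codons <- function(cds, k) {
      if (k == 0L) return(cds)
      fill <- reverse_translate(
        paste(sample(.MT_FILLER, k, replace = TRUE), collapse = ""),
        stop_codon = NULL)
      at <- nchar(cds) - 9L   # before the last 2 codons + stop
      paste0(substr(cds, 1L, at), fill, substr(cds, at + 1L, nchar(cds)))
    }
    extra <- c(Mt1 = 0L, Mt2 = 0L, Mt4 = 1L, Mt3 = 6L)
    out <- lapply(names(extra), function(iso) {
      derive_cds(insert_codons(root, extra[[iso]]), isoform_divergence)
    })
    names(out) <- names(extra)
    out[c("Mt1", "Mt2", "Mt3", "Mt4")]
  })
}

#' Synthetic reference CDS set, one per isoform
#'
#' The simulator's isoform ancestor coding sequences, packaged as records
#' usable as the detection/annotation reference set.  Generated from the
#' grammar; no external accessions are bundled.
#'
#' @param ancestor_seed Seed fixing the ancestral sequences.
#' @return List of four nucleotide `mt_seq` records with ids `Mt1_ref` ...
#'   `Mt4_ref`.
#' @export
mt_reference_set <- function(ancestor_seed = 424243L) {
  anc <- .mt_ancestors(ancestor_seed)
  lapply(names(anc), function(iso) {
    mt_seq(paste0(iso, "_ref"), anc[[iso]],
           description = "synthetic isoform ancestor CDS")
  })
}

#' Simulation configuration with published defaults
#'
#' Defaults encode the published cetacean MT cluster measurements: canonical
#' exon lengths per isoform (Mt1/Mt2 28/66/92 bp, Mt3 31/66/107, Mt4
#' 31/66/92, the modal published values), intron length ranges per isoform
#' from the published min-max envelopes, and intergenic-region ranges per
#' adjacent gene pair likewise.  Species coding sequences descend from fixed
#' per-isoform ancestors by grammar-preserving substitutions at
#' `cds_divergence` per site.
#'
#' @param seed RNG seed; mandatory, drives every draw.
#' @param species_id Contig/species identifier stem.
#' @param cluster_layout Ordered isoform labels placed left to right on the
#'   plus strand.
#' @param exon_lengths,intron_ranges,igr_ranges Override the published
#'   defaults (same shapes as the defaults).
#' @param mutation_rate Per-site point-mutation rate applied to the final
#'   contig outside splice dinucleotides and start/stop codons.
#' @param intron_free_mt1_prob Probability of adding one dispersed
#'   intron-free Mt1 copy outside the main cluster.
#' @param cds_divergence Per-site divergence of each gene from its isoform
#'   ancestor (synonymous/grammar-preserving).
#' @param flank_length Random flanking sequence on each side (bp).
#' @param ancestor_seed Seed fixing the shared ancestral CDS set.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, species_id = "sim1",
                       cluster_layout = c("Mt4", "Mt3", "Mt2", "Mt1a"),
                       exon_lengths = .MT_EXONS,
                       intron_ranges = .MT_INTRON_RANGES,
                       igr_ranges = .MT_IGR_RANGES,
                       mutation_rate = 0,
                       intron_free_mt1_prob = 0,
                       cds_divergence = 0.02,
                       flank_length = 2000L,
                       ancestor_seed = 424243L) {
  stopifnot(!missing(seed), mutation_rate >= 0, mutation_rate <= 1,
            intron_free_mt1_prob >= 0, intron_free_mt1_prob <= 1)
  structure(list(seed = as.integer(seed), species_id = species_id,
                 cluster_layout = cluster_layout,
                 exon_lengths = exon_lengths, intron_ranges = intron_ranges,
                 igr_ranges = igr_ranges, mutation_rate = mutation_rate,
                 intron_free_mt1_prob = intron_free_mt1_prob,
                 cds_divergence = cds_divergence,
                 flank_length = as.integer(flank_length),
                 ancestor_seed = as.integer(ancestor_seed)),
            class = "sim_config")
}

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.draw_intron <- function(range) {
  len <- .draw_range(range)
  repeat {
    interior <- .random_dna(len - 4L)
    intron <- paste0("GT", interior, "AG")
    # forbid an alternative donor right after the true one or an alternative
    # acceptor right before the true one, so the spliced parse is unambiguous
    if (substr(intron, 3L, 4L) != "GT" &&
        substr(intron, len - 3L, len - 2L) != "AG") return(intron)
  }
}

#' Simulate one metallothionein gene
#'
#' Draws exon and intron lengths from the configured ranges, derives the
#' coding sequence from the isoform ancestor (grammar-preserving
#' substitutions at `cds_divergence`), and assembles
#' exon-I/intron-I/exon-II/intron-II/exon-III with GT..AG introns.  Exon III
#' includes the stop codon.  Uses the current RNG stream.
#'
#' @param isoform `"Mt1"` ... `"Mt4"`.
#' @param config A [sim_config()].
#' @param intron_free Emit a single-exon (processed) copy.
#' @return A list with `sequence` (gene string), `exons` (data frame of
#'   gene-relative intervals), `introns` (data frame), `cds`.
#' @export
simulate_gene <- function(isoform, config, intron_free = FALSE) {
  exons <- config$exon_lengths[[isoform]]
  anc <- .mt_ancestors(config$ancestor_seed)[[isoform]]
  if (nchar(anc) == sum(exons)) {
    cds <- derive_cds(anc, config$cds_divergence)
  } else {
    # non-default exon configuration: simulate a fresh grammar protein
    prot <- simulate_mt_protein(isoform)
    need <- sum(exons) / 3L - 1L
    if (nchar(prot) != need) stop("exon draw incompatible with protein length")
    cds <- reverse_translate(prot, sample(c("TAA", "TAG"), 1L))
  }
  if (intron_free) {
    return(list(sequence = cds,
                exons = data.frame(start = 1L, end = nchar(cds)),
                introns = data.frame(start = integer(), end = integer()),
                cds = cds))
  }
  i1 <- .draw_intron(config$intron_ranges[[isoform]][[1L]])
  i2 <- .draw_intron(config$intron_ranges[[isoform]][[2L]])
  e <- cumsum(exons)
  ex1 <- substr(cds, 1L, e[1L])
  ex2 <- substr(cds, e[1L] + 1L, e[2L])
  ex3 <- substr(cds, e[2L] + 1L, e[3L])
  seqs <- paste0(ex1, i1, ex2, i2, ex3)
  s1 <- 1L; e1 <- exons[1L]
  s2 <- e1 + nchar(i1) + 1L; e2 <- s2 + exons[2L] - 1L
  s3 <- e2 + nchar(i2) + 1L; e3 <- s3 + exons[3L] - 1L
  list(sequence = seqs,
       exons = data.frame(start = c(s1, s2, s3), end = c(e1, e2, e3)),
       introns = data.frame(start = c(e1 + 1L, e2 + 1L),
                            end = c(s2 - 1L, s3 - 1L)),
       cds = cds)
}

#' Simulate a contig carrying a metallothionein cluster, with ground truth
#'
#' Places the configured gene layout co-oriented on the plus strand,
#' separated by intergenic regions drawn from the configured ranges and
#' flanked by random sequence; optionally adds one dispersed intron-free Mt1
#' copy beyond the cluster.  Point mutations at `mutation_rate` are applied
#' everywhere except splice dinucleotides and start/stop codons, so truth
#' coordinates are mutation-invariant.  Fully deterministic under
#' (config, seed).
#'
#' @param config A [sim_config()].
#' @return An `mt_truth_set`: list with `contig` (`mt_seq`), `annotations`
#'   (list of ground-truth `mt_gene_model`s), `igr_draws` (named integer
#'   vector of the drawn IGR lengths) and `config`.
#' @export
simulate_cluster_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    contig_id <- paste0(config$species_id, "_contig")
    parts <- character()
    pos <- 0L
    add <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
    add(.random_dna(config$flank_length))
    layout <- config$cluster_layout
    gene_info <- list()
    igr_draws <- integer()
    for (i in seq_along(layout)) {
      label <- layout[i]
      isoform <- sub("[abc]$", "", label)
      g <- simulate_gene(isoform, config)
      gene_info[[label]] <- list(label = label, isoform = isoform,
                                 copy = if (grepl("[abc]$", label))
                                   substr(label, nchar(label), nchar(label))
                                 else NA_character_,
                                 offset = pos, gene = g)
      add(g$sequence)
      if (i < length(layout)) {
        key <- paste(label, layout[i + 1L], sep = "-")
        rng <- config$igr_ranges[[key]]
        if (is.null(rng)) rng <- c(3000L, 5000L)
        igr <- .draw_range(rng)
        igr_draws[[key]] <- igr
        add(.random_dna(igr))
      }
    }
    if (runif(1L) < config$intron_free_mt1_prob) {
      add(.random_dna(sample(5000:15000, 1L)))
      g <- simulate_gene("Mt1", config, intron_free = TRUE)
      gene_info[["Mt1_free"]] <- list(label = "Mt1_free", isoform = "Mt1",
                                      copy = NA_character_, offset = pos, gene = g)
      add(g$sequence)
    }
    add(.random_dna(config$flank_length))
    contig_seq <- paste(parts, collapse = "")

    # point mutations outside splice dinucleotides and start/stop codons
    if (config$mutation_rate > 0) {
      protected <- unlist(lapply(gene_info, function(gi) {
        ex <- gi$gene$exons + gi$offset
        intr <- gi$gene$introns + gi$offset
        p <- c(ex$start[1L]:(ex$start[1L] + 2L),
               (ex$end[nrow(ex)] - 2L):ex$end[nrow(ex)])
        if (nrow(intr)) {
          p <- c(p, intr$start, intr$start + 1L, intr$end - 1L, intr$end)
        }
        p
      }))
      ch <- strsplit(contig_seq, "")[[1L]]
      hit <- which(runif(length(ch)) < config$mutation_rate)
      hit <- setdiff(hit, protected)
      for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      contig_seq <- paste(ch, collapse = "")
    }

    contig <- mt_seq(contig_id, contig_seq,
                     description = paste0("synthetic MT cluster, seed ", config$seed))
    annotations <- lapply(gene_info, function(gi) {
      build_gene_model(paste0(config$species_id, "_", gi$label), contig, "+",
                       gi$gene$exons + gi$offset,
                       isoform = gi$isoform, copy_label = gi$copy)
    })
    names(annotations) <- NULL
    structure(list(contig = contig, annotations = annotations,
                   igr_draws = igr_draws, config = config),
              class = "mt_truth_set")
  })
}

#' @export
print.mt_truth_set <- function(x, ...) {
  cat(sprintf("<mt_truth_set %s> %d bp, %d genes, seed %d\n",
              x$contig$id, nchar(x$contig$residues),
              length(x$annotations), x$config$seed))
  invisible(x)
}

#' Write a truth set to FASTA + GFF3 (+ config echo)
#'
#' @param ts An `mt_truth_set`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_truth_set <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, ts$contig$id)
  fa <- paste0(stem, ".fasta"); gff <- paste0(stem, ".gff3")
  cfgf <- paste0(stem, ".config.txt")
  write_fasta(ts$contig, fa)
  write_gff3(ts$annotations, gff,
             contig_lengths = setNames(nchar(ts$contig$residues), ts$contig$id))
  cfg <- ts$config
  lines <- c(sprintf("seed: %d", cfg$seed),
             sprintf("species_id: %s", cfg$species_id),
             sprintf("cluster_layout: %s", paste(cfg$cluster_layout, collapse = ",")),
             sprintf("mutation_rate: %g", cfg$mutation_rate),
             sprintf("cds_divergence: %g", cfg$cds_divergence),
             sprintf("intron_free_mt1_prob: %g", cfg$intron_free_mt1_prob),
             sprintf("flank_length: %d", cfg$flank_length),
             sprintf("ancestor_seed: %d", cfg$ancestor_seed))
  writeLines(lines, cfgf)
  invisible(c(fasta = fa, gff3 = gff, config = cfgf))
}

#' Equal-length alignment of synthetic isoform coding sequences
#'
#' Derives `n_per` grammar-preserving descendants of each isoform ancestor
#' and truncates all sequences to the shortest CDS length, yielding a
#' strong-signal alignment whose four isoform groups are deeply separated
#' relative to within-group divergence.
#'
#' @param n_per Sequences per isoform.
#' @param seed RNG seed.
#' @param divergence Within-isoform per-site divergence.
#' @param ancestor_seed Seed fixing the shared ancestors.
#' @return Named character vector of equal-length sequences, labels
#'   `Mt1_1` ... `Mt4_<n_per>`.
#' @export
simulate_isoform_alignment <- function(n_per = 5L, seed = 1L,
                                       divergence = 0.02,
                                       ancestor_seed = 424243L) {
  anc <- .mt_ancestors(ancestor_seed)
  .with_seed(seed, {
    out <- character(); labs <- character()
    for (iso in names(anc)) {
      for (i in seq_len(n_per)) {
        out <- c(out, derive_cds(anc[[iso]], divergence))
        labs <- c(labs, sprintf("%s_%d", iso, i))
      }
    }
    len <- min(nchar(out))
    setNames(substr(out, 1L, len), labs)
  })
}
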