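test_that("the generator is deterministic under its seed", {
  p <- sim_params(n_chromosomes = 2, chromosome_lengths = 3e5,
                  contig_min = 5e4, contig_max = 1e5, n_contacts = 1e5,
                  seed = 61)
  g1 <- simulate_genome(p)
  g2 <- simulate_genome(p)
  expect_equal(as.character(g1), as.character(g2))
  expect_equal(Biostrings::width(g1), p$chromosome_lengths)
  e1 <- simulate_hic_experiment(p)
  e2 <- simulate_hic_experiment(p)
  expect_equal(e1$truth$segments, e2$truth$segments)
  expect_equal(as.matrix(e1$matrix$counts), as.matrix(e2$matrix$counts))
})

test_that("simulated sequence composition is uniform within binomial bounds", {
  p <- sim_params(n_chromosomes = 1, chromosome_lengths = 1e6, seed = 62)
  g <- simulate_genome(p)
  gc <- Biostrings::letterFrequency(g[[1]], "GC") / 1e6
  # 3 sigma of a Binomial(1e6, 0.5) proportion
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e6))
})

test_that("fragmentation tiles the genome and inverts cleanly without chimeras", {
  p <- sim_params(n_chromosomes = 2, chromosome_lengths = 4e5,
                  contig_min = 4e4, contig_max = 9e4, seed = 63)
  g <- simulate_genome(p)
  tr <- fragment_genome(p, sequences = g)
  expect_equal(sum(tr$contigs$length), sum(p$chromosome_lengths))
  expect_equal(nrow(tr$junctions), 0)
  # undo flips and concatenate per chromosome: reproduces each chromosome
  seg <- tr$segments
  for (chrom in names(g)) {
    ss <- seg[seg$chrom == chrom, ]
    ss <- ss[order(ss$chrom_start), ]
    rebuilt <- paste(vapply(seq_len(nrow(ss)), function(i) {
      s <- Biostrings::subseq(tr$sequences[[ss$contig_id[i]]],
                              ss$seg_start[i] + 1, ss$seg_end[i])
      if (ss$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1)), collapse = "")
    expect_equal(rebuilt, as.character(g[[chrom]]))
  }
})

test_that("chimeric junction counts match an independent recount from the truth table", {
  p <- sim_params(n_chromosomes = 2, chromosome_lengths = 2e6,
                  chimera_rate = 0.2, seed = 64)
  tr <- fragment_genome(p)
  # recount: a chimeric contig is exactly one with two truth segments
  nseg <- table(tr$segments$contig_id)
  expect_equal(nrow(tr$junctions), sum(nseg == 2))
  expect_true(all(nseg <= 2))
  # junctions lie strictly inside their contig
  for (k in seq_len(nrow(tr$junctions))) {
    L <- tr$contigs$length[tr$contigs$contig_id == tr$junctions$contig_id[k]]
    expect_gt(tr$junctions$position[k], 0)
    expect_lt(tr$junctions$position[k], L)
  }
})

test_that("contact decay follows the configured power law", {
  p <- sim_params(n_chromosomes = 1, chromosome_lengths = 2e6,
                  n_contacts = 4e6, trans_fraction = 0, seed = 65)
  ex <- simulate_hic_experiment(p)
  bins <- ex$matrix$bins
  tp <- hicscaffold:::true_bin_positions(bins, ex$truth)
  cm <- as.matrix(ex$matrix$counts)
  d <- abs(outer(tp$pos, tp$pos, "-"))
  b <- p$bin_size
  pick <- function(dist) {
    sel <- upper.tri(d) & abs(d - dist) < b / 2
    mean(cm[sel])
  }
  ratio <- pick(2 * b) / pick(4 * b)
  expected <- ((4 * b + p$d0) / (2 * b + p$d0))^p$alpha
  expect_equal(ratio, expected, tolerance = 0.05)
  # total mass close to the requested depth (Poisson total)
  total <- sum(Matrix::triu(ex$matrix$counts))
  expect_lt(abs(total - p$n_contacts), 4 * sqrt(p$n_contacts))
})

test_that("a sharp decay with no trans leaves only near-diagonal contacts in true order", {
  p <- sim_params(n_chromosomes = 1, chromosome_lengths = 5e5,
                  contig_min = 1e5, contig_max = 2e5,
                  n_contacts = 1e5, alpha = 20, trans_fraction = 0,
                  seed = 66)
  ex <- simulate_hic_experiment(p)
  tp <- hicscaffold:::true_bin_positions(ex$matrix$bins, ex$truth)
  ord <- order(tp$pos)
  cm <- as.matrix(ex$matrix$counts)[ord, ord]
  n <- nrow(cm)
  far <- abs(.row(dim(cm)) - .col(dim(cm))) > 2
  expect_equal(sum(cm[far]), 0)
  expect_gt(sum(cm[!far]), 0)
})

test_that("the evaluator scores the truth-ordered assembly perfectly and is reflection invariant", {
  p <- sim_params(n_chromosomes = 2, chromosome_lengths = 1.5e6,
                  n_contacts = 1e5, seed = 67)
  tr <- fragment_genome(p)
  tv <- hicscaffold:::truth_contig_view(tr)
  chains <- lapply(split(tv, tv$chrom), function(sub) {
    sub <- sub[order(sub$offset), ]
    data.frame(scaffold_id = sub$contig_id, orientation = sub$strand,
               stringsAsFactors = FALSE)
  })
  names(chains) <- sprintf("hic_scaffold_%d", seq_along(chains))
  a <- structure(list(chains = chains, unplaced_chains = list(),
                      unplaced_originals = character(),
                      set_aside = character(), log = list()),
                 class = "hic_assembly")
  ev <- evaluate_assembly(a, tr)
  expect_equal(ev$adjacency_accuracy, 1.0)
  expect_equal(ev$orientation_accuracy, 1.0)
  expect_equal(ev$grouping_purity, 1.0)
  expect_equal(ev$chain_count, 2)
  # reversing a chain changes nothing
  a2 <- a
  a2$chains[[1]] <- hicscaffold:::flip_chain(a2$chains[[1]])
  expect_equal(evaluate_assembly(a2, tr), ev)
  # chain order does not matter either
  a3 <- a
  a3$chains <- rev(a3$chains)
  expect_equal(evaluate_assembly(a3, tr), ev)
})

test_that("breaking adjacencies is counted per broken true pair", {
  # synthetic truth: one chromosome of 10 contigs tiled in order, all +
  segments <- data.frame(
    contig_id = sprintf("c%02d", 1:10),
    seg_start = 0, seg_end = 100,
    chrom = "chr1", chrom_start = (0:9) * 100,
    chrom_end = (1:10) * 100,
    strand = "+", stringsAsFactors = FALSE)
  tr <- structure(list(contigs = data.frame(contig_id = segments$contig_id,
                                            length = 100),
                       segments = segments,
                       junctions = data.frame(contig_id = character(),
                                              position = numeric()),
                       sequences = NULL), class = "truth_table")
  ord <- c(1, 2, 3, 5, 4, 6, 7, 8, 9, 10)  # swap the adjacent pair (4,5)
  a <- structure(list(chains = list(hic_scaffold_1 = data.frame(
    scaffold_id = sprintf("c%02d", ord), orientation = "+",
    stringsAsFactors = FALSE)),
    unplaced_chains = list(), unplaced_originals = character(),
    set_aside = character(), log = list()), class = "hic_assembly")
  ev <- evaluate_assembly(a, tr)
  # hand enumeration: the swap breaks the true pairs (3,4), (4,5), (5,6);
  # the other 6 of the 9 true adjacencies survive
  expect_equal(ev$adjacency_accuracy, 6 / 9)
  expect_error(
    evaluate_assembly(structure(list(chains = list(data.frame(
      scaffold_id = "nope", orientation = "+")),
      unplaced_chains = list(), unplaced_originals = character(),
      set_aside = character(), log = list()), class = "hic_assembly"), tr),
    "not in truth")
})
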