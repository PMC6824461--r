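test_that("hic_score matches the direct double-sum oracle", {
  expect_equal(hic_score(matrix(0, 3, 3)), 0)
  a <- matrix(0, 3, 3)
  a[1, 3] <- a[3, 1] <- 5
  expect_equal(hic_score(a), 10)
  expect_equal(hic_score(a), score_oracle(a))
  expect_error(hic_score(matrix(0, 2, 3)), "square")
  set.seed(41)
  for (k in 1:20) {
    n <- sample(2:12, 1)
    m <- matrix(runif(n * n, 0, 50), n)
    m <- m + t(m)
    expect_equal(hic_score(m), score_oracle(m))
  }
})

test_that("the true bin order of a decaying matrix scores lower than a swapped order", {
  n <- 4
  a <- outer(1:n, 1:n, function(i, j) 100 / (abs(i - j) + 1))
  swapped <- c(1, 2, 4, 3)
  expect_lt(score_oracle(a), score_oracle(a[swapped, swapped]))
  expect_lt(hic_score(a), hic_score(a[swapped, swapped]))
})

test_that("hic_score is invariant under full reversal of the bin order", {
  set.seed(42)
  for (k in 1:10) {
    n <- sample(3:15, 1)
    m <- matrix(runif(n * n), n)
    m <- m + t(m)
    expect_equal(hic_score(m), hic_score(m[n:1, n:1]))
  }
})

chains_of <- function(...) {
  lapply(list(...), function(ids)
    data.frame(scaffold_id = ids, orientation = "+",
               stringsAsFactors = FALSE))
}

grid_matrix <- function(scaffold_kb, bin_kb = 50) {
  bins <- do.call(rbind, lapply(names(scaffold_kb), function(s) {
    nb <- scaffold_kb[[s]] / bin_kb
    data.frame(scaffold = s, start = (seq_len(nb) - 1) * bin_kb * 1000,
               end = seq_len(nb) * bin_kb * 1000, stringsAsFactors = FALSE)
  }))
  n <- nrow(bins)
  hic_matrix(bins, matrix(1, n, n), balanced = TRUE)
}

test_that("merge groups follow the smallest-scaffold part rule", {
  m <- grid_matrix(c(A = 100, B = 300))
  mg <- make_merge_groups(chains_of("A", "B"), scaffold_set(m$bins), m)
  expect_equal(as.integer(table(mg$part_map$chain)[c("1", "2")]), c(1L, 3L))
  # equal lengths: one part each
  m2 <- grid_matrix(c(A = 200, B = 200))
  mg2 <- make_merge_groups(chains_of("A", "B"), scaffold_set(m2$bins), m2)
  expect_equal(nrow(mg2$part_map), 2)
  # 250 kb at T = 100 kb: round(2.5) = 2 parts
  m3 <- grid_matrix(c(A = 100, B = 250))
  mg3 <- make_merge_groups(chains_of("A", "B"), scaffold_set(m3$bins), m3)
  expect_equal(sum(mg3$part_map$chain == 2), 2)
  # parts are contiguous runs of the chain path covering all retained bins
  expect_equal(sort(unlist(mg3$groups)), seq_len(nrow(m3$bins)))
})

part_matrix <- function(w) {
  n <- nrow(w)
  bins <- data.frame(scaffold = sprintf("p%d", 1:n), start = 0, end = 100)
  hic_matrix(bins, w, balanced = TRUE)
}

test_that("the cutoff is the median of the distance-2 part stratum", {
  # one chain, 4 parts, constant inter-part contacts at d = 2
  w <- matrix(0, 4, 4)
  w[1, 3] <- w[3, 1] <- 7
  w[2, 4] <- w[4, 2] <- 7
  w[1, 2] <- w[2, 1] <- 50
  w[1, 4] <- w[4, 1] <- 2
  pm <- data.frame(part = 1:4, chain = 1, part_index = 1:4)
  expect_equal(as.numeric(estimate_cutoff(part_matrix(w), pm)), 7)

  # strictly decaying contacts: cutoff strictly between d=1 and d=3 medians
  w2 <- outer(1:5, 1:5, function(i, j) 100 / (abs(i - j) + 1)^1.5)
  diag(w2) <- 0
  pm2 <- data.frame(part = 1:5, chain = 1, part_index = 1:5)
  cut2 <- as.numeric(estimate_cutoff(part_matrix(w2), pm2))
  d1 <- median(w2[cbind(1:4, 2:5)])
  d3 <- median(w2[cbind(1:2, 4:5)])
  expect_lt(cut2, d1)
  expect_gt(cut2, d3)

  # only undivided chains: cutoff 0 with a warning
  pm3 <- data.frame(part = 1:4, chain = 1:4, part_index = 1)
  expect_warning(c3 <- estimate_cutoff(part_matrix(w), pm3), "cutoff")
  expect_equal(as.numeric(c3), 0)
})

test_that("edge thresholding removes strictly below the cutoff", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 5
  w[1, 3] <- w[3, 1] <- 3
  w[3, 4] <- w[4, 3] <- 1
  g <- build_scaffold_graph(part_matrix(w), cutoff = 3)
  expect_setequal(g$edges$weight, c(5, 3))
  g0 <- build_scaffold_graph(part_matrix(w), cutoff = 0)
  expect_equal(nrow(g0$edges), 3)
  gmax <- build_scaffold_graph(part_matrix(w), cutoff = 99)
  expect_equal(nrow(gmax$edges), 0)
})

test_that("the maximum spanning forest matches exhaustive enumeration", {
  tri <- structure(list(n_nodes = 3, edges = data.frame(
    from = c(1, 1, 2), to = c(2, 3, 3), weight = c(3, 2, 1))),
    class = "scaffold_graph")
  mst <- max_spanning_tree(tri)
  expect_setequal(mst$edges$weight, c(3, 2))
  set.seed(43)
  for (k in 1:40) {
    n <- sample(4:7, 1)
    edges <- rand_graph(n)
    g <- structure(list(n_nodes = n, edges = edges),
                   class = "scaffold_graph")
    mst <- max_spanning_tree(g)
    expect_equal(sum(mst$edges$weight),
                 spanning_forest_oracle_weight(n, edges))
  }
  # disconnected input: one tree per component
  two <- structure(list(n_nodes = 4, edges = data.frame(
    from = c(1, 3), to = c(2, 4), weight = c(1, 2))),
    class = "scaffold_graph")
  expect_equal(nrow(max_spanning_tree(two)$edges), 2)
})

test_that("hubs keep their two heaviest edges and paths are untouched", {
  star <- structure(list(n_nodes = 4, edges = data.frame(
    from = c(1, 1, 1), to = c(2, 3, 4), weight = c(5, 4, 1))),
    class = "scaffold_graph")
  rh <- resolve_hubs(star, first_iteration = FALSE)
  expect_equal(length(rh$pruned), 0)
  lens <- sort(lengths(rh$chains))
  expect_equal(lens, c(1, 3))  # dropped node 4 becomes a singleton chain

  path <- structure(list(n_nodes = 4, edges = data.frame(
    from = 1:3, to = 2:4, weight = c(1, 2, 3))),
    class = "scaffold_graph")
  rp <- resolve_hubs(path, first_iteration = TRUE)
  expect_equal(length(rp$pruned), 0)
  expect_equal(length(rp$chains), 1)
  expect_equal(sort(rp$chains[[1]]), 1:4)
})

test_that("first-iteration single-node side branches are pruned", {
  # path 1-2-3-4 with leaf 5 hanging off interior node 2
  tree <- structure(list(n_nodes = 5, edges = data.frame(
    from = c(1, 2, 3, 2), to = c(2, 3, 4, 5), weight = c(9, 8, 7, 3))),
    class = "scaffold_graph")
  rh <- resolve_hubs(tree, first_iteration = TRUE)
  # both single-node branches hanging off the hub (the stray leaf 5 and
  # the one-node tail 1) are pruned for later reinsertion
  expect_setequal(rh$pruned, c(1, 5))
  expect_equal(length(rh$chains), 1)
  expect_equal(sort(rh$chains[[1]]), 2:4)
  # outside the first iteration the leaf is kept via the top-two rule
  rh2 <- resolve_hubs(tree, first_iteration = FALSE)
  expect_equal(length(rh2$pruned), 0)
  expect_equal(sum(lengths(rh2$chains)), 5)
})

test_that("pairwise orientation recovers the simulated truth by 4-way scoring", {
  # two scaffolds laid truly as A forward then B reversed
  layout <- data.frame(scaffold_id = c("A", "B"),
                       orientation = c("+", "-"))
  m <- build_true_matrix(c(A = 20, B = 15), layout)
  ss <- scaffold_set(m$bins)
  chains <- chains_of("A", "B")
  joined <- orient_and_join(list(1:2), chains,
                            data.frame(part = 1:2, chain = 1:2,
                                       part_index = 1),
                            m, ss)
  expect_equal(length(joined), 1)
  ch <- joined[[1]]
  # brute-force oracle over the 4 orientation combos
  bins_A <- 1:20; bins_B <- 21:35
  combos <- list(c("+", "+"), c("+", "-"), c("-", "+"), c("-", "-"))
  scores <- vapply(combos, function(o) {
    ba <- if (o[1] == "-") rev(bins_A) else bins_A
    bb <- if (o[2] == "-") rev(bins_B) else bins_B
    ord <- c(ba, bb)
    score_oracle(as.matrix(m$counts)[ord, ord])
  }, numeric(1))
  best <- combos[[which.min(scores)]]
  # result is normalized to first unit forward; compare up to reflection
  got <- paste(ch$scaffold_id, ch$orientation, collapse = " ")
  want1 <- paste(c("A", "B"), best, collapse = " ")
  refl <- paste(c("B", "A"), rev(ifelse(best == "+", "-", "+")),
                collapse = " ")
  expect_true(got %in% c(want1, refl))
  expect_equal(ch$orientation[ch$scaffold_id == "A"], "+")
  expect_equal(ch$orientation[ch$scaffold_id == "B"], "-")
})

test_that("single-unit chains pass through unchanged with forward orientation", {
  m <- grid_matrix(c(A = 100))
  joined <- orient_and_join(list(1), chains_of("A"),
                            data.frame(part = 1, chain = 1, part_index = 1),
                            m, scaffold_set(m$bins))
  expect_equal(joined[[1]]$scaffold_id, "A")
  expect_equal(joined[[1]]$orientation, "+")
})

test_that("greedy orientation agrees with exhaustive on a 5-scaffold chain", {
  set.seed(44)
  ids <- c("A", "B", "C", "D", "E")
  layout <- data.frame(scaffold_id = ids,
                       orientation = sample(c("+", "-"), 5, replace = TRUE))
  nb <- c(A = 12, B = 18, C = 10, D = 15, E = 11)
  m <- build_true_matrix(nb, layout)
  ss <- scaffold_set(m$bins)
  chains <- chains_of("A", "B", "C", "D", "E")
  pm <- data.frame(part = 1:5, chain = 1:5, part_index = 1)
  ex <- orient_and_join(list(1:5), chains, pm, m, ss, max_exhaustive = 8)
  gr <- orient_and_join(list(1:5), chains, pm, m, ss, max_exhaustive = 2)
  expect_equal(ex[[1]], gr[[1]])
  # matches the truth up to global reflection
  truth_fwd <- paste(layout$scaffold_id, layout$orientation,
                     collapse = " ")
  lr <- layout[5:1, ]
  truth_rev <- paste(lr$scaffold_id,
                     ifelse(lr$orientation == "+", "-", "+"),
                     collapse = " ")
  got <- paste(ex[[1]]$scaffold_id, ex[[1]]$orientation, collapse = " ")
  expect_true(got %in% c(truth_fwd, truth_rev))
})

test_that("assembly of simulated chromosomes recovers truth and keeps paths simple", {
  p <- sim_params(n_chromosomes = 1, chromosome_lengths = 5e6,
                  n_contacts = 2.5e6, seed = 45)
  ex <- simulate_hic_experiment(p)
  m <- ice_correct(apply_bin_mask(ex$matrix, mad_filter_bins(ex$matrix)))
  a <- hic_assemble(m)
  ev <- evaluate_assembly(a, ex$truth)
  expect_equal(ev$chain_count, 1)
  expect_equal(ev$adjacency_accuracy, 1.0)
  expect_equal(ev$grouping_purity, 1.0)
  # scaffold/bin path sync: each input scaffold appears exactly once and
  # chain bin paths are valid permutations of the member bins
  ss <- scaffold_set(m$bins)
  ids <- hicscaffold:::assembly_scaffold_ids(a)
  expect_setequal(ids, ss$scaffold_id)
  expect_equal(anyDuplicated(ids), 0L)
  for (ch in a$chains) {
    path <- chain_bins(ch, ss)
    member_bins <- unlist(lapply(match(ch$scaffold_id, ss$scaffold_id),
                                 function(r) ss$first_bin[r]:ss$last_bin[r]))
    expect_setequal(path, member_bins)
  }

  p2 <- sim_params(n_chromosomes = 2, chromosome_lengths = 2.5e6,
                   n_contacts = 2.5e6, seed = 46)
  ex2 <- simulate_hic_experiment(p2)
  m2 <- ice_correct(apply_bin_mask(ex2$matrix, mad_filter_bins(ex2$matrix)))
  a2 <- hic_assemble(m2)
  ev2 <- evaluate_assembly(a2, ex2$truth)
  expect_equal(length(a2$chains), 2)
  expect_equal(ev2$grouping_purity, 1.0)
})

test_that("a single input scaffold is returned unchanged", {
  m <- grid_matrix(c(OnlyOne = 500))
  a <- hic_assemble(m)
  expect_equal(length(a$chains), 1)
  expect_equal(a$chains[[1]]$scaffold_id, "OnlyOne")
  expect_equal(a$chains[[1]]$orientation, "+")
})

test_that("an unbalanced or empty input is rejected", {
  m <- grid_matrix(c(A = 100))
  m$balanced <- FALSE
  expect_error(hic_assemble(m), "balanced")
  m$balanced <- TRUE
  expect_error(hic_assemble(m, min_scaffold_length = 1e9), "set-aside")
})
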