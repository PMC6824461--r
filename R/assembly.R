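#' Partition the current assembly's bins into merge groups
#'
#' Each current Hi-C scaffold (chain of input scaffolds) contributes
#' contiguous, near-equal parts of roughly the size of the smallest current
#' Hi-C scaffold: a chain of length L yields `max(1, round(L / T))` parts,
#' where `T` is the smallest chain length. Only retained bins enter groups.
#'
#' @param chains list of chain data.frames (`scaffold_id`, `orientation`).
#' @param sset a [scaffold_set].
#' @param matrix the working [hic_matrix] (for the retention mask).
#' @param part_length target part length in bp; defaults to the smallest
#'   chain length. The assembly driver passes smaller targets when the
#'   default partition leaves no chain with three or more parts (and hence
#'   no distance-2 stratum for the confidence cutoff).
#' @return list with `groups` (list of bin-index vectors, in chain-path
#'   order), `part_map` (data.frame `part`, `chain`, `part_index`), and
#'   `bin_order` (the concatenated chain bin paths).
#' @export
make_merge_groups <- function(chains, sset, matrix, part_length = NULL) {
  stopifnot(length(chains) >= 1)
  lens <- vapply(chains, function(ch)
    sum(sset$length[match(ch$scaffold_id, sset$scaffold_id)]), numeric(1))
  t_len <- if (is.null(part_length)) min(lens) else part_length
  groups <- list()
  part_chain <- integer()
  part_index <- integer()
  bin_order <- integer()
  for (ci in seq_along(chains)) {
    path <- chain_bins(chains[[ci]], sset, matrix$mask)
    if (length(path) == 0) next
    k <- max(1L, round(lens[ci] / t_len))
    k <- min(k, length(path))
    cut <- ceiling(seq_along(path) * k / length(path))
    gs <- unname(split(path, cut))
    groups <- c(groups, gs)
    part_chain <- c(part_chain, rep(ci, k))
    part_index <- c(part_index, seq_len(k))
    bin_order <- c(bin_order, path)
  }
  list(groups = groups,
       part_map = data.frame(part = seq_along(part_chain),
                             chain = part_chain, part_index = part_index),
       bin_order = bin_order)
}

#' Confidence cutoff from within-chain part distances
#'
#' Collects the corrected contacts between parts of the same divided chain
#' at part-distance 2 (separated by exactly one intervening part, i.e. one
#' scaffold-length apart) and returns their median. Edges weaker than this
#' are not trustworthy evidence of adjacency -- in particular
#' inter-chromosomal background falls below it.
#'
#' @param merged the merged, balanced [hic_matrix] (one bin per part).
#' @param part_map part table from [make_merge_groups()].
#' @return scalar cutoff; 0 with a warning (and `attr(,"ok") = FALSE`) when
#'   no chain is divided into 3 or more parts.
#' @export
estimate_cutoff <- function(merged, part_map) {
  cm <- merged$counts
  vals_by_d <- list()
  for (ci in unique(part_map$chain)) {
    pp <- part_map[part_map$chain == ci, ]
    if (nrow(pp) < 3) next
    pp <- pp[order(pp$part_index), ]
    for (d in 2:(nrow(pp) - 1)) {
      v <- vapply(seq_len(nrow(pp) - d), function(k)
        cm[pp$part[k], pp$part[k + d]], numeric(1))
      key <- as.character(d)
      vals_by_d[[key]] <- c(vals_by_d[[key]], v)
    }
  }
  if (length(vals_by_d) == 0) {
    warning("no Hi-C scaffold divided into >= 3 parts; cutoff set to 0")
    return(structure(0, ok = FALSE))
  }
  stratum <- if (!is.null(vals_by_d[["2"]])) vals_by_d[["2"]] else
    vals_by_d[[as.character(max(as.integer(names(vals_by_d))))]]
  structure(stats::median(stratum), ok = TRUE)
}

#' Build the weighted part graph
#'
#' One node per part; edge weights are the corrected contacts between parts
#' in the merged matrix. Edges strictly below the cutoff are removed; ties
#' at the cutoff are kept. No self-edges.
#'
#' @param merged merged, balanced [hic_matrix].
#' @param cutoff minimum edge weight retained.
#' @return list of class `scaffold_graph` with `n_nodes` and `edges`
#'   (data.frame `from`, `to`, `weight`).
#' @export
build_scaffold_graph <- function(merged, cutoff = 0) {
  tm <- methods::as(Matrix::triu(merged$counts, k = 1), "TsparseMatrix")
  keep <- tm@x > 0 & tm@x >= cutoff
  edges <- data.frame(from = tm@i[keep] + 1L, to = tm@j[keep] + 1L,
                      weight = tm@x[keep])
  structure(list(n_nodes = nrow(merged$bins), edges = edges),
            class = "scaffold_graph")
}

# canonical deterministic edge order: weight desc, then min endpoint id,
# then max endpoint id
edge_order <- function(edges) {
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  order(-edges$weight, a, b)
}

#' Maximum spanning forest
#'
#' Kruskal's algorithm on edges sorted by (weight desc, min node id,
#' max node id), giving a deterministic maximum spanning tree per connected
#' component.
#'
#' @param g a `scaffold_graph`.
#' @return A `scaffold_graph` containing only the forest edges.
#' @export
max_spanning_tree <- function(g) {
  edges <- g$edges[edge_order(g$edges), , drop = FALSE]
  parent <- seq_len(g$n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  take <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$from[k]); rb <- find(edges$to[k])
    if (ra != rb) {
      parent[ra] <- rb
      take[k] <- TRUE
    }
  }
  out <- edges[take, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(n_nodes = g$n_nodes, edges = out),
            class = "scaffold_graph")
}

#' Resolve hubs of a spanning forest into simple chains
#'
#' In the first iteration, side branches containing a single node (a leaf
#' hanging off a node of degree >= 3) are pruned and returned for later
#' reinsertion. Then every node of degree > 2 keeps only its two
#' heaviest incident edges (ties broken deterministically) until the
#' maximum degree is 2, and the remaining forest decomposes into simple
#' chains.
#'
#' @param forest a `scaffold_graph` that is a forest.
#' @param first_iteration prune single-node branches first?
#' @return list with `chains` (list of integer node-id vectors, including
#'   singletons for isolated nodes) and `pruned` (integer node ids).
#' @export
resolve_hubs <- function(forest, first_iteration = FALSE) {
  n <- forest$n_nodes
  edges <- forest$edges
  deg <- function(e) tabulate(c(e$from, e$to), nbins = n)
  pruned <- integer()
  if (first_iteration && nrow(edges) > 0) {
    d <- deg(edges)
    leaf <- which(d == 1)
    for (v in leaf) {
      k <- which(edges$from == v | edges$to == v)
      other <- setdiff(c(edges$from[k], edges$to[k]), v)
      if (d[other] >= 3) pruned <- c(pruned, v)
    }
    if (length(pruned)) {
      drop <- edges$from %in% pruned | edges$to %in% pruned
      edges <- edges[!drop, , drop = FALSE]
    }
  }
  repeat {
    d <- deg(edges)
    hubs <- which(d > 2)
    if (length(hubs) == 0) break
    h <- hubs[1]
    k <- which(edges$from == h | edges$to == h)
    inc <- edges[k, , drop = FALSE]
    keep_local <- edge_order(inc)[1:2]
    edges <- edges[-k[-keep_local], , drop = FALSE]
  }
  # decompose into chains by walking each path from an endpoint
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$from[k]]] <- c(adj[[edges$from[k]]], edges$to[k])
    adj[[edges$to[k]]] <- c(adj[[edges$to[k]]], edges$from[k])
  }
  live <- setdiff(seq_len(n), pruned)
  seen <- rep(FALSE, n)
  chains <- list()
  d <- lengths(adj)
  for (v in live[order(d[live])]) {  # endpoints (deg 0/1) first
    if (seen[v]) next
    path <- v
    seen[v] <- TRUE
    repeat {
      nxt <- setdiff(adj[[path[length(path)]]], path)
      nxt <- nxt[!seen[nxt]]
      if (length(nxt) == 0) break
      path <- c(path, nxt[1])
      seen[nxt[1]] <- TRUE
    }
    chains[[length(chains) + 1]] <- path
  }
  list(chains = chains, pruned = pruned)
}

# Collapse a part-level chain to a sequence of unit (chain) ids:
# consecutive duplicates merge into runs; if a unit recurs in separate
# runs, only its longest run (first on ties) is kept.
collapse_parts <- function(part_ids, part_map) {
  units <- part_map$chain[match(part_ids, part_map$part)]
  r <- rle(units)
  if (anyDuplicated(r$values)) {
    keep <- rep(TRUE, length(r$values))
    for (u in unique(r$values[duplicated(r$values)])) {
      at <- which(r$values == u)
      best <- at[which.max(r$lengths[at])]
      keep[setdiff(at, best)] <- FALSE
    }
    r$values <- r$values[keep]
    r$lengths <- r$lengths[keep]
  }
  r$values
}

# flip a chain: reverse member order and invert orientations
flip_chain <- function(chain) {
  out <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
  out$orientation <- ifelse(out$orientation == "+", "-", "+")
  rownames(out) <- NULL
  out
}

#' Orient and join chained scaffolds
#'
#' For each chain of parts produced by hub resolution, rebuilds the
#' corresponding sequence of current Hi-C scaffolds and chooses the
#' orientation assignment that minimizes the [hic_score()] of the
#' rearranged high-resolution submatrix. Chains of up to `max_exhaustive`
#' units are solved by full `2^k` enumeration; longer chains are solved
#' greedily (first pair exhaustively, then each appended unit tested both
#' ways). The scaffold-level and bin-level paths stay in sync by
#' construction. The winning assignment is reported with the first unit in
#' forward orientation (the global reflection is unidentifiable).
#'
#' @param part_chains list of part-id vectors (from [resolve_hubs()]).
#' @param chains current chain list.
#' @param part_map part table from [make_merge_groups()].
#' @param matrix the working balanced [hic_matrix].
#' @param sset a [scaffold_set].
#' @param max_exhaustive chain size up to which all orientation assignments
#'   are enumerated.
#' @return New list of chains.
#' @export
orient_and_join <- function(part_chains, chains, part_map, matrix, sset,
                            max_exhaustive = 8) {
  used <- sort(unique(part_map$chain[match(unlist(part_chains),
                                           part_map$part)]))
  out <- list()
  for (pc in part_chains) {
    units <- collapse_parts(pc, part_map)
    if (length(units) == 1) {
      out[[length(out) + 1]] <- chains[[units]]
      next
    }
    unit_bins <- lapply(units, function(u)
      chain_bins(chains[[u]], sset, matrix$mask))
    flips <- best_orientation(unit_bins, matrix$counts, max_exhaustive)
    if (flips[1]) {  # normalize: first unit forward
      flips <- rev(!flips)
      units <- rev(units)
    }
    joined <- do.call(rbind, lapply(seq_along(units), function(k) {
      ch <- chains[[units[k]]]
      if (flips[k]) flip_chain(ch) else ch
    }))
    rownames(joined) <- NULL
    out[[length(out) + 1]] <- joined
  }
  # carry over chains whose parts appeared in no chain (none in practice;
  # pruned chains are handled by the caller)
  for (u in setdiff(seq_along(chains), used))
    out[[length(out) + 1]] <- chains[[u]]
  out
}

# Choose per-unit flips minimizing hic_score of the concatenated bin order.
# unit_bins: list of forward bin-index vectors. Returns logical vector.
best_orientation <- function(unit_bins, cm, max_exhaustive = 8) {
  m <- length(unit_bins)
  all_bins <- unlist(unit_bins, use.names = FALSE)
  sub <- as.matrix(cm[all_bins, all_bins, drop = FALSE])
  offs <- cumsum(c(0, lengths(unit_bins)))
  loc <- lapply(seq_len(m), function(k) (offs[k] + 1):offs[k + 1])
  perm_for <- function(flips, upto = length(flips)) {
    unlist(lapply(seq_len(upto), function(k)
      if (flips[k]) rev(loc[[k]]) else loc[[k]]), use.names = FALSE)
  }
  if (m <= max_exhaustive) {
    combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
    scores <- apply(combos, 1, function(fl)
      score_arrangement(sub, perm_for(as.logical(fl))))
    return(as.logical(combos[which.min(scores), ]))
  }
  # greedy: exhaustive on the first pair, then append
  flips <- rep(FALSE, m)
  pair <- as.matrix(expand.grid(c(FALSE, TRUE), c(FALSE, TRUE)))
  sub12 <- sub[c(loc[[1]], loc[[2]]), c(loc[[1]], loc[[2]]), drop = FALSE]
  p12 <- apply(pair, 1, function(fl) {
    f <- c(as.logical(fl), rep(FALSE, m - 2))
    score_arrangement(sub, perm_for(f, 2))
  })
  flips[1:2] <- as.logical(pair[which.min(p12), ])
  for (k in 3:m) {
    s <- vapply(c(FALSE, TRUE), function(fk) {
      f <- flips
      f[k] <- fk
      score_arrangement(sub, perm_for(f, k))
    }, numeric(1))
    flips[k] <- s[2] < s[1]
  }
  flips
}

#' Iterative Hi-C scaffold assembly
#'
#' Runs the iterative ordering/orientation engine on a filtered, balanced
#' contact matrix: per iteration, bins are merged per current Hi-C scaffold
#' ([make_merge_groups()], [merge_bins()]), a confidence cutoff is
#' estimated ([estimate_cutoff()]), the part graph is thresholded and its
#' maximum spanning forest computed, hubs are resolved, and chained
#' scaffolds are oriented and joined by minimizing the [hic_score()].
#' Scaffolds shorter than `min_scaffold_length`, listed in
#' `scaffolds_to_ignore`, or without retained bins are set aside first and
#' reinserted afterwards ([insert_small()]).
#'
#' When no current Hi-C scaffold divides into three or more parts the
#' confidence cutoff cannot be estimated, and the iterative phase stops
#' early rather than making joins that the cutoff cannot vouch for (at that
#' point the flat inter-chromosomal background would otherwise connect
#' chromosomes).
#'
#' @param matrix a filtered, balanced [hic_matrix] (after
#'   [mad_filter_bins()], [apply_bin_mask()], [ice_correct()], and any
#'   [apply_splits()]).
#' @param min_scaffold_length scaffolds shorter than this (bp) are set
#'   aside for post-hoc insertion.
#' @param num_iterations number of join iterations.
#' @param scaffolds_to_ignore scaffold ids excluded from the iterative
#'   phase.
#' @param max_exhaustive see [orient_and_join()].
#' @param snapshot_dir if non-`NULL`, per-iteration merged matrices and
#'   GraphML dumps (before and after the spanning forest) are written here.
#' @return An object of class `hic_assembly`: `chains` (named list of
#'   oriented scaffold chains, longest first), `unplaced_chains`,
#'   `unplaced_originals`, `set_aside`, and a per-iteration `log`.
#' @export
hic_assemble <- function(matrix, min_scaffold_length = 150000,
                         num_iterations = 3,
                         scaffolds_to_ignore = character(),
                         max_exhaustive = 8, snapshot_dir = NULL) {
  if (!matrix$balanced)
    stop("matrix must be balanced; run mad_filter_bins/apply_bin_mask/ice_correct first")
  sset <- scaffold_set(matrix$bins)
  if (nrow(sset) == 0) stop("empty scaffold set")
  n_ret_bins <- vapply(seq_len(nrow(sset)), function(k)
    sum(matrix$mask[sset$first_bin[k]:sset$last_bin[k]]), numeric(1))
  aside <- sset$length < min_scaffold_length |
    sset$scaffold_id %in% scaffolds_to_ignore | n_ret_bins == 0
  set_aside <- sset$scaffold_id[aside]
  work <- sset$scaffold_id[!aside]
  if (length(work) == 0)
    stop("no scaffolds left after set-aside; lower min_scaffold_length")
  chains <- lapply(work, function(s)
    data.frame(scaffold_id = s, orientation = "+", stringsAsFactors = FALSE))
  pruned_ids <- character()
  log <- list()
  for (it in seq_len(num_iterations)) {
    if (length(chains) == 1) break
    t_len <- min(vapply(chains, function(ch)
      sum(sset$length[match(ch$scaffold_id, sset$scaffold_id)]),
      numeric(1)))
    cutoff <- structure(0, ok = FALSE)
    for (scale in c(1, 0.5, 0.25)) {
      mg <- make_merge_groups(chains, sset, matrix,
                              part_length = t_len * scale)
      merged <- suppressWarnings(
        merge_bins(matrix, mg$groups, bin_order = mg$bin_order,
                   balance = TRUE))
      cutoff <- withCallingHandlers(
        estimate_cutoff(merged, mg$part_map),
        warning = function(w) invokeRestart("muffleWarning"))
      if (isTRUE(attr(cutoff, "ok"))) break
    }
    if (!isTRUE(attr(cutoff, "ok"))) {
      log[[length(log) + 1]] <- list(iteration = it, stopped = TRUE,
                                     reason = "cutoff not estimable")
      break
    }
    g <- build_scaffold_graph(merged, cutoff)
    if (!is.null(snapshot_dir))
      write_iteration_snapshots(snapshot_dir, it, merged, g, pre = TRUE)
    forest <- max_spanning_tree(g)
    if (!is.null(snapshot_dir))
      write_iteration_snapshots(snapshot_dir, it, merged, forest, pre = FALSE)
    rh <- resolve_hubs(forest, first_iteration = (it == 1))
    if (it == 1 && length(rh$pruned)) {
      # chains all of whose parts were pruned leave the iterative phase
      gone <- vapply(seq_along(chains), function(ci) {
        pp <- mg$part_map$part[mg$part_map$chain == ci]
        length(pp) > 0 && all(pp %in% rh$pruned)
      }, logical(1))
      pruned_ids <- c(pruned_ids, unlist(lapply(chains[gone],
                                                `[[`, "scaffold_id")))
      keep_map <- mg$part_map$chain %in% which(!gone)
      rh$chains <- lapply(rh$chains, function(pc)
        pc[pc %in% mg$part_map$part[keep_map]])
      rh$chains <- rh$chains[lengths(rh$chains) > 0]
      chains <- chains  # pruned chains dropped below via part chains
    }
    new_chains <- orient_and_join(rh$chains, chains, mg$part_map, matrix,
                                  sset, max_exhaustive)
    if (it == 1 && length(pruned_ids)) {
      new_chains <- Filter(function(ch)
        !all(ch$scaffold_id %in% pruned_ids), new_chains)
    }
    log[[length(log) + 1]] <- list(
      iteration = it, cutoff = as.numeric(cutoff),
      n_parts = nrow(mg$part_map),
      n_edges = nrow(g$edges), n_chains = length(new_chains),
      n_pruned = if (it == 1) length(rh$pruned) else 0L)
    chains <- new_chains
  }
  lens <- vapply(chains, function(ch)
    sum(sset$length[match(ch$scaffold_id, sset$scaffold_id)]), numeric(1))
  chains <- chains[order(-lens)]
  names(chains) <- sprintf("hic_scaffold_%d", seq_along(chains))
  assembly <- structure(list(chains = chains,
                             unplaced_chains = list(),
                             unplaced_originals = character(),
                             set_aside = set_aside,
                             log = log),
                        class = "hic_assembly")
  removed <- unique(c(set_aside, pruned_ids))
  if (length(removed))
    assembly <- insert_small(assembly, removed, matrix, sset,
                             max_exhaustive = max_exhaustive)
  assembly
}

write_iteration_snapshots <- function(dir, it, merged, g, pre) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- if (pre) "pre_mst" else "mst"
  if (pre) {
    write_hic_matrix(merged,
                     file.path(dir, sprintf("iter%02d_merged_bins.tsv", it)),
                     file.path(dir, sprintf("iter%02d_merged_contacts.tsv", it)))
  }
  ig <- igraph::graph_from_data_frame(
    g$edges, directed = FALSE,
    vertices = data.frame(name = seq_len(g$n_nodes)))
  igraph::write_graph(ig, file.path(dir, sprintf("iter%02d_%s.graphml",
                                                 it, tag)),
                      format = "graphml")
  invisible(NULL)
}

#' @export
print.hic_assembly <- function(x, ...) {
  cat(sprintf("hic_assembly: %d Hi-C scaffold(s), %d unplaced chain(s), %d unplaced original(s)\n",
              length(x$chains), length(x$unplaced_chains),
              length(x$unplaced_originals)))
  for (k in seq_along(x$chains)) {
    ch <- x$chains[[k]]
    cat(sprintf("  %s: %s\n", names(x$chains)[k],
                paste0(ch$scaffold_id, ":", ch$orientation, collapse = ",")))
  }
  invisible(x)
}

#' @export
summary.hic_assembly <- function(object, ...) {
  n_members <- vapply(object$chains, nrow, numeric(1))
  cat(sprintf("Hi-C scaffolds: %d (members: %s)\n", length(object$chains),
              paste(n_members, collapse = ", ")))
  cat(sprintf("Unplaced chains: %d; unplaced originals: %d; set aside initially: %d\n",
              length(object$unplaced_chains),
              length(object$unplaced_originals), length(object$set_aside)))
  for (l in object$log) {
    if (isTRUE(l$stopped)) {
      cat(sprintf("  iteration %d: stopped (%s)\n", l$iteration, l$reason))
    } else {
      cat(sprintf("  iteration %d: cutoff %.4g, %d parts, %d edges, %d chains, %d pruned\n",
                  l$iteration, l$cutoff, l$n_parts, l$n_edges, l$n_chains,
                  l$n_pruned))
    }
  }
  invisible(object)
}

# every scaffold id exactly once across the three collections
assembly_scaffold_ids <- function(assembly) {
  c(unlist(lapply(assembly$chains, `[[`, "scaffold_id")),
    unlist(lapply(assembly$unplaced_chains, `[[`, "scaffold_id")),
    assembly$unplaced_originals)
}
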