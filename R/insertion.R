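# scaffold-by-scaffold contact weights: W[s, t] = summed balanced contacts
# between the retained bins of s and t
scaffold_contact_matrix <- function(ids, matrix, sset) {
  rows <- match(ids, sset$scaffold_id)
  n <- nrow(matrix$bins)
  memb <- lapply(rows, function(r) {
    b <- sset$first_bin[r]:sset$last_bin[r]
    b[matrix$mask[b]]
  })
  a <- Matrix::sparseMatrix(
    i = rep(seq_along(ids), lengths(memb)),
    j = unlist(memb, use.names = FALSE), x = 1,
    dims = c(length(ids), n))
  w <- as.matrix(a %*% matrix$counts %*% Matrix::t(a))
  dimnames(w) <- list(ids, ids)
  w
}

# median balanced contact between bin pairs adjacent in the assembled paths
consecutive_bin_median <- function(assembly, matrix, sset) {
  vals <- unlist(lapply(assembly$chains, function(ch) {
    path <- chain_bins(ch, sset, matrix$mask)
    if (length(path) < 2) return(numeric())
    vapply(seq_len(length(path) - 1), function(k)
      matrix$counts[path[k], path[k + 1]], numeric(1))
  }), use.names = FALSE)
  if (length(vals) == 0) 0 else stats::median(vals)
}

#' Reinsert removed scaffolds into the assembled chains
#'
#' Scaffolds set aside before the iterative phase (tiny or ignored
#' scaffolds, first-iteration pruned nodes) are placed back: a
#' scaffold-level contact graph is built in which edges between already
#' joined chain neighbors are pinned at the maximum weight (so the spanning
#' forest can never cut an existing chain) and edges touching a removed
#' scaffold carry their corrected contact weight, thresholded at the median
#' contact of consecutive assembled bins. On the maximum spanning forest,
#' removed scaffolds form branches hanging off chain nodes; each branch is
#' reduced to a path (top-two rule), oriented by [hic_score()], and spliced
#' in next to its anchor -- on the anchor side where the path's far end
#' shares more contacts than the displaced neighbor does. Branches with no
#' anchor become unplaced chains (two or more scaffolds) or unplaced
#' originals (singletons).
#'
#' @param assembly a `hic_assembly` (chains final).
#' @param removed character vector of scaffold ids to insert.
#' @param matrix the working balanced [hic_matrix].
#' @param sset a [scaffold_set].
#' @param max_exhaustive see [orient_and_join()].
#' @return The updated `hic_assembly`.
#' @export
insert_small <- function(assembly, removed, matrix, sset,
                         max_exhaustive = 8) {
  removed <- unique(removed)
  if (length(removed) == 0) return(assembly)
  rows <- match(removed, sset$scaffold_id)
  if (anyNA(rows)) stop("unknown scaffold in removed set")
  n_ret <- vapply(rows, function(r)
    sum(matrix$mask[sset$first_bin[r]:sset$last_bin[r]]), numeric(1))
  no_bins <- removed[n_ret == 0]
  removed <- removed[n_ret > 0]
  assembly$unplaced_originals <- c(assembly$unplaced_originals, no_bins)
  if (length(removed) == 0) return(assembly)

  placed <- unlist(lapply(assembly$chains, `[[`, "scaffold_id"))
  ids <- c(placed, removed)
  w <- scaffold_contact_matrix(ids, matrix, sset)
  cutoff <- consecutive_bin_median(assembly, matrix, sset)
  is_removed <- ids %in% removed

  # candidate edges: removed-touching pairs above cutoff
  edges <- NULL
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  touch <- is_removed[ut[, 1]] | is_removed[ut[, 2]]
  wv <- w[ut]
  keep <- touch & wv >= cutoff
  edges <- data.frame(from = ut[keep, 1], to = ut[keep, 2],
                      weight = wv[keep])
  # pinned chain-neighbor edges
  max_w <- if (nrow(edges) > 0) max(c(edges$weight, w)) else max(c(w, 1))
  pin <- do.call(rbind, lapply(assembly$chains, function(ch) {
    if (nrow(ch) < 2) return(NULL)
    p <- match(ch$scaffold_id, ids)
    data.frame(from = p[-length(p)], to = p[-1], weight = max_w)
  }))
  g <- structure(list(n_nodes = length(ids),
                      edges = rbind(pin, edges)),
                 class = "scaffold_graph")
  mst <- max_spanning_tree(g)

  # components of the removed-only subforest, with their anchor edges
  sub <- mst$edges[is_removed[mst$edges$from] & is_removed[mst$edges$to], ,
                   drop = FALSE]
  anchor_edges <- mst$edges[xor(is_removed[mst$edges$from],
                                is_removed[mst$edges$to]), , drop = FALSE]
  comp <- rep(NA_integer_, length(ids))
  comp[which(is_removed)] <- seq_along(which(is_removed))
  if (nrow(sub) > 0) {
    repeat {
      merged_any <- FALSE
      for (k in seq_len(nrow(sub))) {
        a <- comp[sub$from[k]]; b <- comp[sub$to[k]]
        if (a != b) {
          comp[comp == b] <- a
          merged_any <- TRUE
        }
      }
      if (!merged_any) break
    }
  }

  for (cid in unique(stats::na.omit(comp))) {
    members <- which(!is.na(comp) & comp == cid)
    ae <- anchor_edges[anchor_edges$from %in% members |
                         anchor_edges$to %in% members, , drop = FALSE]
    # local forest over members, reduced to a simple path
    local <- match(members, members)
    le <- sub[sub$from %in% members & sub$to %in% members, , drop = FALSE]
    lg <- structure(list(n_nodes = length(members),
                         edges = data.frame(
                           from = match(le$from, members),
                           to = match(le$to, members),
                           weight = le$weight)),
                    class = "scaffold_graph")
    rh <- resolve_hubs(lg, first_iteration = FALSE)
    paths <- lapply(rh$chains, function(pc) members[pc])
    if (nrow(ae) == 0) {
      for (p in paths) assembly <- add_unplaced(assembly, ids[p], matrix,
                                                sset, max_exhaustive)
      next
    }
    ae <- ae[edge_order(ae)[1], ]
    anchor <- if (is_removed[ae$from]) ae$to else ae$from
    attach <- if (is_removed[ae$from]) ae$from else ae$to
    on_path <- vapply(paths, function(p) attach %in% p, logical(1))
    main <- paths[[which(on_path)[1]]]
    for (p in paths[!seq_along(paths) %in% which(on_path)[1]])
      assembly <- add_unplaced(assembly, ids[p], matrix, sset,
                               max_exhaustive)
    # orient the path to start at the attachment node
    if (main[length(main)] == attach) main <- rev(main)
    if (main[1] != attach) {
      # attachment in the interior: rotate so the nearer end leads
      pos <- which(main == attach)
      if (pos > length(main) / 2) main <- rev(main)
    }
    assembly <- splice_branch(assembly, ids[main], anchor_id = ids[anchor],
                              w = w, matrix = matrix, sset = sset,
                              max_exhaustive = max_exhaustive)
  }
  assembly
}

# orient a free-standing path of scaffolds by hic_score and record it as an
# unplaced chain (or unplaced original if a singleton)
add_unplaced <- function(assembly, path_ids, matrix, sset, max_exhaustive) {
  if (length(path_ids) == 1) {
    assembly$unplaced_originals <- c(assembly$unplaced_originals, path_ids)
    return(assembly)
  }
  unit_bins <- lapply(path_ids, function(s) {
    b <- seq.int(sset$first_bin[match(s, sset$scaffold_id)],
                 sset$last_bin[match(s, sset$scaffold_id)])
    b[matrix$mask[b]]
  })
  flips <- best_orientation(unit_bins, matrix$counts, max_exhaustive)
  if (flips[1]) {
    flips <- rev(!flips)
    path_ids <- rev(path_ids)
  }
  ch <- data.frame(scaffold_id = path_ids,
                   orientation = ifelse(flips, "-", "+"),
                   stringsAsFactors = FALSE)
  assembly$unplaced_chains <- c(assembly$unplaced_chains, list(ch))
  assembly
}

# splice an oriented branch path next to its anchor inside a chain
splice_branch <- function(assembly, path_ids, anchor_id, w, matrix, sset,
                          max_exhaustive) {
  ci <- which(vapply(assembly$chains, function(ch)
    anchor_id %in% ch$scaffold_id, logical(1)))[1]
  chain <- assembly$chains[[ci]]
  pos <- which(chain$scaffold_id == anchor_id)
  far <- path_ids[length(path_ids)]
  side_score <- function(neigh_pos) {
    if (neigh_pos < 1 || neigh_pos > nrow(chain)) return(0)
    v <- chain$scaffold_id[neigh_pos]
    w[far, v] - w[anchor_id, v]
  }
  left <- side_score(pos - 1)
  right <- side_score(pos + 1)
  # orientation: score [anchor, p1..pk] with the anchor fixed as placed
  anchor_row <- chain[pos, , drop = FALSE]
  ctx_bins <- c(list(chain_bins(anchor_row, sset, matrix$mask)),
                lapply(path_ids, function(s) {
                  r <- match(s, sset$scaffold_id)
                  b <- seq.int(sset$first_bin[r], sset$last_bin[r])
                  b[matrix$mask[b]]
                }))
  flips <- best_orientation_fixed_first(ctx_bins, matrix$counts,
                                        max_exhaustive)
  branch <- data.frame(scaffold_id = path_ids,
                       orientation = ifelse(flips[-1], "-", "+"),
                       stringsAsFactors = FALSE)
  if (right >= left) {
    # branch extends rightward from the anchor
    new_chain <- rbind(chain[seq_len(pos), , drop = FALSE], branch,
                       if (pos < nrow(chain))
                         chain[(pos + 1):nrow(chain), , drop = FALSE])
  } else {
    # leftward: mirror the branch
    new_chain <- rbind(if (pos > 1) chain[seq_len(pos - 1), , drop = FALSE],
                       flip_chain(branch),
                       chain[pos:nrow(chain), , drop = FALSE])
  }
  rownames(new_chain) <- NULL
  assembly$chains[[ci]] <- new_chain
  assembly
}

# like best_orientation but the first unit's orientation is fixed forward
best_orientation_fixed_first <- function(unit_bins, cm, max_exhaustive = 8) {
  m <- length(unit_bins)
  if (m == 1) return(FALSE)
  all_bins <- unlist(unit_bins, use.names = FALSE)
  sub <- as.matrix(cm[all_bins, all_bins, drop = FALSE])
  offs <- cumsum(c(0, lengths(unit_bins)))
  loc <- lapply(seq_len(m), function(k) (offs[k] + 1):offs[k + 1])
  perm_for <- function(flips, upto = length(flips)) {
    unlist(lapply(seq_len(upto), function(k)
      if (flips[k]) rev(loc[[k]]) else loc[[k]]), use.names = FALSE)
  }
  if (m - 1 <= max_exhaustive) {
    combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m - 1)))
    scores <- apply(combos, 1, function(fl)
      score_arrangement(sub, perm_for(c(FALSE, as.logical(fl)))))
    return(c(FALSE, as.logical(combos[which.min(scores), ])))
  }
  flips <- rep(FALSE, m)
  for (k in 2:m) {
    s <- vapply(c(FALSE, TRUE), function(fk) {
      f <- flips
      f[k] <- fk
      score_arrangement(sub, perm_for(f, k))
    }, numeric(1))
    flips[k] <- s[2] < s[1]
  }
  flips
}
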