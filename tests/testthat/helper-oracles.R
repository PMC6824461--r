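# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written the slow, obvious way.

# direct double-sum oracle for the distance-weighted contact score
score_oracle <- function(a) {
  a <- as.matrix(a)
  s <- 0
  n <- nrow(a)
  if (n < 2) return(0)
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      s <- s + a[i, j] * (j - i)
  s
}

# exhaustive maximum spanning forest: per connected component, enumerate
# all edge subsets of size (nodes - 1) and keep the heaviest spanning one
spanning_forest_oracle_weight <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- comp[edges$from[k]]; b <- comp[edges$to[k]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  total <- 0
  for (cc in unique(comp)) {
    nodes <- which(comp == cc)
    if (length(nodes) < 2) next
    ek <- which(edges$from %in% nodes & edges$to %in% nodes)
    need <- length(nodes) - 1
    best <- -Inf
    for (sel in utils::combn(ek, need, simplify = FALSE)) {
      sub <- edges[sel, ]
      c2 <- seq_len(n)
      for (k in seq_len(nrow(sub))) {
        a <- c2[sub$from[k]]; b <- c2[sub$to[k]]
        if (a == b) { c2 <- NULL; break }
        c2[c2 == max(a, b)] <- min(a, b)
      }
      if (is.null(c2)) next
      if (length(unique(c2[nodes])) == 1)
        best <- max(best, sum(sub$weight))
    }
    total <- total + best
  }
  total
}

rand_graph <- function(n, p = 0.6, max_edges = 12) {
  all_pairs <- utils::combn(n, 2)
  keep <- which(stats::runif(ncol(all_pairs)) < p)
  if (length(keep) > max_edges) keep <- sort(sample(keep, max_edges))
  data.frame(from = all_pairs[1, keep], to = all_pairs[2, keep],
             weight = round(stats::runif(length(keep), 1, 100), 2))
}

# Deterministic noise-free contact matrix from a true linear layout.
# scaffold_nbins: named vector; layout: data.frame(scaffold_id, orientation)
# giving the true order along one chromosome (or a list of such data.frames,
# one per chromosome). Bin emission order is alphabetical scaffold id, bins
# forward, so the matrix is scrambled relative to the truth.
build_true_matrix <- function(scaffold_nbins, layout, bin_size = 1e4,
                              C = 1e4, trans = 0, alpha = 1) {
  if (is.data.frame(layout)) layout <- list(layout)
  ids <- names(scaffold_nbins)
  pos <- list(); chrom <- list()
  for (ci in seq_along(layout)) {
    cur <- 0
    lay <- layout[[ci]]
    for (k in seq_len(nrow(lay))) {
      s <- lay$scaffold_id[k]
      nb <- scaffold_nbins[[s]]
      p <- cur + (seq_len(nb) - 0.5) * bin_size
      if (lay$orientation[k] == "-") p <- rev(p)
      pos[[s]] <- p
      chrom[[s]] <- ci
      cur <- cur + nb * bin_size
    }
  }
  bins <- do.call(rbind, lapply(sort(ids), function(s)
    data.frame(scaffold = s, start = (seq_len(scaffold_nbins[[s]]) - 1) * bin_size,
               end = seq_len(scaffold_nbins[[s]]) * bin_size,
               stringsAsFactors = FALSE)))
  pvec <- unlist(pos[sort(ids)], use.names = FALSE)
  cvec <- rep(unlist(chrom[sort(ids)]),
              scaffold_nbins[sort(ids)])
  n <- length(pvec)
  d <- abs(outer(pvec, pvec, "-"))
  same <- outer(cvec, cvec, "==")
  m <- matrix(trans, n, n)
  m[same] <- C / (d[same] / bin_size + 1)^alpha
  hic_matrix(bins, m, balanced = TRUE)
}

# --- liftover chain parsing and coordinate mapping (independent of the
# --- package writers; plain interval arithmetic on the UCSC chain spec)
parse_chain_file <- function(path) {
  lines <- readLines(path)
  heads <- grep("^chain ", lines, value = TRUE)
  do.call(rbind, lapply(heads, function(h) {
    f <- strsplit(h, " ")[[1]]
    data.frame(score = as.numeric(f[2]), tName = f[3],
               tSize = as.numeric(f[4]), tStrand = f[5],
               tStart = as.numeric(f[6]), tEnd = as.numeric(f[7]),
               qName = f[8], qSize = as.numeric(f[9]), qStrand = f[10],
               qStart = as.numeric(f[11]), qEnd = as.numeric(f[12]),
               id = as.integer(f[13]), stringsAsFactors = FALSE)
  }))
}

# forward lift: 0-based position on the original scaffold -> (object, pos)
chain_lift <- function(chains, scaffold, pos) {
  rec <- chains[chains$tName == scaffold, ]
  stopifnot(nrow(rec) == 1, pos >= rec$tStart, pos < rec$tEnd)
  if (rec$qStrand == "+") {
    list(object = rec$qName, pos = rec$qStart + (pos - rec$tStart))
  } else {
    q_rc <- rec$qStart + (pos - rec$tStart)
    list(object = rec$qName, pos = rec$qSize - 1 - q_rc)
  }
}

# inverse lift: assembly position -> original scaffold position
chain_lift_back <- function(chains, scaffold, obj_pos) {
  rec <- chains[chains$tName == scaffold, ]
  if (rec$qStrand == "+") {
    rec$tStart + (obj_pos - rec$qStart)
  } else {
    q_rc <- rec$qSize - 1 - obj_pos
    rec$tStart + (q_rc - rec$qStart)
  }
}

read_fasta_plain <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# reconstruct assembly sequences from an AGP file plus input sequences
agp_reconstruct <- function(agp_path, sequences) {
  rows <- utils::read.table(agp_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
  names(rows)[1:9] <- c("object", "beg", "end", "part", "type",
                        "c6", "c7", "c8", "c9")
  out <- list()
  for (o in unique(rows$object)) {
    sub <- rows[rows$object == o, ]
    sub <- sub[order(sub$part), ]
    pieces <- vapply(seq_len(nrow(sub)), function(k) {
      if (sub$type[k] == "U") return(strrep("N", as.numeric(sub$c6[k])))
      s <- sequences[[sub$c6[k]]]
      s <- substr(s, as.numeric(sub$c7[k]), as.numeric(sub$c8[k]))
      if (sub$c9[k] == "-")
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      s
    }, character(1))
    out[[o]] <- paste(pieces, collapse = "")
  }
  out
}

# random assembly + matching random sequences, for writer property tests
random_assembly <- function(n_scaffolds = 6, min_len = 20, max_len = 80) {
  ids <- sprintf("s%02d", seq_len(n_scaffolds))
  lens <- sample(min_len:max_len, n_scaffolds, replace = TRUE)
  seqs <- stats::setNames(vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)), ids)
  shuffled <- sample(ids)
  k1 <- sample(1:(n_scaffolds - 1), 1)
  mk <- function(v) data.frame(
    scaffold_id = v, orientation = sample(c("+", "-"), length(v), TRUE),
    stringsAsFactors = FALSE)
  chains <- list(hic_scaffold_1 = mk(shuffled[1:k1]))
  rest <- shuffled[-(1:k1)]
  unplaced <- character()
  unplaced_chains <- list()
  if (length(rest) >= 2 && stats::runif(1) < 0.5) {
    unplaced_chains <- list(mk(rest))
  } else {
    unplaced <- rest
  }
  assembly <- structure(list(chains = chains,
                             unplaced_chains = unplaced_chains,
                             unplaced_originals = unplaced,
                             set_aside = character(), log = list()),
                        class = "hic_assembly")
  list(assembly = assembly, sequences = seqs,
       lengths = stats::setNames(as.numeric(lens), ids))
}
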