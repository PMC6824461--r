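#' Simulation parameters
#'
#' Study conditions for the synthetic Hi-C generator: a multi-chromosome
#' genome is fragmented into contigs, intra-chromosomal contacts follow a
#' power-law decay with genomic distance with Poisson noise, and
#' inter-chromosomal pairs share a flat background. Defaults describe a
#' small fly-sized test genome at typical Hi-C depth: two 5-Mb
#' chromosomes, 10-kb bins, contigs of 200-700 kb (N50 around half a megabase,
#' as for hybrid short/long-read contig assemblies), 5 million contacts,
#' decay exponent 1 (fractal-globule-like), 5% trans contacts.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_lengths lengths in bp (recycled to `n_chromosomes`).
#' @param bin_size bin width in bp.
#' @param contig_min,contig_max contig length range in bp.
#' @param n_contacts total expected contact count.
#' @param alpha power-law decay exponent.
#' @param d0 decay offset in bp (default: one bin).
#' @param trans_fraction fraction of contacts between chromosomes, in
#'   `[0, 1)`.
#' @param chimera_rate probability that a contig is chimeric (two fragments
#'   from distant loci concatenated).
#' @param seed integer seed; all generator stages derive from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_chromosomes = 2, chromosome_lengths = 5e6,
                       bin_size = 1e4, contig_min = 2e5, contig_max = 7e5,
                       n_contacts = 5e6, alpha = 1, d0 = bin_size,
                       trans_fraction = 0.05, chimera_rate = 0, seed = 1) {
  chromosome_lengths <- rep_len(chromosome_lengths, n_chromosomes)
  stopifnot(n_chromosomes >= 1, all(chromosome_lengths > 0), bin_size > 0,
            contig_min > 0, contig_max >= contig_min, n_contacts > 0,
            alpha > 0, d0 > 0, trans_fraction >= 0, trans_fraction < 1,
            chimera_rate >= 0, chimera_rate <= 1,
            seed >= 0, seed < 2^31 - 10)
  structure(list(n_chromosomes = n_chromosomes,
                 chromosome_lengths = chromosome_lengths,
                 bin_size = bin_size, contig_min = contig_min,
                 contig_max = contig_max, n_contacts = n_contacts,
                 alpha = alpha, d0 = d0, trans_fraction = trans_fraction,
                 chimera_rate = chimera_rate, seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate chromosome sequences
#'
#' Uniform random A/C/G/T per chromosome; deterministic under the seed.
#'
#' @param params a [sim_params].
#' @return A [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
simulate_genome <- function(params) {
  set.seed(params$seed)
  seqs <- vapply(params$chromosome_lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("chr%d", seq_along(seqs))
  out
}

#' Fragment a genome into contigs with ground truth
#'
#' Cuts each chromosome at random points into fragments within the
#' configured length range (a short terminal remainder is merged into the
#' previous fragment). Each fragment is independently strand-flipped with
#' probability 0.5. With probability `chimera_rate` a contig is made
#' chimeric by concatenating its fragment with a random fragment from a
#' different chromosome, recording the junction. Contigs are emitted in
#' shuffled order.
#'
#' @param params a [sim_params].
#' @param sequences optional chromosome [Biostrings::DNAStringSet] from
#'   [simulate_genome()]; when given, contig sequences are returned too.
#' @return list of class `truth_table`: `contigs` (data.frame `contig_id`,
#'   `length`), `segments` (per contig segment: contig-local interval,
#'   source chromosome interval, strand), `junctions` (data.frame
#'   `contig_id`, `position`), and `sequences` (DNAStringSet or `NULL`).
#' @export
fragment_genome <- function(params, sequences = NULL) {
  if (params$contig_min > min(params$chromosome_lengths))
    stop("contig_min exceeds a chromosome length")
  set.seed(params$seed + 1L)
  frags <- list()
  for (ci in seq_len(params$n_chromosomes)) {
    L <- params$chromosome_lengths[ci]
    cuts <- numeric()
    pos <- 0
    repeat {
      step <- round(stats::runif(1, params$contig_min, params$contig_max))
      if (pos + step >= L) break
      pos <- pos + step
      cuts <- c(cuts, pos)
    }
    if (length(cuts) && L - cuts[length(cuts)] < params$contig_min)
      cuts <- cuts[-length(cuts)]  # merge short remainder into last fragment
    starts <- c(0, cuts)
    ends <- c(cuts, L)
    frags[[ci]] <- data.frame(chrom = sprintf("chr%d", ci),
                              start = starts, end = ends,
                              stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, frags)
  frags$strand <- sample(c("+", "-"), nrow(frags), replace = TRUE)
  # chimera pairing over shuffled fragments
  avail <- sample(nrow(frags))
  contigs <- list()
  while (length(avail) > 0) {
    f <- avail[1]
    avail <- avail[-1]
    members <- f
    if (stats::runif(1) < params$chimera_rate) {
      partner <- avail[frags$chrom[avail] != frags$chrom[f]]
      if (length(partner) > 0) {
        g <- partner[sample.int(length(partner), 1)]
        avail <- setdiff(avail, g)
        members <- c(f, g)
      }
    }
    contigs[[length(contigs) + 1]] <- members
  }
  segs <- list()
  juncs <- list()
  for (k in seq_along(contigs)) {
    id <- sprintf("contig_%03d", k)
    mem <- frags[contigs[[k]], , drop = FALSE]
    lens <- mem$end - mem$start
    off <- cumsum(c(0, lens[-length(lens)]))
    segs[[k]] <- data.frame(contig_id = id, seg_start = off,
                            seg_end = off + lens, chrom = mem$chrom,
                            chrom_start = mem$start, chrom_end = mem$end,
                            strand = mem$strand, stringsAsFactors = FALSE)
    if (nrow(mem) > 1)
      juncs[[length(juncs) + 1]] <-
        data.frame(contig_id = id, position = off[-1],
                   stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, segs)
  junctions <- if (length(juncs)) do.call(rbind, juncs) else
    data.frame(contig_id = character(), position = numeric(),
               stringsAsFactors = FALSE)
  ctab <- stats::aggregate(seg_end ~ contig_id, segments, max)
  names(ctab) <- c("contig_id", "length")
  ctab <- ctab[order(match(ctab$contig_id,
                           unique(segments$contig_id))), ]
  rownames(ctab) <- NULL
  cseq <- NULL
  if (!is.null(sequences)) {
    cseq <- Biostrings::DNAStringSet(vapply(
      split(segments, segments$contig_id)[unique(segments$contig_id)],
      function(ss) {
        ss <- ss[order(ss$seg_start), ]
        paste(vapply(seq_len(nrow(ss)), function(i) {
          s <- Biostrings::subseq(sequences[[ss$chrom[i]]],
                                  ss$chrom_start[i] + 1, ss$chrom_end[i])
          if (ss$strand[i] == "-") s <- Biostrings::reverseComplement(s)
          as.character(s)
        }, character(1)), collapse = "")
      }, character(1)))
    names(cseq) <- unique(segments$contig_id)
  }
  structure(list(contigs = ctab, segments = segments,
                 junctions = junctions, sequences = cseq),
            class = "truth_table")
}

# map bin midpoints through the truth embedding to (chromosome, position)
true_bin_positions <- function(bins, truth) {
  seg <- truth$segments
  chrom <- character(nrow(bins))
  pos <- numeric(nrow(bins))
  for (k in seq_len(nrow(bins))) {
    mid <- (bins$start[k] + bins$end[k]) / 2
    ss <- seg[seg$contig_id == bins$scaffold[k] &
                seg$seg_start <= mid & mid < seg$seg_end, , drop = FALSE]
    if (nrow(ss) == 0) stop("bin not covered by truth segments")
    ss <- ss[1, ]
    chrom[k] <- ss$chrom
    local <- mid - ss$seg_start
    pos[k] <- if (ss$strand == "+") ss$chrom_start + local else
      ss$chrom_end - local
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate a Hi-C contact matrix over fragmented contigs
#'
#' Bins are laid over the contigs at the configured bin size (last bin of a
#' contig truncated). For a bin pair at true same-chromosome distance `d`
#' (through the truth embedding, respecting strand flips and chimeric
#' junctions), the expected count is proportional to `(d + d0)^(-alpha)`;
#' inter-chromosomal pairs share a flat rate sized so that trans contacts
#' make up `trans_fraction` of the total. Counts are independent Poisson
#' draws, scaled so the expected total is `n_contacts`.
#'
#' @param truth a `truth_table` from [fragment_genome()].
#' @param params a [sim_params].
#' @return A raw [hic_matrix] over the contigs, in truth emission order.
#' @export
simulate_hic <- function(truth, params) {
  set.seed(params$seed + 2L)
  bs <- params$bin_size
  bins <- do.call(rbind, lapply(seq_len(nrow(truth$contigs)), function(k) {
    L <- truth$contigs$length[k]
    starts <- seq(0, L - 1, by = bs)
    data.frame(scaffold = truth$contigs$contig_id[k], start = starts,
               end = pmin(starts + bs, L), stringsAsFactors = FALSE)
  }))
  tp <- true_bin_positions(bins, truth)
  n <- nrow(bins)
  same <- outer(tp$chrom, tp$chrom, "==")
  d <- abs(outer(tp$pos, tp$pos, "-"))
  lam <- matrix(0, n, n)
  lam[same] <- (d[same] + params$d0)^(-params$alpha)
  up <- upper.tri(lam, diag = TRUE)
  s_cis <- sum(lam[up])
  n_trans <- sum(!same & up)
  tf <- if (n_trans > 0) params$trans_fraction else 0
  lam <- lam * (params$n_contacts * (1 - tf) / s_cis)
  if (n_trans > 0)
    lam[!same] <- params$n_contacts * tf / n_trans
  counts <- matrix(0, n, n)
  counts[up] <- stats::rpois(sum(up), lam[up])
  counts <- counts + t(counts) - diag(diag(counts))
  hic_matrix(bins, counts)
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper chaining [simulate_genome()] (optional),
#' [fragment_genome()] and [simulate_hic()].
#'
#' @param params a [sim_params].
#' @param with_sequences generate and carry nucleotide sequences? (The
#'   truth table and matrix are identical either way.)
#' @return list with `params`, `genome` (DNAStringSet or `NULL`), `truth`
#'   and `matrix`.
#' @export
simulate_hic_experiment <- function(params = sim_params(),
                                    with_sequences = FALSE) {
  genome <- if (with_sequences) simulate_genome(params) else NULL
  truth <- fragment_genome(params, sequences = genome)
  matrix <- simulate_hic(truth, params)
  list(params = params, genome = genome, truth = truth, matrix = matrix)
}

# contig-level truth view: chromosome/offset/strand of the primary
# (longest) segment of each contig
truth_contig_view <- function(truth) {
  do.call(rbind, lapply(split(truth$segments, truth$segments$contig_id),
                        function(ss) {
    best <- ss[which.max(ss$seg_end - ss$seg_start), ]
    data.frame(contig_id = best$contig_id, chrom = best$chrom,
               offset = best$chrom_start, strand = best$strand,
               stringsAsFactors = FALSE)
  }))
}

#' Evaluate an assembly against simulation ground truth
#'
#' Metrics: `adjacency_accuracy` -- fraction of truly adjacent contig pairs
#' placed adjacently with the correct relative orientation;
#' `orientation_accuracy` -- per chain, under the better of the two global
#' reflections, the fraction of contigs with the correct strand (weighted
#' mean over chains); `grouping_purity` -- fraction of co-chained contig
#' pairs sharing a true chromosome; `chain_count` -- total number of output
#' units (placed chains, unplaced chains and unplaced originals). All
#' metrics are invariant to chain reversal and chain order.
#'
#' @param assembly a `hic_assembly`.
#' @param truth a `truth_table`.
#' @return list of metrics.
#' @export
evaluate_assembly <- function(assembly, truth) {
  tv <- truth_contig_view(truth)
  chains <- c(assembly$chains, assembly$unplaced_chains)
  ids <- c(unlist(lapply(chains, `[[`, "scaffold_id")),
           assembly$unplaced_originals)
  unknown <- setdiff(ids, tv$contig_id)
  if (length(unknown))
    stop("contig in assembly but not in truth: ",
         paste(unknown, collapse = ", "))
  # true adjacencies: consecutive contigs along each chromosome
  true_adj <- do.call(rbind, lapply(split(tv, tv$chrom), function(sub) {
    sub <- sub[order(sub$offset), ]
    if (nrow(sub) < 2) return(NULL)
    data.frame(a = sub$contig_id[-nrow(sub)], b = sub$contig_id[-1],
               stringsAsFactors = FALSE)
  }))
  # assembly adjacencies with orientations
  asm_adj <- do.call(rbind, lapply(chains, function(ch) {
    if (nrow(ch) < 2) return(NULL)
    data.frame(x = ch$scaffold_id[-nrow(ch)], y = ch$scaffold_id[-1],
               ox = ch$orientation[-nrow(ch)], oy = ch$orientation[-1],
               stringsAsFactors = FALSE)
  }))
  adj_ok <- 0
  if (!is.null(true_adj)) for (k in seq_len(nrow(true_adj))) {
    a <- true_adj$a[k]; b <- true_adj$b[k]
    ta <- tv$strand[tv$contig_id == a]
    tb <- tv$strand[tv$contig_id == b]
    ok <- FALSE
    if (!is.null(asm_adj)) {
      fwd <- asm_adj[asm_adj$x == a & asm_adj$y == b, , drop = FALSE]
      if (nrow(fwd) && fwd$ox[1] == ta && fwd$oy[1] == tb) ok <- TRUE
      rev_ <- asm_adj[asm_adj$x == b & asm_adj$y == a, , drop = FALSE]
      if (nrow(rev_) && rev_$ox[1] != tb && rev_$oy[1] != ta) ok <- TRUE
    }
    adj_ok <- adj_ok + ok
  }
  adjacency_accuracy <- if (is.null(true_adj)) NA_real_ else
    adj_ok / nrow(true_adj)
  # orientation accuracy, best global reflection per chain
  ori <- vapply(chains, function(ch) {
    t_str <- tv$strand[match(ch$scaffold_id, tv$contig_id)]
    f <- mean(ch$orientation == t_str)
    max(f, 1 - f) * nrow(ch)
  }, numeric(1))
  n_in_chains <- sum(vapply(chains, nrow, numeric(1)))
  orientation_accuracy <- if (n_in_chains > 0) sum(ori) / n_in_chains else
    NA_real_
  # grouping purity over co-chained pairs
  pairs_same <- 0; pairs_all <- 0
  for (ch in chains) {
    if (nrow(ch) < 2) next
    cc <- tv$chrom[match(ch$scaffold_id, tv$contig_id)]
    pr <- utils::combn(cc, 2)
    pairs_all <- pairs_all + ncol(pr)
    pairs_same <- pairs_same + sum(pr[1, ] == pr[2, ])
  }
  grouping_purity <- if (pairs_all > 0) pairs_same / pairs_all else
    NA_real_
  list(adjacency_accuracy = adjacency_accuracy,
       orientation_accuracy = orientation_accuracy,
       grouping_purity = grouping_purity,
       chain_count = length(assembly$chains) +
         length(assembly$unplaced_chains) +
         length(assembly$unplaced_originals))
}
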