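#' Insulation (TAD-separation style) score along each scaffold
#'
#' For every internal bin boundary of a scaffold, the score is the mean
#' balanced contact between the `w` bins upstream and the `w` bins
#' downstream of the boundary, averaged over a range of window sizes.
#' Boundaries where contacts across the junction are depleted -- genuine
#' insulation points, or chimeric joins inside a misassembled scaffold --
#' show up as local minima.
#'
#' Windows truncated by a scaffold end are skipped, so boundaries within
#' `min_depth` bins of an end are unscored. Scores are z-standardized
#' jointly over all scored boundaries; scaffolds with fewer than
#' `min_scored` scored boundaries are too short for a reliable score and
#' are left unscored.
#'
#' @param matrix a balanced [hic_matrix].
#' @param min_depth,max_depth,step window range in bins. Defaults are
#'   derived from the bin size as the equivalent of 15 kb / 50 kb / 2 kb,
#'   floored at 3 / `min_depth` / 1 bins.
#' @param min_scored minimum scored boundaries per scaffold.
#' @return data.frame of class `score_track` with columns `scaffold`,
#'   `bin` (global index of the bin to the right of the boundary),
#'   `raw_score`, `z_score`.
#' @export
separation_score <- function(matrix, min_depth = NULL, max_depth = NULL,
                             step = NULL, min_scored = 10) {
  bs <- stats::median(matrix$bins$end - matrix$bins$start)
  if (is.null(min_depth)) min_depth <- max(3L, round(15000 / bs))
  if (is.null(max_depth)) max_depth <- max(min_depth, round(50000 / bs))
  if (is.null(step)) step <- max(1L, round(2000 / bs))
  if (min_depth > max_depth) stop("min_depth > max_depth")
  windows <- seq.int(min_depth, max_depth, by = step)

  cm <- matrix$counts
  msk <- matrix$mask
  idx <- split(seq_len(nrow(matrix$bins)), matrix$bins$scaffold)
  res <- lapply(names(idx), function(sc) {
    ii <- idx[[sc]]
    nb <- length(ii)
    if (nb < 2) return(NULL)
    rows <- lapply(2:nb, function(b) {
      gb <- ii[b]
      vals <- vapply(windows, function(w) {
        if (b - w < 1 || b + w - 1 > nb) return(NA_real_)
        p <- ii[(b - w):(b - 1)]
        q <- ii[b:(b + w - 1)]
        p <- p[msk[p]]; q <- q[msk[q]]
        if (length(p) == 0 || length(q) == 0) return(NA_real_)
        mean(as.matrix(cm[p, q, drop = FALSE]))
      }, numeric(1))
      if (all(is.na(vals))) return(NULL)
      data.frame(scaffold = sc, bin = gb,
                 raw_score = mean(vals, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out) || nrow(out) < min_scored) return(NULL)
    out
  })
  track <- do.call(rbind, res)
  if (is.null(track))
    track <- data.frame(scaffold = character(), bin = integer(),
                        raw_score = numeric(), stringsAsFactors = FALSE)
  track$z_score <- if (nrow(track) > 1)
    as.numeric(scale(track$raw_score)) else rep(NA_real_, nrow(track))
  class(track) <- c("score_track", "data.frame")
  track
}

#' Call misassembly split positions from a score track
#'
#' A boundary is called when it is a strict local minimum of the raw score
#' within its scaffold and its z-score falls below `z_threshold`.
#'
#' @param track a `score_track` from [separation_score()].
#' @param z_threshold z-score cutoff (boundaries with `z < z_threshold`
#'   qualify).
#' @return data.frame of class `split_plan` with columns `scaffold_id`,
#'   `split_bin` (global index of the first bin of the downstream part),
#'   `source`.
#' @export
find_split_positions <- function(track, z_threshold = -1.0) {
  plans <- lapply(split(seq_len(nrow(track)), track$scaffold), function(ii) {
    sub <- track[ii, ]
    sub <- sub[order(sub$bin), ]
    n <- nrow(sub)
    if (n < 3) return(NULL)
    r <- sub$raw_score
    is_min <- c(FALSE, r[2:(n - 1)] < r[1:(n - 2)] &
                         r[2:(n - 1)] < r[3:n], FALSE)
    hit <- is_min & !is.na(sub$z_score) & sub$z_score < z_threshold
    if (!any(hit)) return(NULL)
    data.frame(scaffold_id = sub$scaffold[hit], split_bin = sub$bin[hit],
               source = "automatic", stringsAsFactors = FALSE)
  })
  plan <- do.call(rbind, plans)
  if (is.null(plan))
    plan <- data.frame(scaffold_id = character(), split_bin = integer(),
                       source = character(), stringsAsFactors = FALSE)
  rownames(plan) <- NULL
  class(plan) <- c("split_plan", "data.frame")
  plan
}

#' Read a manual split-position file
#'
#' TSV of (scaffold_id, position in bp); each position is snapped to the
#' nearest bin boundary of that scaffold (snap distances reported via
#' message).
#'
#' @param path split file path.
#' @param matrix the [hic_matrix] whose bins define the boundaries.
#' @return A `split_plan` data.frame with `source == "manual"`.
#' @export
read_split_file <- function(path, matrix) {
  sp <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("scaffold_id", "position"))
  bins <- matrix$bins
  rows <- lapply(seq_len(nrow(sp)), function(k) {
    ii <- which(bins$scaffold == sp$scaffold_id[k])
    if (length(ii) == 0) stop("split file references unknown scaffold: ",
                              sp$scaffold_id[k])
    starts <- bins$start[ii]
    interior <- ii[starts > 0]
    if (length(interior) == 0)
      stop("scaffold ", sp$scaffold_id[k], " has no interior bin boundary")
    d <- abs(bins$start[interior] - sp$position[k])
    pick <- interior[which.min(d)]
    message(sprintf("split %s:%d snapped to bin boundary at %d (%d bp away)",
                    sp$scaffold_id[k], sp$position[k], bins$start[pick],
                    min(d)))
    data.frame(scaffold_id = sp$scaffold_id[k], split_bin = pick,
               source = "manual", stringsAsFactors = FALSE)
  })
  plan <- do.call(rbind, rows)
  class(plan) <- c("split_plan", "data.frame")
  plan
}

#' Split scaffolds at planned positions
#'
#' Each split scaffold is partitioned at the planned bin boundaries into
#' parts named `<id>/1`, `<id>/2`, ... Matrix entries are untouched; only
#' the bin-to-scaffold binding (and bin-local coordinates) change.
#'
#' @param matrix a [hic_matrix].
#' @param plan a `split_plan`.
#' @return The [hic_matrix] with an updated bin table.
#' @export
apply_splits <- function(matrix, plan) {
  if (nrow(plan) == 0) return(matrix)
  bins <- matrix$bins
  for (sc in unique(plan$scaffold_id)) {
    ii <- which(bins$scaffold == sc)
    if (length(ii) == 0)
      stop("split plan references unknown scaffold: ", sc)
    cuts <- sort(unique(plan$split_bin[plan$scaffold_id == sc]))
    if (any(cuts <= min(ii) | cuts > max(ii)))
      stop("split position outside scaffold ", sc)
    part <- findInterval(ii, cuts) + 1L
    offs <- bins$start[c(min(ii), cuts)]
    bins$scaffold[ii] <- sprintf("%s/%d", sc, part)
    bins$start[ii] <- bins$start[ii] - offs[part]
    bins$end[ii] <- bins$end[ii] - offs[part]
  }
  matrix$bins <- bins
  matrix
}
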