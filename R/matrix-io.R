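#' Hi-C contact matrix container
#'
#' Bundles an ordered bin table with a symmetric sparse matrix of contact
#' counts, a per-bin retention mask, and (after balancing) per-bin correction
#' factors.
#'
#' @param bins data.frame with columns `scaffold`, `start`, `end`.
#'   Coordinates are 0-based half-open base pairs, local to each scaffold.
#'   Bins of one scaffold must be contiguous rows that tile the scaffold
#'   from 0 without gaps or overlap. Row order defines the bin index.
#' @param counts symmetric sparse (or dense) numeric matrix of contact
#'   counts, one row/column per bin. Values must be non-negative.
#' @param mask logical vector, `TRUE` for retained bins.
#' @param reason character vector of removal reasons (`NA` for retained
#'   bins).
#' @param factors per-bin multiplicative correction factors, or `NULL` for a
#'   raw matrix.
#' @param balanced logical; has the matrix been balanced?
#'
#' @return An object of class `hic_matrix`.
#' @export
hic_matrix <- function(bins, counts, mask = NULL, reason = NULL,
                       factors = NULL, balanced = FALSE) {
  bins <- as.data.frame(bins)
  stopifnot(all(c("scaffold", "start", "end") %in% names(bins)))
  n <- nrow(bins)
  validate_bins(bins)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != n || ncol(counts) != n)
    stop("counts dimensions do not match the bin table")
  if (any(counts@x < 0)) stop("negative contact count")
  if (!Matrix::isSymmetric(counts, tol = 1e-8))
    stop("contact matrix must be symmetric")
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (is.null(reason)) reason <- rep(NA_character_, n)
  stopifnot(length(mask) == n, length(reason) == n)
  structure(list(bins = bins, counts = counts, mask = mask,
                 reason = reason, factors = factors, balanced = balanced),
            class = "hic_matrix")
}

validate_bins <- function(bins) {
  if (any(bins$end <= bins$start)) stop("bin with end <= start")
  idx <- split(seq_len(nrow(bins)), bins$scaffold)
  for (ii in idx) {
    if (any(diff(ii) != 1L))
      stop("bins of one scaffold must be contiguous in index order")
    sub <- bins[ii, ]
    if (sub$start[1] != 0) stop("first bin of a scaffold must start at 0")
    if (length(ii) > 1 && any(sub$start[-1] != sub$end[-length(ii)]))
      stop("bins must tile the scaffold without gaps or overlap")
  }
  invisible(TRUE)
}

#' @export
print.hic_matrix <- function(x, ...) {
  cat(sprintf("hic_matrix: %d bins over %d scaffolds (%s)\n",
              nrow(x$bins), length(unique(x$bins$scaffold)),
              if (x$balanced) "balanced" else "raw"))
  cat(sprintf("  retained bins: %d, total contacts: %.6g\n",
              sum(x$mask), sum(x$counts) / 2 + sum(Matrix::diag(x$counts)) / 2))
  invisible(x)
}

#' @export
dim.hic_matrix <- function(x) dim(x$counts)

#' Plot a contact matrix as a heat map
#'
#' Log-scaled image of the (optionally reordered) contact matrix, the
#' standard diagnostic view for scaffolding progress.
#'
#' @param x a [hic_matrix].
#' @param bin_order optional integer vector reordering the bins.
#' @param ... passed to [graphics::image].
#' @export
plot.hic_matrix <- function(x, bin_order = NULL, ...) {
  m <- as.matrix(x$counts)
  if (!is.null(bin_order)) m <- m[bin_order, bin_order, drop = FALSE]
  graphics::image(log10(m + 1), useRaster = TRUE, axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Derive the scaffold inventory from a bin table
#'
#' @param bins bin table of a [hic_matrix] (or the matrix itself).
#' @return data.frame of class `scaffold_set` with columns `scaffold_id`,
#'   `length` (bp), `first_bin`, `last_bin` (1-based bin indices, inclusive).
#' @export
scaffold_set <- function(bins) {
  if (inherits(bins, "hic_matrix")) bins <- bins$bins
  idx <- split(seq_len(nrow(bins)), bins$scaffold)
  out <- data.frame(
    scaffold_id = names(idx),
    length = vapply(idx, function(ii) max(bins$end[ii]), numeric(1)),
    first_bin = vapply(idx, min, numeric(1)),
    last_bin = vapply(idx, max, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$first_bin), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scaffold_set", "data.frame")
  out
}

#' Load a contact matrix from bin-table and triplet files
#'
#' The bin table is a headerless TSV with columns scaffold, start, end,
#' bin_index (0-based), optionally followed by a mask column (0/1) and a
#' correction-factor column. Contacts are a headerless TSV of
#' (i, j, value) triplets with 0-based bin indices; duplicates are summed
#' and lower-triangle entries are folded into the upper triangle.
#'
#' @param bins_path,contacts_path file paths.
#' @return A [hic_matrix].
#' @export
load_hic_matrix <- function(bins_path, contacts_path) {
  bt <- utils::read.table(bins_path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bt) < 4) stop("bin table needs >= 4 columns")
  names(bt)[1:4] <- c("scaffold", "start", "end", "bin_index")
  if (!identical(as.integer(bt$bin_index), seq_len(nrow(bt)) - 1L))
    stop("bin_index must be dense 0..N-1 in file order")
  n <- nrow(bt)
  mask <- if (ncol(bt) >= 5) as.logical(bt[[5]]) else rep(TRUE, n)
  factors <- if (ncol(bt) >= 6) {
    f <- suppressWarnings(as.numeric(bt[[6]]))
    if (all(is.na(f))) NULL else f
  } else NULL

  tp <- tryCatch(
    utils::read.table(contacts_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE,
                      col.names = c("i", "j", "value")),
    error = function(e) data.frame(i = integer(), j = integer(),
                                   value = numeric()))
  if (nrow(tp) > 0) {
    if (any(tp$i < 0 | tp$j < 0 | tp$i >= n | tp$j >= n))
      stop("triplet bin index out of range")
    if (any(tp$value < 0)) stop("negative contact count")
  }
  counts <- triplets_to_symmetric(tp$i, tp$j, tp$value, n)
  hic_matrix(bt[, c("scaffold", "start", "end")], counts,
             mask = mask, factors = factors,
             balanced = !is.null(factors))
}

# Fold (i, j, v) 0-based triplets into a full symmetric dgCMatrix,
# summing duplicates.
triplets_to_symmetric <- function(i, j, v, n) {
  if (length(i) == 0)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  ii <- pmin(i, j) + 1L
  jj <- pmax(i, j) + 1L
  up <- Matrix::sparseMatrix(i = ii, j = jj, x = v, dims = c(n, n))
  full <- up + Matrix::t(up)
  Matrix::diag(full) <- Matrix::diag(up)
  methods::as(methods::as(full, "generalMatrix"), "CsparseMatrix")
}

#' Write a contact matrix to bin-table and triplet files
#'
#' Inverse of [load_hic_matrix()]: bins as TSV (scaffold, start, end,
#' bin_index, mask, factor), contacts as upper-triangle COO TSV sorted by
#' (i, j).
#'
#' @param matrix a [hic_matrix].
#' @param bins_path,contacts_path output paths.
#' @export
write_hic_matrix <- function(matrix, bins_path, contacts_path) {
  bt <- matrix$bins
  out <- data.frame(bt$scaffold, bt$start, bt$end,
                    seq_len(nrow(bt)) - 1L,
                    as.integer(matrix$mask),
                    if (is.null(matrix$factors)) "." else
                      sprintf("%.17g", matrix$factors))
  utils::write.table(out, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tm <- methods::as(Matrix::triu(matrix$counts), "TsparseMatrix")
  ord <- order(tm@i, tm@j)
  df <- data.frame(i = tm@i[ord], j = tm@j[ord],
                   value = sprintf("%.17g", tm@x[ord]))
  df <- df[tm@x[ord] != 0, , drop = FALSE]
  utils::write.table(df, contacts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Bin sequence of a scaffold chain
#'
#' Concatenates the matrix bin indices of the chain members in chain order,
#' reversing the bins of members placed in reverse orientation. This is the
#' bin-level path kept in sync with the scaffold-level path.
#'
#' @param chain data.frame with columns `scaffold_id`, `orientation`
#'   (`"+"`/`"-"`).
#' @param sset a [scaffold_set].
#' @param mask optional logical retention mask; masked bins are dropped.
#' @return integer vector of 1-based bin indices.
#' @export
chain_bins <- function(chain, sset, mask = NULL) {
  rows <- match(chain$scaffold_id, sset$scaffold_id)
  if (anyNA(rows))
    stop("chain references unknown scaffold: ",
         paste(chain$scaffold_id[is.na(rows)], collapse = ", "))
  out <- unlist(lapply(seq_along(rows), function(k) {
    b <- seq.int(sset$first_bin[rows[k]], sset$last_bin[rows[k]])
    if (chain$orientation[k] == "-") rev(b) else b
  }), use.names = FALSE)
  if (!is.null(mask)) out <- out[mask[out]]
  out
}
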