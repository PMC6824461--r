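#' Flag coverage-outlier bins for removal
#'
#' Per-bin coverage is the row sum of raw counts. A bin is removed when its
#' coverage is zero, below a low-coverage cutoff (a quantile of the nonzero
#' coverages), or when its robust z-score exceeds `mad_z_high`. The z-score
#' is (cov - median) / (1.4826 * MAD), computed over nonzero bins; the high
#' cut targets collapsed repeats, which show up as abnormally high coverage.
#'
#' @param matrix a raw [hic_matrix].
#' @param mad_z_high one-sided MAD z-score removal threshold.
#' @param low_count_quantile quantile of nonzero coverages below which bins
#'   are dropped as near-empty. The default is deliberately conservative
#'   (bottom 1 percent): bins flanking scaffold ends and chimeric junctions
#'   legitimately have reduced coverage, and removing them would blind the
#'   misassembly detector exactly where it is needed.
#' @return list of class `bin_mask` with `retained` (logical) and `reason`
#'   (`"zero/low"`, `"high-MAD"`, or `NA`).
#' @export
mad_filter_bins <- function(matrix, mad_z_high = 1.6,
                            low_count_quantile = 0.01) {
  cov <- Matrix::rowSums(matrix$counts)
  nz <- cov > 0
  if (!any(nz)) stop("matrix unusable: all bins have zero coverage")
  med <- stats::median(cov[nz])
  s <- stats::mad(cov[nz])  # 1.4826 consistency constant is mad()'s default
  z <- if (s > 0) (cov - med) / s else ifelse(cov > med, Inf, 0)
  low_cut <- stats::quantile(cov[nz], low_count_quantile, names = FALSE)
  reason <- rep(NA_character_, length(cov))
  reason[z > mad_z_high] <- "high-MAD"
  reason[cov == 0 | cov < low_cut] <- "zero/low"
  retained <- is.na(reason)
  if (!any(retained)) stop("matrix unusable: all bins removed")
  structure(list(retained = retained, reason = reason), class = "bin_mask")
}

#' Apply a bin mask to a contact matrix
#'
#' Rows and columns of removed bins are zeroed; the mask and removal reasons
#' are recorded on the matrix.
#'
#' @param matrix a [hic_matrix].
#' @param mask a `bin_mask` from [mad_filter_bins()] (or a logical vector).
#' @return The masked [hic_matrix].
#' @export
apply_bin_mask <- function(matrix, mask) {
  if (inherits(mask, "bin_mask")) {
    retained <- mask$retained
    matrix$reason <- mask$reason
  } else {
    retained <- as.logical(mask)
    matrix$reason <- ifelse(retained, NA_character_, "masked")
  }
  stopifnot(length(retained) == nrow(matrix$bins))
  d <- Matrix::Diagonal(x = as.numeric(retained))
  matrix$counts <- methods::as(methods::as(d %*% matrix$counts %*% d,
                                           "generalMatrix"), "CsparseMatrix")
  matrix$mask <- retained
  matrix
}

#' Iterative correction (matrix balancing)
#'
#' Multiplicative row/column balancing of the retained submatrix: bins get
#' per-bin factors such that retained row sums become equal. Convergence is
#' declared when the coefficient of variation of the retained row sums drops
#' below `tol`. The balanced matrix is rescaled to conserve the total raw
#' contact mass, and masked bins carry exactly zero rows.
#'
#' @param matrix a masked [hic_matrix] (see [apply_bin_mask()]).
#' @param mask optional logical override of the matrix's own mask.
#' @param tol convergence tolerance on the row-sum coefficient of variation.
#' @param max_iter iteration cap; on non-convergence the best iterate is
#'   returned with a warning and `attr(, "converged") == FALSE`.
#' @return A balanced [hic_matrix] with `factors` filled in.
#' @export
ice_correct <- function(matrix, mask = matrix$mask, tol = 1e-5,
                        max_iter = 200) {
  n <- nrow(matrix$bins)
  retained <- as.logical(mask)
  m <- matrix$counts
  d <- Matrix::Diagonal(x = as.numeric(retained))
  m <- d %*% m %*% d
  rs <- Matrix::rowSums(m)
  if (any(retained & rs == 0))
    stop("retained bin with empty row; filter bins first")
  total_raw <- sum(m)
  b <- rep(1, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    rs <- Matrix::rowSums(m)
    r <- rs[retained]
    cv <- stats::sd(r) / mean(r)
    if (is.finite(cv) && cv < tol) { converged <- TRUE; break }
    f <- rep(1, n)
    f[retained] <- r / mean(r)
    b <- b * f
    di <- Matrix::Diagonal(x = 1 / f)
    m <- di %*% m %*% di
  }
  if (!converged)
    warning(sprintf("iterative correction did not reach tol %.3g in %d iterations",
                    tol, max_iter))
  # conserve total contact mass so balanced values stay on the count scale
  sc <- total_raw / sum(m)
  m <- m * sc
  b <- b / sqrt(sc)
  out <- matrix
  out$counts <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  out$mask <- retained
  out$factors <- ifelse(retained, b, NA_real_)
  out$balanced <- TRUE
  attr(out, "converged") <- converged
  out
}

#' Merge bins into larger groups
#'
#' Sums matrix entries over an ordered partition of (retained) bins. Each
#' group must be a contiguous run of the bin order given by `bin_order`
#' (matrix order by default; pass a chain's bin path for merged assembly
#' matrices). Because groups have variable member counts the merged matrix
#' is re-balanced by default.
#'
#' @param matrix a [hic_matrix].
#' @param groups list of integer vectors of 1-based bin indices; disjoint,
#'   all retained.
#' @param bin_order bin sequence within which each group must be contiguous.
#' @param balance re-balance the merged matrix with [ice_correct()]?
#' @return A [hic_matrix] with one bin per group. Group bin coordinates are
#'   synthetic (one merged "scaffold" per group).
#' @export
merge_bins <- function(matrix, groups, bin_order = seq_len(nrow(matrix$bins)),
                       balance = TRUE) {
  n <- nrow(matrix$bins)
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members)) stop("groups overlap")
  if (any(!matrix$mask[all_members])) stop("group contains a masked bin")
  pos <- match(all_members, bin_order)
  if (anyNA(pos)) stop("group member not in bin_order")
  off <- 0L
  for (g in groups) {
    p <- pos[seq_along(g) + off]
    if (length(p) > 1 && any(diff(sort(p)) != 1L))
      stop("non-contiguous group")
    off <- off + length(g)
  }
  ng <- length(groups)
  a <- Matrix::sparseMatrix(
    i = rep(seq_len(ng), lengths(groups)),
    j = all_members, x = 1, dims = c(ng, n))
  # sum each unordered bin pair once: merged(g,h) = sum of upper-triangle
  # entries with one end in g and the other in h
  mu <- a %*% Matrix::triu(matrix$counts) %*% Matrix::t(a)
  merged <- mu + Matrix::t(mu)
  Matrix::diag(merged) <- Matrix::diag(mu)
  widths <- vapply(groups, function(g)
    sum(matrix$bins$end[g] - matrix$bins$start[g]), numeric(1))
  bins <- data.frame(scaffold = sprintf("part_%04d", seq_len(ng)),
                     start = 0, end = widths, stringsAsFactors = FALSE)
  out <- hic_matrix(bins, merged, balanced = FALSE)
  if (balance) out <- ice_correct(out)
  out
}
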