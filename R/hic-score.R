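#' Distance-weighted off-diagonal contact score
#'
#' For a square symmetric non-negative matrix `a`, computes
#' `sum_{i<j} a[i,j] * (j - i)`: each contact is weighted by its distance
#' from the main diagonal. Bin arrangements that concentrate contacts near
#' the diagonal -- the signature of a correctly ordered and oriented
#' Hi-C submatrix under contact-decay -- score low, so the score is
#' minimized over candidate scaffold orientations.
#'
#' @param a square numeric matrix (dense or sparse).
#' @return scalar score.
#' @export
hic_score <- function(a) {
  a <- as.matrix(a)
  n <- nrow(a)
  if (n != ncol(a)) stop("hic_score needs a square matrix")
  if (n < 2) return(0)
  w <- abs(.row(dim(a)) - .col(dim(a)))
  sum(a * w) / 2
}

# Score a candidate bin arrangement given a precomputed dense submatrix
# `sub` (bins in reference order) and an index permutation into it.
score_arrangement <- function(sub, perm) {
  hic_score(sub[perm, perm, drop = FALSE])
}
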