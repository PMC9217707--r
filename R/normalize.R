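#' Quantile normalization across samples
#'
#' Forces every sample (column) onto the common distribution of rank-wise
#' means: values are sorted within each column, the mean across columns is
#' taken at each rank, and each value is replaced by the mean at its rank.
#' Ties within a column all receive the mean of the rank-means over their
#' tied rank span, so the column sum (and hence the grand mean) is preserved
#' exactly and the map is idempotent.
#'
#' Applied to linear-scale values (e.g. FPKM) before any log transform or
#' ratio computation.
#'
#' @param mat numeric expression matrix (genes x samples), all values finite.
#' @return matrix of the same shape and dimnames with equalized column
#'   distributions.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("quantile_normalize expects a numeric matrix")
  if (any(!is.finite(mat))) stop("matrix contains non-finite values")
  if (ncol(mat) < 2L) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(mat)
  }
  mu <- rowMeans(apply(mat, 2L, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    v <- mu[rank(x, ties.method = "first")]
    # tied values share the mean of the rank-means over their span
    out[, j] <- stats::ave(v, match(x, x), FUN = mean)
  }
  out
}
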