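#' Sample covariance of a gene-by-sample expression matrix
#'
#' Computes the maximum-likelihood sample covariance `(1/n) X_c X_c'` of a
#' genes x samples matrix after centering each gene (row) at zero. With
#' `standardize = TRUE` each gene is additionally scaled to unit standard
#' deviation before the cross-product, so the result is the sample
#' correlation matrix.
#'
#' @param x numeric matrix, genes in rows, samples in columns (`p x n`).
#' @param standardize logical; scale each gene to unit standard deviation
#'   (population sd, `1/n` denominator) before forming the covariance.
#' @param unbiased logical; use the `1/(n-1)` denominator instead of the
#'   maximum-likelihood `1/n`.
#' @return symmetric positive semidefinite `p x p` matrix, with `dimnames`
#'   taken from the row names of `x`.
#' @examples
#' x <- matrix(c(1, 2, -1, -2), nrow = 2)
#' sample_covariance(x)          # [[1,2],[2,4]]
#' @export
sample_covariance <- function(x, standardize = FALSE, unbiased = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (anyNA(x)) stop("expression matrix contains missing values")
  n <- ncol(x)
  if (n < 2L) stop("at least 2 samples are required to form a covariance")
  xc <- x - rowMeans(x)
  if (standardize) {
    sds <- sqrt(rowSums(xc^2) / n)
    bad <- which(sds == 0)
    if (length(bad)) {
      nm <- rownames(x)[bad[1L]]
      if (is.null(nm)) nm <- as.character(bad[1L])
      stop("cannot standardize zero-variance gene: ", nm)
    }
    xc <- xc / sds
  }
  denom <- if (unbiased) n - 1L else n
  s <- tcrossprod(xc) / denom
  s <- (s + t(s)) / 2
  if (!is.null(rownames(x))) dimnames(s) <- list(rownames(x), rownames(x))
  s
}

#' Per-state sample covariances
#'
#' @param x list of genes x samples matrices (one per state) sharing the
#'   same gene order.
#' @inheritParams sample_covariance
#' @return list with elements `S` (list of covariance matrices) and `n`
#'   (integer vector of per-state sample sizes).
#' @export
sample_covariances <- function(x, standardize = FALSE, unbiased = FALSE) {
  x <- as_state_list(x)
  p <- nrow(x[[1L]])
  for (k in seq_along(x)) {
    if (nrow(x[[k]]) != p) stop("all states must share the same gene count")
  }
  list(
    S = lapply(x, sample_covariance, standardize = standardize, unbiased = unbiased),
    n = vapply(x, ncol, integer(1L))
  )
}

# Accept a single matrix (K = 1) or a list of matrices.
as_state_list <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) x <- list(as.matrix(x))
  if (!is.list(x) || !length(x)) stop("x must be a matrix or a non-empty list of matrices")
  lapply(x, as.matrix)
}
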