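#' Canonicalize a pathway collection
#'
#' Pathways are represented as a list of integer vectors of gene indices
#' (1-based, indexing into the shared gene vector). Normalization sorts and
#' deduplicates each set, drops duplicated sets, and appends every gene not
#' covered by any pathway as a singleton pathway so that the collection
#' partitions responsibility for all `p` genes (a singleton gene keeps only
#' its diagonal entry in the support mask).
#'
#' @param pathways list of integer vectors (or a single vector) of gene
#'   indices in `1:p`; names are preserved where present.
#' @param p total number of genes.
#' @return list of sorted integer vectors whose union is `1:p`.
#' @export
normalize_pathways <- function(pathways, p) {
  if (is.numeric(pathways)) pathways <- list(pathways)
  if (!is.list(pathways)) stop("pathways must be a list of index vectors")
  p <- as.integer(p)
  if (!length(pathways) && p > 0L) {
    warning("empty pathway collection: using one singleton pathway per gene")
    pathways <- list()
  }
  sets <- lapply(pathways, function(s) {
    s <- as.integer(s)
    if (!length(s)) stop("pathways must be non-empty")
    if (anyDuplicated(s)) s <- unique(s)
    if (any(s < 1L | s > p)) stop("pathway index out of range [1, ", p, "]")
    sort(s)
  })
  if (length(sets)) {
    keys <- vapply(sets, paste, character(1L), collapse = ",")
    keep <- !duplicated(keys)
    sets <- sets[keep]
  }
  covered <- logical(p)
  for (s in sets) covered[s] <- TRUE
  singletons <- which(!covered)
  c(sets, lapply(singletons, identity))
}

#' Pathway co-occurrence support mask
#'
#' Builds the binary symmetric `p x p` matrix `Q` with `Q[i, j] = 1` iff
#' `i == j` or genes `i` and `j` co-occur in at least one pathway. Precision
#' entries outside `Q` are structural zeros of the model.
#'
#' @param pathways list of integer index vectors (see [normalize_pathways()]).
#' @param p total number of genes.
#' @return binary symmetric `p x p` matrix with unit diagonal.
#' @examples
#' support_mask(list(c(1, 2), c(2, 3)), 3)
#' @export
support_mask <- function(pathways, p) {
  if (is.numeric(pathways)) pathways <- list(pathways)
  p <- as.integer(p)
  q <- diag(1, p)
  for (s in pathways) {
    s <- as.integer(s)
    if (any(s < 1L | s > p)) stop("pathway index out of range [1, ", p, "]")
    q[s, s] <- 1
  }
  q
}

#' Per-pathway block views for the pathway-separable updates
#'
#' For each pathway `t` the precision matrix can be permuted so that the
#' pathway block, its overlap with other pathways, and the rest form a
#' 3 x 3 block-arrow structure; the likelihood update of the pathway block
#' then depends on the rest of the matrix only through a Schur-complement
#' correction supported on the overlap rows/columns. This helper records,
#' per pathway: the member indices, the complement, and which member genes
#' are allowed (by `Q`) to connect to complement genes.
#'
#' @param pathways normalized pathway collection.
#' @param Q support mask from [support_mask()].
#' @return list of views; each has `inside`, `outside`, `overlap` (positions
#'   within `inside`).
#' @export
pathway_blocks <- function(pathways, Q) {
  p <- nrow(Q)
  lapply(pathways, function(s) {
    inside <- sort(as.integer(s))
    outside <- setdiff(seq_len(p), inside)
    overlap <- if (length(outside)) {
      which(rowSums(Q[inside, outside, drop = FALSE] != 0) > 0)
    } else {
      integer(0)
    }
    list(inside = inside, outside = outside, overlap = overlap)
  })
}

#' Schur-complement correction for one pathway block
#'
#' Computes `Delta_t = B A^{-1} B'`, where `A` is the block of `Theta` on
#' the genes outside pathway `t` and `B` the inside x outside block. Rows
#' and columns of `Delta_t` for genes with no allowed outside connection are
#' structurally zero, so the linear solve is restricted to the overlap rows.
#' `A` is factorized by Cholesky; no matrix larger than the outside block is
#' ever inverted.
#'
#' @param theta symmetric positive definite `p x p` matrix respecting the
#'   support mask.
#' @param view one element of [pathway_blocks()].
#' @param t pathway index, used only in error messages.
#' @return symmetric positive semidefinite `p_t x p_t` matrix.
#' @export
compute_delta <- function(theta, view, t = NA_integer_) {
  inside <- view$inside
  pt <- length(inside)
  delta <- matrix(0, pt, pt)
  if (!length(view$outside) || !length(view$overlap)) return(delta)
  b <- theta[inside[view$overlap], view$outside, drop = FALSE]
  a <- theta[view$outside, view$outside, drop = FALSE]
  r <- tryCatch(chol(a), error = function(e) {
    stop("outside block of pathway ", t, " is singular or not positive definite")
  })
  # w = R^{-T} B' so that Delta_ov = B A^{-1} B' = w'w (symmetric PSD)
  w <- backsolve(r, t(b), transpose = TRUE)
  dov <- crossprod(w)
  delta[view$overlap, view$overlap] <- (dov + t(dov)) / 2
  delta
}
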