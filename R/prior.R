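#' Prior gene-interaction adjacency matrix
#'
#' Coerces an edge list (two-column matrix/data.frame of gene indices or
#' gene identifiers) or a square adjacency matrix into the canonical binary
#' symmetric adjacency `G` with zero diagonal. Duplicate and reversed
#' duplicate edges collapse; self-loops are dropped.
#'
#' @param edges two-column object of edges, or a `p x p` adjacency matrix.
#' @param p number of genes (required for an index edge list).
#' @param gene_ids optional character vector mapping identifiers to indices.
#' @return binary symmetric `p x p` matrix with zero diagonal.
#' @export
prior_network <- function(edges, p = NULL, gene_ids = NULL) {
  if (is.matrix(edges) && nrow(edges) == ncol(edges) && nrow(edges) != 2L &&
      (is.null(p) || nrow(edges) == p)) {
    g <- (edges != 0) * 1
    g <- pmax(g, t(g))
    diag(g) <- 0
    return(g)
  }
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) < 2L) stop("edge list must have two columns")
  if (is.character(edges)) {
    if (is.null(gene_ids)) stop("gene_ids required to resolve a character edge list")
    i <- match(edges[, 1L], gene_ids)
    j <- match(edges[, 2L], gene_ids)
    drop <- is.na(i) | is.na(j)
    i <- i[!drop]; j <- j[!drop]
    p <- length(gene_ids)
  } else {
    if (is.null(p)) stop("p required for an index edge list")
    i <- as.integer(edges[, 1L])
    j <- as.integer(edges[, 2L])
  }
  g <- matrix(0, p, p)
  keep <- which(i != j)
  g[cbind(i[keep], j[keep])] <- 1
  g <- pmax(g, t(g))
  if (!is.null(gene_ids)) dimnames(g) <- list(gene_ids, gene_ids)
  g
}

#' Penalty weight matrix from a prior network
#'
#' Known interactions are penalized less: `W[i, j] = w` where `G[i, j] = 1`
#' and `1` elsewhere, with `w` in `[0, 1]`. Smaller `w` makes a prior edge
#' (and changes on it across states) easier to detect; `w = 1` disables the
#' prior and `w = 0` exempts prior edges from both penalties entirely. The
#' diagonal is fixed at 1.
#'
#' @param G binary symmetric adjacency from [prior_network()] (or `NULL` for
#'   no prior: all weights 1).
#' @param w prior weight in `[0, 1]`; default 0.3.
#' @param p number of genes (needed when `G` is `NULL`).
#' @return symmetric `p x p` matrix with entries in `{w, 1}`.
#' @export
weight_matrix <- function(G, w = 0.3, p = NULL) {
  if (length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    stop("w must be a single value in [0, 1]")
  }
  if (is.null(G)) {
    if (is.null(p)) stop("p required when G is NULL")
    return(matrix(1, p, p))
  }
  G <- as.matrix(G)
  if (any(G != t(G))) stop("G must be symmetric")
  W <- matrix(1, nrow(G), ncol(G))
  W[G != 0] <- w
  diag(W) <- 1
  dimnames(W) <- dimnames(G)
  W
}
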