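#' Binarize an estimated network
#'
#' @param network symmetric matrix.
#' @param tol entries with `|value| > tol` become edges (default `1e-8`; the
#'   fitted networks carry exact zeros, so any tiny tolerance agrees).
#' @return binary adjacency with zero diagonal.
#' @export
binarize_network <- function(network, tol = 1e-8) {
  b <- (abs(network) > tol) * 1
  diag(b) <- 0
  b
}

#' Recovery metrics for individual and differential networks
#'
#' Computes, over the upper triangle (`i < j`) and all states `k` (and all
#' state pairs `k < k'` for the differential metrics):
#' * TPR — estimated edges among true edges / true edges;
#' * FPR — estimated edges among true non-edges / true non-edges;
#' * TPDR — detected differences among truly differing entries / truly
#'   differing entries;
#' * FPDR — detected differences among truly equal entries / truly equal
#'   entries.
#' Truth entries are compared exactly (the generator produces exact copies
#' and exact zeros); estimated entries use `|.| > tol` for presence and
#' `|difference| > tol` for inequality.
#'
#' @param truth list of K true (weighted) precision or network matrices.
#' @param estimates list of K estimated networks.
#' @param tol numeric tolerance for the estimates.
#' @return list of class `wfpgl_metrics` with the four rates and the
#'   integer counts behind each ratio.
#' @export
network_metrics <- function(truth, estimates, tol = 1e-8) {
  if (is.matrix(truth)) truth <- list(truth)
  if (is.matrix(estimates)) estimates <- list(estimates)
  K <- length(truth)
  if (length(estimates) != K) stop("truth and estimates must have the same length")
  p <- nrow(truth[[1L]])
  ut <- upper.tri(truth[[1L]])
  tp <- fp <- pos <- neg <- 0L
  for (k in seq_len(K)) {
    te <- truth[[k]][ut] != 0
    ee <- abs(estimates[[k]][ut]) > tol
    tp <- tp + sum(ee & te); pos <- pos + sum(te)
    fp <- fp + sum(ee & !te); neg <- neg + sum(!te)
  }
  out <- list(
    tpr = tp / pos, fpr = fp / neg,
    counts = list(tp = tp, true_edges = pos, fp = fp, true_nonedges = neg)
  )
  if (K >= 2L) {
    td <- fd <- dpos <- dneg <- 0L
    pr <- utils::combn(K, 2L)
    for (q in seq_len(ncol(pr))) {
      k1 <- pr[1L, q]; k2 <- pr[2L, q]
      tdiff <- truth[[k1]][ut] != truth[[k2]][ut]
      ediff <- abs(estimates[[k1]][ut] - estimates[[k2]][ut]) > tol
      td <- td + sum(ediff & tdiff); dpos <- dpos + sum(tdiff)
      fd <- fd + sum(ediff & !tdiff); dneg <- dneg + sum(!tdiff)
    }
    out$tpdr <- td / dpos
    out$fpdr <- fd / dneg
    out$counts <- c(out$counts, list(
      td = td, true_differential = dpos, fd = fd, true_equal = dneg
    ))
  }
  class(out) <- "wfpgl_metrics"
  out
}

#' @export
print.wfpgl_metrics <- function(x, ...) {
  cat(sprintf("TPR  = %.4f (%d / %d)\n", x$tpr,
              x$counts$tp, x$counts$true_edges))
  cat(sprintf("FPR  = %.4f (%d / %d)\n", x$fpr,
              x$counts$fp, x$counts$true_nonedges))
  if (!is.null(x$tpdr)) {
    cat(sprintf("TPDR = %.4f (%d / %d)\n", x$tpdr,
                x$counts$td, x$counts$true_differential))
    cat(sprintf("FPDR = %.4f (%d / %d)\n", x$fpdr,
                x$counts$fd, x$counts$true_equal))
  }
  invisible(x)
}

#' Differential edges between two estimated networks
#'
#' @param est_a,est_b symmetric matrices of the same size.
#' @param tol report pairs `i < j` with `|a_ij - b_ij| > tol`.
#' @param gene_ids optional identifiers used in the output.
#' @return data.frame with columns `gene_a`, `gene_b`, `difference`
#'   (signed `a_ij - b_ij`), sorted by decreasing absolute difference.
#' @export
differential_edges <- function(est_a, est_b, tol = 1e-8, gene_ids = NULL) {
  if (!all(dim(est_a) == dim(est_b))) stop("matrices must share dimensions")
  d <- est_a - est_b
  idx <- which(upper.tri(d) & abs(d) > tol)
  ij <- arrayInd(idx, dim(d))
  ids <- if (is.null(gene_ids)) {
    rn <- rownames(est_a)
    if (is.null(rn)) as.character(seq_len(nrow(d))) else rn
  } else gene_ids
  out <- data.frame(
    gene_a = ids[ij[, 1L]], gene_b = ids[ij[, 2L]],
    difference = d[idx], stringsAsFactors = FALSE
  )
  out[order(-abs(out$difference), out$gene_a, out$gene_b), , drop = FALSE]
}

#' AIC of a set of estimated precision matrices
#'
#' `AIC = sum_k [ n_k tr(S^(k) Theta^(k)) - n_k log det(Theta^(k)) + 2 n_e^(k) ]`,
#' where `n_e^(k)` counts the nonzero parameters of state k. By default the
#' count is the nonzero upper-triangle off-diagonal entries (edges), so the
#' complexity term is twice the edge count; `count_mode` exposes
#' alternatives. Non-positive-definite estimates get `+Inf`.
#'
#' @param S list of sample covariances.
#' @param estimates list of estimated precision matrices (positive definite
#'   for a finite value).
#' @param n per-state sample sizes.
#' @param tol nonzero tolerance for the parameter count.
#' @param count_mode `"edges"` (upper-triangle off-diagonal), `"offdiag"`
#'   (both triangles) or `"all"` (including the diagonal).
#' @param sparsity optional list of matrices whose support is used for the
#'   parameter count instead of `estimates` (e.g. the exactly sparse Z
#'   networks while `estimates` are the positive definite Theta iterates).
#' @return scalar AIC value.
#' @export
wfpgl_aic <- function(S, estimates, n, tol = 1e-8, count_mode = c("edges", "offdiag", "all"),
                      sparsity = NULL) {
  count_mode <- match.arg(count_mode)
  if (is.matrix(S)) S <- list(S)
  if (is.matrix(estimates)) estimates <- list(estimates)
  if (is.null(sparsity)) sparsity <- estimates
  if (is.matrix(sparsity)) sparsity <- list(sparsity)
  total <- 0
  for (k in seq_along(estimates)) {
    th <- estimates[[k]]
    ld <- determinant(th, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    ev_ok <- tryCatch({ chol(th); TRUE }, error = function(e) FALSE)
    if (!ev_ok) return(Inf)
    sp <- sparsity[[k]]
    ne <- switch(count_mode,
      edges = sum(abs(sp[upper.tri(sp)]) > tol),
      offdiag = sum(abs(sp) > tol) - sum(abs(diag(sp)) > tol),
      all = sum(abs(sp) > tol)
    )
    total <- total + n[k] * sum(S[[k]] * th) - n[k] * as.numeric(ld$modulus) + 2 * ne
  }
  total
}

#' Select tuning parameters by AIC over a grid
#'
#' Fits the model at every `(lambda1, lambda2)` pair, evaluates [wfpgl_aic()]
#' on the positive definite Theta iterate with the parameter count taken
#' from the exactly sparse Z networks, and returns the full table together
#' with the argmin fit. Ties break toward the smallest `lambda1`, then the
#' smallest `lambda2`; failed fits are recorded with `NA` and excluded.
#'
#' @inheritParams wfpgl
#' @param lambda1_grid,lambda2_grid numeric grids (non-empty).
#' @param ... further arguments passed to [wfpgl()].
#' @return list of class `wfpgl_select`: `table` (data.frame of
#'   `lambda1`, `lambda2`, `aic`), `best` (the argmin `wfpgl` fit),
#'   `lambda1`, `lambda2`.
#' @export
wfpgl_select <- function(x, lambda1_grid, lambda2_grid = 0,
                         pathways = NULL, prior = NULL, w = 0.3, ...) {
  if (!length(lambda1_grid) || !length(lambda2_grid)) stop("grids must be non-empty")
  lambda1_grid <- sort(lambda1_grid)
  lambda2_grid <- sort(lambda2_grid)
  grid <- expand.grid(lambda1 = lambda1_grid, lambda2 = lambda2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$lambda1, grid$lambda2), , drop = FALSE]
  aics <- rep(NA_real_, nrow(grid))
  best <- NULL
  best_aic <- Inf
  for (r in seq_len(nrow(grid))) {
    fit <- tryCatch(
      wfpgl(x, pathways = pathways, prior = prior,
            lambda1 = grid$lambda1[r], lambda2 = grid$lambda2[r], w = w, ...),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    aics[r] <- wfpgl_aic(fit$S, fit$theta, fit$n, sparsity = fit$networks)
    if (is.finite(aics[r]) && aics[r] < best_aic) {
      best_aic <- aics[r]
      best <- fit
    }
  }
  structure(list(
    table = cbind(grid, aic = aics),
    best = best,
    lambda1 = if (is.null(best)) NA_real_ else best$lambda1,
    lambda2 = if (is.null(best)) NA_real_ else best$lambda2
  ), class = "wfpgl_select")
}

#' @export
print.wfpgl_select <- function(x, ...) {
  cat(sprintf("AIC selection over %d grid points\n", nrow(x$table)))
  cat(sprintf("  selected lambda1 = %g, lambda2 = %g (AIC = %.2f)\n",
              x$lambda1, x$lambda2, min(x$table$aic, na.rm = TRUE)))
  invisible(x)
}

#' Rank hub genes by degree
#'
#' @param network adjacency or weighted symmetric matrix (nonzero = edge).
#' @param gene_ids identifiers (defaults to row names).
#' @param top_m number of genes to return.
#' @return data.frame with `gene` and `degree`, degree descending with
#'   lexicographic tie-break on the identifier.
#' @export
hub_ranking <- function(network, gene_ids = NULL, top_m = 10L) {
  adj <- binarize_network(network, tol = 0)
  if (is.null(gene_ids)) {
    gene_ids <- rownames(network)
    if (is.null(gene_ids)) gene_ids <- as.character(seq_len(nrow(network)))
  }
  deg <- rowSums(adj)
  ord <- order(-deg, gene_ids)
  take <- ord[seq_len(min(top_m, length(ord)))]
  data.frame(gene = gene_ids[take], degree = as.integer(deg[take]),
             row.names = NULL, stringsAsFactors = FALSE)
}
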