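#' Control parameters for the WFPGL optimizer
#'
#' @param mu ADMM penalty parameter (> 0); fixed throughout the run.
#' @param max_iter maximum number of ADMM iterations.
#' @param tol relative squared-Frobenius change below which the algorithm
#'   stops (see [has_converged()]).
#' @param debug verify, at every iteration, that each precision iterate is
#'   symmetric positive definite (Cholesky) and exactly zero outside the
#'   support mask; intended for small problems.
#' @return list of class `wfpgl_control`.
#' @export
wfpgl_control <- function(mu = 1, max_iter = 500L, tol = 1e-5, debug = FALSE) {
  stopifnot(mu > 0, max_iter >= 1L, tol > 0)
  structure(list(mu = mu, max_iter = as.integer(max_iter), tol = tol,
                 debug = debug), class = "wfpgl_control")
}

#' Weighted fused pathway graphical lasso
#'
#' Jointly estimates K state-specific gene networks (sparse precision
#' matrices) from expression data by maximizing the penalized multi-state
#' Gaussian log-likelihood
#' \deqn{\sum_k n_k[\log\det\Theta^{(k)} - \mathrm{tr}(S^{(k)}\Theta^{(k)})]
#'  - \lambda_1\sum_k\sum_{i\ne j} W_{ij}|\theta^{(k)}_{ij}|
#'  - \lambda_2\sum_{k<k'}\sum_{i,j} W_{ij}|\theta^{(k)}_{ij}-\theta^{(k')}_{ij}|}
#' subject to \eqn{\theta^{(k)}_{ij} = 0} whenever genes i and j do not
#' co-occur in any pathway. `W` down-weights the penalties on known prior
#' interactions (`W_ij = w` on prior edges, 1 elsewhere). Optimization is by
#' ADMM with pathway-separable closed-form block updates; the returned
#' networks are the proximal (Z) iterates, which carry exact zeros and exact
#' cross-state ties.
#'
#' @param x list of K genes x samples expression matrices (shared gene
#'   order), or a single matrix for K = 1. Alternatively the output of
#'   [sample_covariances()] may be passed via `S`/`n` (leave `x` missing).
#' @param pathways list of pathway membership vectors (gene indices in
#'   `1:p`, or gene identifiers when the matrices have row names). `NULL`
#'   treats all genes as one pathway (no structural constraint).
#' @param prior prior-interaction edge list or adjacency matrix (see
#'   [prior_network()]); `NULL` for no prior.
#' @param lambda1 sparsity tuning parameter (>= 0).
#' @param lambda2 fusion tuning parameter (>= 0).
#' @param w prior weight in `[0, 1]` (default 0.3).
#' @param standardize standardize genes to zero mean, unit variance before
#'   forming covariances (recommended for real expression data).
#' @param S,n optional precomputed list of sample covariances and vector of
#'   sample sizes, used instead of `x`.
#' @param control a [wfpgl_control()] list.
#' @return object of class `wfpgl` with components `networks` (list of K
#'   sparse symmetric matrices), `theta` (positive definite likelihood
#'   iterates), `iterations`, `converged`, `rel_change` (trace),
#'   `gene_ids`, and the call/configuration.
#' @examples
#' sc <- wfpgl_scenario("two_state", p = 30, n = 60, J = 3, seed = 1)
#' fit <- wfpgl(sc$x, pathways = sc$pathways, prior = sc$prior,
#'              lambda1 = 8, lambda2 = 0.01)
#' fit
#' @export
wfpgl <- function(x, pathways = NULL, prior = NULL,
                  lambda1, lambda2 = 0, w = 0.3,
                  standardize = FALSE, S = NULL, n = NULL,
                  control = wfpgl_control()) {
  cl <- match.call()
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be >= 0")
  if (is.null(S)) {
    cov <- sample_covariances(x, standardize = standardize)
    S <- cov$S
    n <- cov$n
  } else {
    if (is.null(n)) stop("n must accompany a precomputed S")
    S <- lapply(S, function(m) (as.matrix(m) + t(as.matrix(m))) / 2)
    n <- as.numeric(n)
  }
  if (length(S) != length(n)) stop("length(S) must equal length(n)")
  p <- nrow(S[[1L]])
  gene_ids <- rownames(S[[1L]])
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(p))

  pw <- resolve_pathways(pathways, p, gene_ids)
  pw <- normalize_pathways(pw, p)
  Q <- support_mask(pw, p)
  views <- pathway_blocks(pw, Q)

  G <- if (is.null(prior)) NULL else prior_network(prior, p = p, gene_ids = gene_ids)
  W <- weight_matrix(G, w = w, p = p)

  res <- admm_fit(S, n, views, Q, W, lambda1, lambda2,
                  mu = control$mu, max_iter = control$max_iter,
                  tol = control$tol, debug = control$debug)
  for (s in seq_along(res$networks)) {
    dimnames(res$networks[[s]]) <- list(gene_ids, gene_ids)
  }
  structure(c(res, list(
    lambda1 = lambda1, lambda2 = lambda2, w = w, mu = control$mu,
    tol = control$tol, p = p, K = length(S), n = n,
    gene_ids = gene_ids, pathways = pw, Q = Q, W = W, S = S, call = cl
  )), class = "wfpgl")
}

# Pathways may arrive as indices, as gene identifiers, or NULL (all genes in
# one pathway).
resolve_pathways <- function(pathways, p, gene_ids) {
  if (is.null(pathways)) return(list(seq_len(p)))
  if (is.numeric(pathways)) pathways <- list(pathways)
  lapply(pathways, function(s) {
    if (is.character(s)) {
      idx <- match(s, gene_ids)
      idx <- idx[!is.na(idx)]
      if (!length(idx)) stop("a pathway has no gene present in the expression data")
      idx
    } else {
      as.integer(s)
    }
  })
}

#' @export
print.wfpgl <- function(x, ...) {
  cat("Weighted fused pathway graphical lasso fit\n")
  cat(sprintf("  states: %d, genes: %d, samples: %s\n",
              x$K, x$p, paste(x$n, collapse = "/")))
  cat(sprintf("  lambda1 = %g, lambda2 = %g, w = %g\n",
              x$lambda1, x$lambda2, x$w))
  ne <- vapply(x$networks, function(m) sum(m[upper.tri(m)] != 0), numeric(1L))
  cat(sprintf("  edges per state: %s\n", paste(ne, collapse = ", ")))
  cat(sprintf("  %s after %d iterations (relative change %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, utils::tail(x$rel_change, 1L)))
  invisible(x)
}

#' @export
summary.wfpgl <- function(object, tol = 1e-8, ...) {
  ne <- vapply(object$networks, function(m) sum(m[upper.tri(m)] != 0), numeric(1L))
  diffs <- NULL
  if (object$K >= 2L) {
    pr <- utils::combn(object$K, 2L)
    diffs <- data.frame(
      state_a = pr[1L, ], state_b = pr[2L, ],
      differential_edges = apply(pr, 2L, function(q) {
        nrow(differential_edges(object$networks[[q[1L]]],
                                object$networks[[q[2L]]], tol = tol))
      })
    )
  }
  out <- list(
    K = object$K, p = object$p, n = object$n,
    lambda1 = object$lambda1, lambda2 = object$lambda2, w = object$w,
    edges = ne, differential = diffs,
    iterations = object$iterations, converged = object$converged,
    final_rel_change = utils::tail(object$rel_change, 1L)
  )
  class(out) <- "summary.wfpgl"
  out
}

#' @export
print.summary.wfpgl <- function(x, ...) {
  cat(sprintf("WFPGL fit: K = %d states, p = %d genes\n", x$K, x$p))
  cat(sprintf("  lambda1 = %g, lambda2 = %g, w = %g\n", x$lambda1, x$lambda2, x$w))
  for (s in seq_len(x$K)) {
    cat(sprintf("  state %d: n = %g, %d edges\n", s, x$n[s], x$edges[s]))
  }
  if (!is.null(x$differential)) {
    for (r in seq_len(nrow(x$differential))) {
      cat(sprintf("  differential edges %d vs %d: %d\n",
                  x$differential$state_a[r], x$differential$state_b[r],
                  x$differential$differential_edges[r]))
    }
  }
  cat(sprintf("  %s after %d iterations (relative change %.3g)\n",
              if (x$converged) "converged" else "not converged",
              x$iterations, x$final_rel_change))
  invisible(x)
}

#' Extract estimated networks from a WFPGL fit
#'
#' @param object a `wfpgl` fit.
#' @param state integer state index, or `NULL` for the full list.
#' @param ... unused.
#' @return one network matrix, or the list of all K.
#' @export
coef.wfpgl <- function(object, state = NULL, ...) {
  if (is.null(state)) object$networks else object$networks[[state]]
}

#' Plot a WFPGL fit
#'
#' `type = "trace"` shows the ADMM relative-change trace on a log scale;
#' `type = "network"` shows the sparsity pattern of one estimated network.
#'
#' @param x a `wfpgl` fit.
#' @param type `"trace"` or `"network"`.
#' @param state state index for `type = "network"`.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.wfpgl <- function(x, type = c("trace", "network"), state = 1L, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    graphics::plot(seq_along(x$rel_change), x$rel_change, type = "l",
                   log = "y", xlab = "ADMM iteration",
                   ylab = "relative change", ...)
    graphics::abline(h = x$tol, lty = 2)
  } else {
    m <- x$networks[[state]]
    graphics::image(seq_len(x$p), seq_len(x$p),
                    t((m != 0)[x$p:1, , drop = FALSE]),
                    col = c("white", "black"), xlab = "gene", ylab = "gene",
                    main = sprintf("state %d support", state), ...)
  }
  invisible(x)
}
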