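#' Proximal operator of the weighted fused lasso penalty (one entry)
#'
#' Solves, for a single matrix entry shared across the K states,
#' \deqn{\min_z \sum_k \frac{\mu}{2}(a_k - z_k)^2
#'   + \lambda_1 W \sum_k |z_k| + \lambda_2 W \sum_{k<k'} |z_k - z_{k'}|,}
#' the subproblem that the ADMM Z-update applies to every matrix position.
#' Off-diagonal entries receive both penalties; diagonal entries
#' (`diagonal = TRUE`) receive the fusion term only, since the sparsity sum
#' runs over `i != j`. For K <= 2 the closed-form fuse-then-soft-threshold
#' solution is used; for K >= 3 the exact minimizer is found by enumerating
#' ordered value-groupings with sign patterns and taking the candidate with
#' the smallest objective (the penalty is piecewise quadratic, so the global
#' minimizer is the stationary point of one such configuration). Output
#' zeros and cross-state ties are exact.
#'
#' @param a numeric length-K vector of inputs (one value per state).
#' @param lambda1 sparsity penalty (>= 0).
#' @param lambda2 fusion penalty (>= 0).
#' @param mu quadratic (ADMM) penalty parameter (> 0).
#' @param weight entry weight `W_ij` in `[0, 1]` (1 = no prior).
#' @param diagonal logical; `TRUE` drops the lambda1 term.
#' @return numeric length-K vector, the exact minimizer.
#' @examples
#' fused_prox(0.5, lambda1 = 0.2, lambda2 = 0)        # 0.3
#' fused_prox(c(1, 3), lambda1 = 0, lambda2 = 10)     # c(2, 2)
#' @export
fused_prox <- function(a, lambda1, lambda2, mu = 1, weight = 1, diagonal = FALSE) {
  k <- length(a)
  if (k < 1L) stop("a must have length K >= 1")
  if (lambda1 < 0 || lambda2 < 0 || mu <= 0) {
    stop("penalties must be >= 0 and mu > 0")
  }
  am <- matrix(as.numeric(a), nrow = k)
  l1 <- if (diagonal) 0 else lambda1 * weight
  l2 <- lambda2 * weight
  drop(prox_columns(am, l1, l2, mu))
}

# Vectorized prox over M entries: a is K x M; l1, l2 recycled to length M
# (already including the entry weight and the diagonal rule).
prox_columns <- function(a, l1, l2, mu) {
  k <- nrow(a)
  m <- ncol(a)
  l1 <- rep_len(l1, m)
  l2 <- rep_len(l2, m)
  if (k == 1L) {
    z <- soft_threshold(a[1L, ], l1 / mu)
    return(matrix(z, 1L, m))
  }
  if (k == 2L) return(prox_pair(a, l1, l2, mu))
  prox_enumerate(a, l1, l2, mu)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# K = 2 closed form: fuse the pair toward its mean by lambda2*W/mu (capped at
# pooling), then soft-threshold each by lambda1*W/mu.
prox_pair <- function(a, l1, l2, mu) {
  mid <- (a[1L, ] + a[2L, ]) / 2
  half <- (a[1L, ] - a[2L, ]) / 2
  shrunk <- sign(half) * pmax(abs(half) - l2 / mu, 0)
  z <- rbind(mid + shrunk, mid - shrunk)
  rbind(soft_threshold(z[1L, ], l1 / mu),
        soft_threshold(z[2L, ], l1 / mu))
}

# --- exact enumeration for K >= 3 ------------------------------------------

# Both penalty terms are symmetric functions of the K states and the
# quadratic term is strictly convex, so the minimizer preserves the ordering
# of the inputs (exchange argument): pooled groups are contiguous in sorted
# order. Candidate configurations are therefore the compositions of K into
# contiguous blocks with strictly increasing common values, crossed with
# every feasible sign pattern (a prefix of negative blocks, optionally one
# zero block, then positive blocks). The stationary value of each signed
# block is closed form; the global minimizer is the best-scoring candidate.
prox_config_cache <- new.env(parent = emptyenv())

prox_configs <- function(k) {
  key <- as.character(k)
  if (!is.null(prox_config_cache[[key]])) return(prox_config_cache[[key]])
  compositions <- function(n) {
    if (n == 0L) return(list(integer(0)))
    out <- list()
    for (first in seq_len(n)) {
      for (rest in compositions(n - first)) {
        out[[length(out) + 1L]] <- c(first, rest)
      }
    }
    out
  }
  configs <- list()
  for (sizes in compositions(k)) {
    m <- length(sizes)
    f <- rep.int(seq_len(m), sizes)
    gmat <- matrix(0, m, k)
    gmat[cbind(f, seq_len(k))] <- 1
    csum <- vapply(seq_len(m), function(g) {
      sum(sizes[seq_len(m) < g]) - sum(sizes[seq_len(m) > g])
    }, numeric(1L))
    for (nneg in 0:m) {
      for (has_zero in c(FALSE, TRUE)) {
        if (nneg + has_zero > m) next
        signs <- c(rep(-1, nneg), if (has_zero) 0, rep(1, m - nneg - has_zero))
        configs[[length(configs) + 1L]] <- list(
          gmat = gmat, sizes = as.numeric(sizes), csum = csum, signs = signs
        )
      }
    }
  }
  prox_config_cache[[key]] <- configs
  configs
}

prox_enumerate <- function(a, l1, l2, mu) {
  k <- nrow(a)
  m <- ncol(a)
  ord <- apply(a, 2L, order)
  asort <- matrix(a[ord + rep((seq_len(m) - 1L) * k, each = k)], k, m)
  configs <- prox_configs(k)
  pairs <- utils::combn(k, 2L)
  best_obj <- rep(Inf, m)
  best_z <- matrix(0, k, m)
  for (cf in configs) {
    abar <- (cf$gmat %*% asort) / cf$sizes
    v <- abar - (outer(cf$signs, l1) + outer(cf$csum, l2)) / mu
    if (any(cf$signs == 0)) v[cf$signs == 0, ] <- 0
    z <- crossprod(cf$gmat, v)
    obj <- (mu / 2) * colSums((asort - z)^2) + l1 * colSums(abs(z))
    fuse <- 0
    for (q in seq_len(ncol(pairs))) {
      fuse <- fuse + abs(z[pairs[1L, q], ] - z[pairs[2L, q], ])
    }
    obj <- obj + l2 * fuse
    better <- obj < best_obj
    if (any(better)) {
      best_obj[better] <- obj[better]
      best_z[, better] <- z[, better]
    }
  }
  # undo the per-column sort
  out <- matrix(0, k, m)
  out[ord + rep((seq_len(m) - 1L) * k, each = k)] <- best_z
  out
}

# Entrywise weighted fused prox applied to Theta + V across all states.
# Returns exactly symmetric matrices with exact zeros/ties; entries outside
# the diagonal use both penalties, diagonal entries fusion only.
update_z <- function(theta, v, W, lambda1, lambda2, mu = 1) {
  k <- length(theta)
  p <- nrow(theta[[1L]])
  ut <- which(upper.tri(W, diag = TRUE))
  ij <- arrayInd(ut, c(p, p))
  offdiag <- ij[, 1L] != ij[, 2L]
  a <- matrix(0, k, length(ut))
  for (s in seq_len(k)) a[s, ] <- theta[[s]][ut] + v[[s]][ut]
  wvec <- W[ut]
  l1 <- lambda1 * wvec * offdiag
  l2 <- lambda2 * wvec
  z <- prox_columns(a, l1, l2, mu)
  lapply(seq_len(k), function(s) {
    zm <- matrix(0, p, p)
    zm[ut] <- z[s, ]
    lw <- lower.tri(zm)
    zm[lw] <- t(zm)[lw]
    zm
  })
}
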