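#' Closed-form likelihood update of one pathway block
#'
#' Minimizes, over symmetric positive definite `T`,
#' \deqn{-n_k[\log\det T - \mathrm{tr}(S_t T)]
#'   + \frac{\mu}{2}\|T + \Delta_t - Z_t + V_t\|_F^2,}
#' the pathway-local subproblem of the ADMM Theta-step, and returns
#' `Theta_t = Delta_t + T`. With `A = S_t + (mu/n_k)(Delta_t - Z_t + V_t) =
#' U D U'`, the solution is `T = U C U'` where
#' `C_ii = (n_k / (2 mu)) (-D_ii + sqrt(D_ii^2 + 4 mu / n_k))`; every
#' `C_ii > 0`, so `T` is positive definite for any symmetric input.
#'
#' @param S_t pathway block of the sample covariance (`p_t x p_t`).
#' @param Delta_t Schur-complement correction from [compute_delta()].
#' @param Z_t,V_t pathway blocks of the ADMM auxiliary and scaled dual
#'   variables.
#' @param n_k sample size of the state.
#' @param mu ADMM penalty parameter (> 0).
#' @return symmetric `p_t x p_t` matrix `Delta_t + T` with `T` positive
#'   definite.
#' @export
update_theta_block <- function(S_t, Delta_t, Z_t, V_t, n_k, mu = 1) {
  a <- S_t + (mu / n_k) * (Delta_t - Z_t + V_t)
  if (max(abs(a - t(a))) > 1e-8) stop("theta block input is not symmetric")
  a <- (a + t(a)) / 2
  ed <- eigen(a, symmetric = TRUE)
  d <- ed$values
  cvals <- (n_k / (2 * mu)) * (-d + sqrt(d^2 + 4 * mu / n_k))
  tmat <- ed$vectors %*% (cvals * t(ed$vectors))
  Delta_t + (tmat + t(tmat)) / 2
}

# One full block-coordinate sweep of the Theta-update over all pathways for
# every state, in fixed ascending pathway order. Delta_t is recomputed from
# the current iterate before each block update; entries outside the support
# mask are never touched (they stay exactly zero). Overlapping entries are
# rewritten by every pathway that contains them (sequential convention).
sweep_theta <- function(theta, S, n, views, z, v, mu = 1) {
  k <- length(theta)
  for (s in seq_len(k)) {
    th <- theta[[s]]
    for (t in seq_along(views)) {
      vw <- views[[t]]
      idx <- vw$inside
      delta <- compute_delta(th, vw, t)
      th[idx, idx] <- update_theta_block(
        S[[s]][idx, idx, drop = FALSE], delta,
        z[[s]][idx, idx, drop = FALSE], v[[s]][idx, idx, drop = FALSE],
        n[s], mu
      )
    }
    theta[[s]] <- th
  }
  theta
}

# Scaled dual ascent: V <- V + Theta - Z, per state.
update_v <- function(v, theta, z) {
  lapply(seq_along(v), function(s) v[[s]] + theta[[s]] - z[[s]])
}

#' Relative-change stopping rule
#'
#' Returns `TRUE` when
#' `sum_k ||Theta_curr^(k) - Theta_prev^(k)||_F^2 / sum_k ||Theta_prev^(k)||_F^2`
#' falls below `tol` (default `1e-5`).
#'
#' @param theta_prev,theta_curr lists of K matrices (previous and current
#'   iterates).
#' @param tol positive tolerance.
#' @return logical flag; the attribute `"rel_change"` carries the ratio.
#' @export
has_converged <- function(theta_prev, theta_curr, tol = 1e-5) {
  denom <- sum(vapply(theta_prev, function(m) sum(m^2), numeric(1L)))
  if (denom == 0) stop("previous iterate is all zero: relative change undefined")
  num <- sum(vapply(seq_along(theta_prev), function(s) {
    sum((theta_curr[[s]] - theta_prev[[s]])^2)
  }, numeric(1L)))
  rel <- num / denom
  structure(rel < tol, rel_change = rel)
}

# Full ADMM loop on precomputed covariances. Initialization Theta = I,
# Z = V = 0, mu fixed. Returns Theta/Z/V, the per-iteration relative-change
# trace, and the final networks (Z masked by Q).
admm_fit <- function(S, n, views, Q, W, lambda1, lambda2,
                     mu = 1, max_iter = 500L, tol = 1e-5, debug = FALSE) {
  k <- length(S)
  p <- nrow(S[[1L]])
  theta <- replicate(k, diag(1, p), simplify = FALSE)
  z <- replicate(k, matrix(0, p, p), simplify = FALSE)
  v <- replicate(k, matrix(0, p, p), simplify = FALSE)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    theta_prev <- theta
    theta <- sweep_theta(theta, S, n, views, z, v, mu)
    z <- update_z(theta, v, W, lambda1, lambda2, mu)
    v <- update_v(v, theta, z)
    if (any(!vapply(theta, function(m) all(is.finite(m)), logical(1L)))) {
      stop("non-finite values in Theta at iteration ", iter)
    }
    if (debug) {
      for (s in seq_len(k)) {
        stopifnot(max(abs(theta[[s]][Q == 0])) == 0)
        chol(theta[[s]])
      }
    }
    ok <- has_converged(theta_prev, theta, tol)
    trace <- c(trace, attr(ok, "rel_change"))
    # The relative-change rule alone can fire while Theta and Z still
    # disagree (the dual variable accumulates slowly when mu/n_k is small),
    # so convergence additionally requires the relative primal residual
    # ||Theta - Z||_F^2 / ||Theta||_F^2 to reach the same level.
    primal <- sum(vapply(seq_len(k), function(s) {
      sum((theta[[s]] - z[[s]])^2)
    }, numeric(1L))) / sum(vapply(theta, function(m) sum(m^2), numeric(1L)))
    if (ok && primal < tol) { converged <- TRUE; break }
  }
  networks <- lapply(z, function(m) m * Q)
  list(
    networks = networks, theta = theta, z = z, v = v,
    iterations = iter, converged = converged, rel_change = trace
  )
}
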