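# Shared fixtures and independent oracles used across the test files.
# Everything here is built in code at test time; the oracles deliberately
# avoid the code paths they validate.

# Random symmetric positive definite matrix respecting a support mask.
random_pd_masked <- function(p, Q, strength = 0.2) {
  m <- matrix(0, p, p)
  idx <- which(upper.tri(Q) & Q != 0)
  m[idx] <- stats::runif(length(idx), -strength, strength)
  m <- m + t(m)
  diag(m) <- rowSums(abs(m)) + stats::runif(p, 0.5, 1)
  m
}

# Penalty function F({Z}) of the weighted fused lasso (sparsity over
# off-diagonal entries, fusion over all entries, both full-matrix sums).
penalty_value <- function(z, W, lambda1, lambda2) {
  K <- length(z)
  val <- 0
  for (k in seq_len(K)) {
    off <- z[[k]]; diag(off) <- 0
    val <- val + lambda1 * sum(W * abs(off))
  }
  if (K >= 2) {
    pr <- utils::combn(K, 2)
    for (q in seq_len(ncol(pr))) {
      val <- val + lambda2 * sum(W * abs(z[[pr[1, q]]] - z[[pr[2, q]]]))
    }
  }
  val
}

# Augmented Lagrangian of the ADMM splitting (scaled-dual form).
aug_lagrangian <- function(theta, z, v, S, n, W, lambda1, lambda2, mu) {
  val <- penalty_value(z, W, lambda1, lambda2)
  for (k in seq_along(theta)) {
    ld <- determinant(theta[[k]], logarithm = TRUE)
    val <- val - n[k] * (as.numeric(ld$modulus) - sum(S[[k]] * theta[[k]]))
    val <- val + (mu / 2) * sum((theta[[k]] - z[[k]] + v[[k]])^2) -
      (mu / 2) * sum(v[[k]]^2)
  }
  val
}

# Objective of the pathway-block likelihood subproblem, as a function of the
# full returned block (T = block - Delta must be positive definite).
theta_block_objective <- function(block, S_t, Delta_t, Z_t, V_t, n_k, mu) {
  tm <- block - Delta_t
  ld <- determinant(tm, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  -n_k * (as.numeric(ld$modulus) - sum(S_t * tm)) +
    (mu / 2) * sum((tm + Delta_t - Z_t + V_t)^2)
}

# Independent numeric minimizer of the block subproblem: BFGS over the
# Cholesky factor of T (unconstrained smooth parameterization), analytic
# gradient, identity start.
theta_block_numeric <- function(S_t, Delta_t, Z_t, V_t, n_k, mu) {
  p <- nrow(S_t)
  lw <- which(lower.tri(diag(p), diag = TRUE))
  par2t <- function(par) {
    L <- matrix(0, p, p)
    L[lw] <- par
    tcrossprod(L)
  }
  fn <- function(par) {
    tm <- par2t(par)
    ld <- determinant(tm, logarithm = TRUE)
    if (ld$sign <= 0 || !is.finite(ld$modulus)) return(1e10)
    -n_k * (as.numeric(ld$modulus) - sum(S_t * tm)) +
      (mu / 2) * sum((tm + Delta_t - Z_t + V_t)^2)
  }
  gr <- function(par) {
    L <- matrix(0, p, p)
    L[lw] <- par
    tm <- tcrossprod(L)
    g <- -n_k * (solve(tm) - S_t) + mu * (tm + Delta_t - Z_t + V_t)
    (2 * g %*% L)[lw]
  }
  par0 <- diag(p)[lw]
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(block = par2t(opt$par) + Delta_t, value = opt$value)
}

# Brute-force recovery metrics: explicit loops over every state (pair) and
# every i < j, translated directly from the metric definitions.
metrics_bruteforce <- function(truth, estimates, tol = 1e-8) {
  K <- length(truth)
  p <- nrow(truth[[1]])
  tp <- pos <- fp <- neg <- 0
  for (k in seq_len(K)) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      te <- truth[[k]][i, j] != 0
      ee <- abs(estimates[[k]][i, j]) > tol
      if (te) { pos <- pos + 1; if (ee) tp <- tp + 1 }
      else { neg <- neg + 1; if (ee) fp <- fp + 1 }
    }
  }
  td <- dpos <- fd <- dneg <- 0
  if (K >= 2) {
    for (k1 in seq_len(K - 1)) for (k2 in (k1 + 1):K) {
      for (i in seq_len(p - 1)) for (j in (i + 1):p) {
        tdiff <- truth[[k1]][i, j] != truth[[k2]][i, j]
        ediff <- abs(estimates[[k1]][i, j] - estimates[[k2]][i, j]) > tol
        if (tdiff) { dpos <- dpos + 1; if (ediff) td <- td + 1 }
        else { dneg <- dneg + 1; if (ediff) fd <- fd + 1 }
      }
    }
  }
  list(tpr = tp / pos, fpr = fp / neg,
       tpdr = if (K >= 2) td / dpos else NULL,
       fpdr = if (K >= 2) fd / dneg else NULL)
}

# Batch-solve fused-prox problems with the scipy SLSQP oracle; `problems` is
# a list of lists with fields a, l1, l2, mu. Returns a list of solutions.
run_prox_oracle <- function(problems) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  infile <- file.path(dir, "problems.json")
  outfile <- file.path(dir, "solutions.json")
  jsonlite::write_json(problems, infile, auto_unbox = FALSE, digits = NA)
  status <- system2("python", c(testthat::test_path("fused_prox_oracle.py"),
                                infile, outfile))
  stopifnot(status == 0)
  jsonlite::fromJSON(outfile, simplifyVector = FALSE)
}

# Reference graphical lasso (scikit-learn) on a covariance matrix.
run_glasso_oracle <- function(S, alpha) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  infile <- file.path(dir, "S.tsv")
  outfile <- file.path(dir, "prec.tsv")
  utils::write.table(S, infile, row.names = FALSE, col.names = FALSE)
  status <- system2("python", c(testthat::test_path("glasso_oracle.py"),
                                infile, outfile, format(alpha, digits = 16)))
  stopifnot(status == 0)
  as.matrix(utils::read.table(outfile))
}

edge_count <- function(m, tol = 0) sum(abs(m[upper.tri(m)]) > tol)

support_f1 <- function(truth, estimate, tol = 1e-8) {
  tru <- abs(truth[upper.tri(truth)]) > 0
  est <- abs(estimate[upper.tri(estimate)]) > tol
  tp <- sum(tru & est)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + sum(!tru & est) + sum(tru & !est))
}
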