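test_that("theta block update matches the scalar stationarity solution", {
  z0 <- matrix(0, 2, 2)
  got <- update_theta_block(diag(2), z0, z0, z0, n_k = 1, mu = 1)
  expect_equal(got, diag((-1 + sqrt(5)) / 2, 2), tolerance = 1e-12)
  expect_error(update_theta_block(matrix(c(0, 1, 0, 0), 2, 2), z0, z0, z0, 1, 1),
               "symmetric")
})

test_that("theta block update approaches the unpenalized MLE as mu/n -> 0", {
  set.seed(61)
  s <- crossprod(matrix(rnorm(40), 10, 4)) / 10 + diag(0.5, 4)
  z0 <- matrix(0, 4, 4)
  got <- update_theta_block(s, z0, z0, z0, n_k = 1e8, mu = 1)
  expect_equal(got, solve(s), tolerance = 1e-5)
})

test_that("theta block update attains the subproblem minimum", {
  set.seed(62)
  for (rep in 1:15) {
    p <- sample(2:4, 1)
    s <- crossprod(matrix(rnorm(4 * p), 4, p)) / 4 + diag(0.3, p)
    delta <- crossprod(matrix(rnorm(p * p) * 0.1, p, p))
    zt <- matrix(rnorm(p * p) * 0.3, p, p); zt <- (zt + t(zt)) / 2
    vt <- matrix(rnorm(p * p) * 0.3, p, p); vt <- (vt + t(vt)) / 2
    n_k <- sample(c(1, 10, 100), 1); mu <- runif(1, 0.5, 2)
    got <- update_theta_block(s, delta, zt, vt, n_k, mu)
    ours <- theta_block_objective(got, s, delta, zt, vt, n_k, mu)
    ref <- theta_block_numeric(s, delta, zt, vt, n_k, mu)
    expect_lte(ours, ref$value + 1e-5)
    # returned T = block - delta must be PD
    expect_gt(min(eigen(got - delta, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("a sweep with one all-covering pathway equals a global update", {
  set.seed(63)
  p <- 5
  s <- list(crossprod(matrix(rnorm(4 * p), 4, p)) / 4 + diag(0.3, p))
  pw <- list(1:p)
  views <- pathway_blocks(pw, support_mask(pw, p))
  z <- list(matrix(0, p, p)); v <- list(matrix(0, p, p))
  theta <- list(diag(p))
  got <- wfpgl:::sweep_theta(theta, s, 10, views, z, v, mu = 1)
  direct <- update_theta_block(s[[1]], matrix(0, p, p), z[[1]], v[[1]], 10, 1)
  expect_equal(got[[1]], direct)
})

test_that("disjoint pathways update independently of processing order", {
  set.seed(64)
  p <- 6
  pw1 <- list(1:3, 4:6)
  pw2 <- rev(pw1)
  q <- support_mask(pw1, p)
  s <- list(random_pd_masked(p, q))
  z <- list(matrix(0, p, p)); v <- list(matrix(0, p, p))
  theta <- list(diag(p))
  a <- wfpgl:::sweep_theta(theta, s, 20, pathway_blocks(pw1, q), z, v, 1)
  b <- wfpgl:::sweep_theta(theta, s, 20, pathway_blocks(pw2, q), z, v, 1)
  expect_equal(a, b)
  expect_true(all(a[[1]][q == 0] == 0))
})

test_that("a theta sweep never increases the augmented Lagrangian", {
  set.seed(65)
  pw <- list(1:2, 2:3)
  q <- support_mask(pw, 3)
  views <- pathway_blocks(pw, q)
  W <- matrix(1, 3, 3)
  for (rep in 1:10) {
    s <- list(random_pd_masked(3, q))
    z <- list(random_pd_masked(3, q) * 0.3)
    v <- list(random_pd_masked(3, q) * 0.1)
    theta <- list(diag(3))
    before <- aug_lagrangian(theta, z, v, s, 5, W, 0.1, 0.1, mu = 1)
    swept <- wfpgl:::sweep_theta(theta, s, 5, views, z, v, mu = 1)
    after <- aug_lagrangian(swept, z, v, s, 5, W, 0.1, 0.1, mu = 1)
    expect_lte(after, before + 1e-10)
  }
})

test_that("dual update accumulates the primal residual", {
  v <- list(matrix(0, 2, 2))
  theta <- list(matrix(c(1, 0.2, 0.2, 1), 2, 2))
  z <- list(diag(2))
  e <- theta[[1]] - z[[1]]
  v1 <- wfpgl:::update_v(v, theta, z)
  expect_equal(v1[[1]], e)
  v2 <- wfpgl:::update_v(v1, theta, z)
  expect_equal(v2[[1]], 2 * e)
  expect_equal(wfpgl:::update_v(v, theta, theta)[[1]], v[[1]])
})

test_that("convergence flag follows the relative-change ratio", {
  th <- list(diag(10))
  expect_true(has_converged(th, th, 1e-5))
  ok <- has_converged(th, list(1.1 * diag(10)), 1e-5)
  expect_false(ok)
  expect_equal(attr(ok, "rel_change"), 0.01)
  expect_true(has_converged(th, list(5 * diag(10)), Inf))
  expect_error(has_converged(list(matrix(0, 2, 2)), th, 1e-5), "all zero")
})

test_that("penalty limits force diagonal or identical networks", {
  set.seed(66)
  sc <- wfpgl_scenario("two_state", p = 20, n = 40, J = 2, n_ol = 4, seed = 3)
  f <- wfpgl(sc$x, pathways = sc$pathways, lambda1 = 1e6, lambda2 = 0)
  for (k in 1:2) {
    off <- f$networks[[k]]; diag(off) <- 0
    expect_true(all(off == 0))
  }
  f <- wfpgl(sc$x, pathways = sc$pathways, lambda1 = 2, lambda2 = 1e6)
  expect_equal(f$networks[[1]], f$networks[[2]])
})

test_that("iterates stay PD, masked by Q, and reach the fixed point", {
  set.seed(67)
  sc <- wfpgl_scenario("two_state", p = 24, n = 60, J = 3, n_ol = 4, seed = 5)
  f <- wfpgl(sc$x, pathways = sc$pathways, prior = sc$prior,
             lambda1 = 6, lambda2 = 0.01,
             control = wfpgl_control(debug = TRUE, tol = 1e-7))
  expect_true(f$converged)
  for (k in 1:2) {
    expect_true(all(f$theta[[k]][sc$Q == 0] == 0))
    expect_true(all(f$networks[[k]][sc$Q == 0] == 0))
    expect_lt(max(abs(f$theta[[k]] - f$z[[k]])), 1e-3)
  }
})

test_that("relabeling genes permutes the solution consistently", {
  set.seed(68)
  sc <- wfpgl_scenario("two_state", p = 15, n = 40, J = 2, n_ol = 3, seed = 7)
  perm <- sample(15)
  f1 <- wfpgl(sc$x, pathways = sc$pathways, prior = sc$prior,
              lambda1 = 4, lambda2 = 0.01)
  xp <- lapply(sc$x, function(m) m[perm, ])
  pwp <- lapply(sc$pathways, function(s) match(s, perm))
  f2 <- wfpgl(xp, pathways = pwp, prior = sc$prior[perm, perm],
              lambda1 = 4, lambda2 = 0.01)
  for (k in 1:2) {
    expect_equal(unname(f2$networks[[k]]), unname(f1$networks[[k]][perm, perm]),
                 tolerance = 1e-8)
  }
})

test_that("edge count is non-increasing in lambda1", {
  set.seed(69)
  sc <- wfpgl_scenario("two_state", p = 20, n = 50, J = 2, n_ol = 4, seed = 9)
  counts <- sapply(c(1, 4, 8, 16, 40), function(l1) {
    f <- wfpgl(sc$x, pathways = sc$pathways, lambda1 = l1, lambda2 = 0.01)
    sum(sapply(f$networks, edge_count))
  })
  expect_true(all(diff(counts) <= 0))
})
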