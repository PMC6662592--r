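test_that("pathway generator reproduces the published benchmark layout", {
  pw <- generate_pathways(400, 10, 5)
  expect_equal(pw[[1]], 1:45)
  expect_equal(pw[[2]], 41:85)
  expect_equal(pw[[10]], 361:400)
  for (t in 1:9) expect_length(intersect(pw[[t]], pw[[t + 1]]), 5)
  expect_equal(sort(unique(unlist(pw))), 1:400)
})

test_that("pathway generator handles small and degenerate layouts", {
  expect_equal(generate_pathways(10, 2, 2), list(1:6, 5:10))
  expect_equal(generate_pathways(7, 1, 0), list(1:7))
  expect_error(generate_pathways(3, 2, 4), "infeasible")
})

test_that("base network is a connected seeded scale-free tree", {
  expect_equal(generate_base_network(2, seed = 1),
               matrix(c(0, 1, 1, 0), 2, 2))
  m <- generate_base_network(50, seed = 2)
  expect_equal(sum(m) / 2, 49)  # tree with m = 1
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 50))
  expect_identical(m, generate_base_network(50, seed = 2))

  # heavy-tailed degrees: max degree far above the median over seeded draws
  degs <- unlist(lapply(1:10, function(s) {
    rowSums(generate_base_network(400, seed = s))
  }))
  expect_gt(max(degs), 10 * median(degs))
})

test_that("edge weights live on the signed uniform interval", {
  m <- generate_base_network(200, seed = 3)
  mw <- assign_edge_weights(m, seed = 4)
  vals <- mw[upper.tri(mw) & m != 0]
  expect_true(all(abs(vals) >= 0.3 & abs(vals) <= 0.6))
  expect_true(all(mw[m == 0] == 0))
  expect_equal(mw, t(mw))
  expect_equal(assign_edge_weights(matrix(0, 3, 3)), matrix(0, 3, 3))
})

test_that("edge weight signs are balanced", {
  set.seed(5)
  m <- matrix(1, 150, 150); diag(m) <- 0
  mw <- assign_edge_weights(m, seed = 6)
  sgn <- sign(mw[upper.tri(mw)])
  expect_equal(mean(sgn < 0), 0.5, tolerance = 0.05)
})

test_that("state networks follow the removal/reassignment scheme", {
  m <- generate_base_network(100, seed = 7)
  mw <- assign_edge_weights(m, seed = 8)
  e <- edge_count(mw)

  nets <- derive_state_networks(mw, K = 2, r = 0, seed = 9)
  expect_equal(nets[[2]], nets[[1]])
  nets <- derive_state_networks(mw, K = 2, r = 1, seed = 9)
  expect_equal(nets[[2]], matrix(0, 100, 100))

  nets <- derive_state_networks(mw, K = 2, r = 0.3, seed = 10)
  expect_equal(edge_count(nets[[2]]), e - floor(0.3 * e))
  # removals only: every surviving edge keeps its weight
  kept <- nets[[2]] != 0
  expect_equal(nets[[2]][kept], mw[kept])

  nets <- derive_state_networks(mw, K = 3, r = 0.1, seed = 11)
  removed <- which(upper.tri(mw) & mw != 0 & nets[[2]] == 0)
  back <- which(upper.tri(mw) & nets[[3]] != 0 & nets[[2]] == 0)
  expect_true(all(back %in% removed))           # reassignments come from removals
  expect_true(all(abs(nets[[3]][back]) >= 0.3 & abs(nets[[3]][back]) <= 0.6))

  nets <- derive_state_networks(mw, K = 4, r = 0.2, seed = 12)
  expect_equal(edge_count(nets[[4]]), e - floor(0.2 * e))
  for (k in 1:4) expect_equal(nets[[k]], t(nets[[k]]))
  expect_error(derive_state_networks(mw, K = 5, r = 0.1), "K must be")
})

test_that("prior network samples the requested share of state-1 edges", {
  m <- generate_base_network(150, seed = 13)
  e <- sum(m) / 2
  expect_equal(generate_prior_network(m, 0, seed = 14), matrix(0, 150, 150))
  expect_equal(generate_prior_network(m, 1, seed = 14), m)
  g <- generate_prior_network(m, 0.5, seed = 14)
  expect_equal(sum(g) / 2, round(0.5 * e))
  expect_true(all(m[g == 1] == 1))
})

test_that("precision construction is PD with one shared diagonal shift", {
  expect_equal(build_precision(matrix(0, 3, 3), matrix(1, 3, 3), 0.2)[[1]],
               diag(0.2, 3))

  mw <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  th <- build_precision(mw, matrix(1, 2, 2), pd_buffer = 0.2)[[1]]
  expect_equal(th, matrix(c(0.7, 0.5, 0.5, 0.7), 2, 2))
  expect_equal(min(eigen(th, only.values = TRUE)$values), 0.2)

  m <- generate_base_network(60, seed = 15)
  mw1 <- assign_edge_weights(m, seed = 16)
  nets <- derive_state_networks(mw1, K = 2, r = 0.3, seed = 17)
  q <- support_mask(generate_pathways(60, 3, 5), 60)
  ths <- build_precision(nets, q, pd_buffer = 0.2)
  expect_equal(diag(ths[[1]]), diag(ths[[2]]))  # shared sigma
  for (th in ths) {
    expect_silent(chol(th))
    expect_gte(min(eigen(th, only.values = TRUE)$values), 0.2 - 1e-10)
  }
  per <- build_precision(nets, q, pd_buffer = 0.2, per_state_sigma = TRUE)
  for (th in per) expect_silent(chol(th))
})

test_that("expression sampling is seeded and matches its covariance", {
  th <- build_precision(matrix(c(0, 0.4, 0.4, 0), 2, 2), matrix(1, 2, 2), 0.3)[[1]]
  x1 <- sample_expression(th, 50, seed = 18)
  x2 <- sample_expression(th, 50, seed = 18)
  expect_identical(x1, x2)

  p5 <- diag(0.8, 5); p5[1, 2] <- p5[2, 1] <- 0.3
  x <- sample_expression(p5, 1e5, seed = 19)
  sigma <- solve(p5)
  expect_lt(max(abs(sample_covariance(x) - sigma)), 0.05)
  expect_lt(max(abs(rowMeans(x))), 0.02)
  expect_error(sample_expression(matrix(c(1, 2, 2, 1), 2, 2), 10),
               "positive definite")
})

test_that("scenario presets echo the benchmark settings deterministically", {
  sc <- wfpgl_scenario("two_state", seed = 20)
  expect_equal(sc$config[c("p", "K", "n", "J", "n_ol", "r")],
               list(p = 400L, K = 2L, n = 100L, J = 10L, n_ol = 5L, r = 0.3))
  expect_length(sc$x, 2)
  expect_equal(dim(sc$x[[1]]), c(400, 100))

  sc4 <- wfpgl_scenario("four_state", p = 60, seed = 21)
  expect_length(sc4$truth$Theta, 4)
  expect_equal(dim(sc4$truth$Theta[[4]]), c(60, 60))

  a <- wfpgl_scenario("two_state", p = 30, n = 20, J = 2, seed = 22)
  b <- wfpgl_scenario("two_state", p = 30, n = 20, J = 2, seed = 22)
  expect_identical(a$truth, b$truth)
  expect_identical(a$x, b$x)
})

test_that("scenario ground truth respects the support mask", {
  sc <- wfpgl_scenario("two_state", p = 50, n = 20, J = 3, seed = 23)
  for (k in 1:2) {
    off <- sc$truth$Theta[[k]]; diag(off) <- 0
    expect_true(all(off[sc$Q == 0] == 0))
  }
  # differential edges are exactly the removed edges that survive masking
  d <- (sc$truth$Theta[[1]] != sc$truth$Theta[[2]])
  removed <- (sc$truth$M_weighted[[1]] != 0) & (sc$truth$M_weighted[[2]] == 0)
  expect_equal(unname(d), unname(removed & sc$Q == 1))
})
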