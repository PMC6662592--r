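#' Overlapping blocks of successive genes as benchmark pathways
#'
#' Builds J equally sized pathways of consecutive gene indices, each sharing
#' exactly `n_ol` genes with its neighbor, together covering `1:p`. The
#' common size is `s = ceiling((p + (J - 1) n_ol) / J)` and pathway `t`
#' starts at `(t - 1)(s - n_ol) + 1`; the last pathway is truncated at `p`.
#' With `p = 400`, `J = 10`, `n_ol = 5` this yields `P_1 = {1..45}`,
#' `P_2 = {41..85}`, ..., `P_10 = {361..400}`.
#'
#' @param p number of genes.
#' @param J number of pathways.
#' @param n_ol overlap between neighboring pathways.
#' @return list of J integer vectors.
#' @export
generate_pathways <- function(p, J, n_ol = 0L) {
  p <- as.integer(p); J <- as.integer(J); n_ol <- as.integer(n_ol)
  if (J < 1L || n_ol < 0L) stop("J >= 1 and n_ol >= 0 required")
  s <- ceiling((p + (J - 1L) * n_ol) / J)
  if (s <= n_ol) stop("infeasible pathway layout: size ", s, " <= overlap ", n_ol)
  lapply(seq_len(J), function(t) {
    start <- (t - 1L) * (s - n_ol) + 1L
    seq.int(start, min(start + s - 1L, p))
  })
}

#' Random scale-free base network
#'
#' Generates the state-1 adjacency by Barabasi-Albert preferential
#' attachment (`m` edges per arriving node, default 1, which gives a
#' connected tree with `p - 1` edges and a heavy-tailed degree sequence).
#'
#' @param p number of genes (>= 2).
#' @param m edges added per node.
#' @param seed integer seed.
#' @return binary symmetric `p x p` adjacency, zero diagonal.
#' @export
generate_base_network <- function(p, m = 1L, seed = NULL) {
  if (p < 2L) stop("p >= 2 required")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(p, power = 1, m = m, directed = FALSE)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  a <- (a != 0) * 1
  a <- pmax(a, t(a))
  diag(a) <- 0
  a
}

#' Assign signed uniform weights to network edges
#'
#' Each edge receives magnitude `Uniform(value_range[1], value_range[2])`
#' and an independent sign, negative with probability 1/2, mirrored to keep
#' the matrix symmetric (default range `[0.3, 0.6]`, i.e. values on
#' `[-0.6, -0.3] U [0.3, 0.6]`).
#'
#' @param M binary symmetric adjacency.
#' @param value_range length-2 magnitude interval.
#' @param seed integer seed.
#' @return symmetric weighted matrix with zero diagonal.
#' @export
assign_edge_weights <- function(M, value_range = c(0.3, 0.6), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(M)
  out <- matrix(0, p, p)
  idx <- which(upper.tri(M) & M != 0)
  ne <- length(idx)
  if (ne) {
    mag <- stats::runif(ne, value_range[1L], value_range[2L])
    sgn <- ifelse(stats::runif(ne) < 0.5, -1, 1)
    out[idx] <- sgn * mag
    lw <- lower.tri(out)
    out[lw] <- t(out)[lw]
  }
  out
}

#' Derive the K state networks from the state-1 weighted network
#'
#' Two states: state 2 is a copy of state 1 with `floor(r E)` uniformly
#' chosen edges removed (`E` = edge count). Three states: states 1-2 as
#' above; state 3 copies state 2 and re-assigns each removed edge, with
#' probability 1/2, a fresh signed uniform weight. Four states: states 1-3
#' as in the three-state scheme, and state 4 copies state 1 with 20% of its
#' edges removed.
#'
#' @param M1 weighted state-1 matrix from [assign_edge_weights()].
#' @param K number of states (2, 3 or 4).
#' @param r edge-removal rate for the state-1 to state-2 transition.
#' @param value_range magnitude interval for re-assigned weights.
#' @param seed integer seed.
#' @return list of K symmetric weighted matrices.
#' @export
derive_state_networks <- function(M1, K, r, value_range = c(0.3, 0.6),
                                  seed = NULL) {
  if (!K %in% 2:4) stop("K must be 2, 3 or 4")
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(M1)
  edges <- which(upper.tri(M1) & M1 != 0)
  nrem <- floor(r * length(edges))
  removed <- if (nrem > 0) sample(edges, nrem) else integer(0)
  M2 <- drop_edges(M1, removed)
  nets <- list(M1, M2)
  if (K >= 3L) {
    M3 <- M2
    if (length(removed)) {
      back <- removed[stats::runif(length(removed)) < 0.5]
      if (length(back)) {
        mag <- stats::runif(length(back), value_range[1L], value_range[2L])
        sgn <- ifelse(stats::runif(length(back)) < 0.5, -1, 1)
        M3[back] <- sgn * mag
        lw <- lower.tri(M3)
        M3[lw] <- t(M3)[lw]
      }
    }
    nets[[3L]] <- M3
  }
  if (K == 4L) {
    nrem4 <- floor(0.2 * length(edges))
    removed4 <- if (nrem4 > 0) sample(edges, nrem4) else integer(0)
    nets[[4L]] <- drop_edges(M1, removed4)
  }
  nets
}

drop_edges <- function(M, idx) {
  if (!length(idx)) return(M)
  p <- nrow(M)
  ij <- arrayInd(idx, c(p, p))
  M[idx] <- 0
  M[cbind(ij[, 2L], ij[, 1L])] <- 0
  M
}

#' Simulated prior gene-interaction network
#'
#' Samples `round(eta * E)` edges uniformly without replacement from the
#' edges of the state-1 adjacency (prior edges need not be differential).
#'
#' @param M1 binary state-1 adjacency.
#' @param eta prior rate in `[0, 1]`.
#' @param seed integer seed.
#' @return binary symmetric adjacency (a subset of `M1`'s edges).
#' @export
generate_prior_network <- function(M1, eta, seed = NULL) {
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(M1)
  edges <- which(upper.tri(M1) & M1 != 0)
  ntake <- round(eta * length(edges))
  take <- if (ntake > 0) sample(edges, ntake) else integer(0)
  g <- matrix(0, p, p)
  g[take] <- 1
  pmax(g, t(g))
}

#' Ground-truth precision matrices from weighted networks
#'
#' Forms `A^(k) = M_weighted^(k) * Q` (Hadamard mask by the pathway support)
#' and returns `Theta^(k) = A^(k) + (sigma + pd_buffer) I`, where `sigma` is
#' the largest `|lambda_min(A^(k))|` across states (one shared shift, so
#' cross-state differences come only from the network edits, never from the
#' diagonal). The literal shift by `sigma` alone would make the smallest
#' eigenvalue exactly zero, hence the strictly positive `pd_buffer`;
#' every returned matrix satisfies `lambda_min >= pd_buffer`.
#'
#' @param M_weighted list of K weighted matrices (or a single matrix).
#' @param Q support mask.
#' @param pd_buffer positive diagonal buffer beyond `sigma` (default 0.2).
#' @param per_state_sigma use each state's own `|lambda_min|` instead of the
#'   shared maximum.
#' @return list of K positive definite matrices.
#' @export
build_precision <- function(M_weighted, Q, pd_buffer = 0.2,
                            per_state_sigma = FALSE) {
  if (pd_buffer <= 0) stop("pd_buffer must be > 0")
  if (is.matrix(M_weighted)) M_weighted <- list(M_weighted)
  a <- lapply(M_weighted, function(m) m * Q)
  sig <- vapply(a, function(m) abs(min(eigen(m, symmetric = TRUE,
                                             only.values = TRUE)$values)),
                numeric(1L))
  if (!per_state_sigma) sig <- rep(max(sig), length(sig))
  lapply(seq_along(a), function(s) {
    a[[s]] + diag(sig[s] + pd_buffer, nrow(a[[s]]))
  })
}

#' Draw multivariate normal expression samples
#'
#' Generates `n` independent zero-mean draws with covariance
#' `Sigma = Theta^{-1}`, via the Cholesky factor of `Sigma`.
#'
#' @param Theta positive definite precision matrix.
#' @param n number of samples.
#' @param seed integer seed.
#' @return `p x n` matrix (genes x samples).
#' @export
sample_expression <- function(Theta, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- tryCatch(chol(Theta), error = function(e) {
    stop("Theta must be positive definite")
  })
  sigma <- chol2inv(r)
  l <- t(chol((sigma + t(sigma)) / 2))
  p <- nrow(Theta)
  l %*% matrix(stats::rnorm(p * n), p, n)
}

#' Benchmark scenario generator
#'
#' Composes the full simulation pipeline: overlapping successive-gene
#' pathways, a scale-free state-1 network with signed uniform edge weights,
#' state-specific edits, a prior network covering a fraction `eta` of
#' state-1 edges, pathway-masked positive definite precision matrices with a
#' shared diagonal shift, and multivariate normal expression samples per
#' state. The presets mirror the benchmark settings: `two_state`
#' (p = 400, K = 2, n = 100, J = 10, n_ol = 5, r = 0.3), `three_state`
#' (p = 400, K = 3, n = 50, J = 8, n_ol = 10, r = 0.1) and `four_state`
#' (p = 200, K = 4, n = 50, J = 5, n_ol = 8, r = 0.2); any field may be
#' overridden. One root seed fans out to fixed sub-streams (topology,
#' weights, edits, prior, sampling) so each component is independently
#' reproducible.
#'
#' @param preset `"two_state"`, `"three_state"` or `"four_state"`.
#' @param p,K,n,J,n_ol,r,eta scenario parameters overriding the preset
#'   (genes, states, samples per state, pathways, pathway overlap,
#'   edge-removal rate, prior rate).
#' @param value_range edge-weight magnitude interval.
#' @param pd_buffer diagonal buffer for [build_precision()].
#' @param m preferential-attachment edges per node.
#' @param seed root integer seed.
#' @return object of class `wfpgl_scenario`: a list with `x` (expression
#'   matrices), `pathways`, `Q`, `prior` (adjacency `G`), `truth`
#'   (`M`, `M_weighted`, `Theta`, and the per-state edge supports after
#'   pathway masking) and the effective `config`.
#' @export
wfpgl_scenario <- function(preset = c("two_state", "three_state", "four_state"),
                           p = NULL, K = NULL, n = NULL, J = NULL,
                           n_ol = NULL, r = NULL, eta = 0.8,
                           value_range = c(0.3, 0.6), pd_buffer = 0.2,
                           m = 1L, seed = 1L) {
  preset <- match.arg(preset)
  base <- switch(preset,
    two_state   = list(p = 400L, K = 2L, n = 100L, J = 10L, n_ol = 5L, r = 0.3),
    three_state = list(p = 400L, K = 3L, n = 50L,  J = 8L,  n_ol = 10L, r = 0.1),
    four_state  = list(p = 200L, K = 4L, n = 50L,  J = 5L,  n_ol = 8L, r = 0.2)
  )
  cfg <- list(
    preset = preset,
    p = if (is.null(p)) base$p else as.integer(p),
    K = if (is.null(K)) base$K else as.integer(K),
    n = if (is.null(n)) base$n else as.integer(n),
    J = if (is.null(J)) base$J else as.integer(J),
    n_ol = if (is.null(n_ol)) base$n_ol else as.integer(n_ol),
    r = if (is.null(r)) base$r else r,
    eta = eta, value_range = value_range, pd_buffer = pd_buffer,
    m = as.integer(m), seed = as.integer(seed)
  )
  pw <- generate_pathways(cfg$p, cfg$J, cfg$n_ol)
  Q <- support_mask(pw, cfg$p)
  M1 <- generate_base_network(cfg$p, m = cfg$m, seed = sub_seed(cfg$seed, 1L))
  M1w <- assign_edge_weights(M1, cfg$value_range, seed = sub_seed(cfg$seed, 2L))
  Mw <- derive_state_networks(M1w, cfg$K, cfg$r, cfg$value_range,
                              seed = sub_seed(cfg$seed, 3L))
  G <- generate_prior_network(M1, cfg$eta, seed = sub_seed(cfg$seed, 4L))
  Theta <- build_precision(Mw, Q, cfg$pd_buffer)
  x <- lapply(seq_len(cfg$K), function(k) {
    xs <- sample_expression(Theta[[k]], cfg$n, seed = sub_seed(cfg$seed, 4L + k))
    rownames(xs) <- gene_names(cfg$p)
    xs
  })
  gene_ids <- gene_names(cfg$p)
  structure(list(
    x = x, pathways = pw, Q = Q, prior = G,
    truth = list(
      M = lapply(Mw, function(mw) (mw != 0) * 1),
      M_weighted = Mw,
      Theta = Theta,
      support = lapply(Theta, function(th) {
        s <- (th != 0) * 1; diag(s) <- 0; s
      })
    ),
    gene_ids = gene_ids, config = cfg
  ), class = "wfpgl_scenario")
}

#' @export
print.wfpgl_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("WFPGL benchmark scenario '%s'\n", cfg$preset))
  cat(sprintf("  p = %d genes, K = %d states, n = %d samples/state\n",
              cfg$p, cfg$K, cfg$n))
  cat(sprintf("  J = %d pathways (overlap %d), r = %g, eta = %g, seed = %d\n",
              cfg$J, cfg$n_ol, cfg$r, cfg$eta, cfg$seed))
  ne <- vapply(x$truth$Theta, function(th) sum(th[upper.tri(th)] != 0), numeric(1L))
  cat(sprintf("  true edges per state (after pathway masking): %s\n",
              paste(ne, collapse = ", ")))
  invisible(x)
}

gene_names <- function(p) sprintf("g%03d", seq_len(p))

# Deterministic sub-stream seeds derived from one root seed; kept within the
# 32-bit integer range.
sub_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009 + stream * 9973) %% 2147483647)
}
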