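# Multilayer (temporal) modularity maximization over a wPLI layer stack.
#
# Quality function (ordinal inter-layer coupling, node-layer partition g):
#   Q = (1/2mu) * sum_{ijsr} [ (A_ijs - gamma * k_is k_js / (2 m_s)) d_sr
#                              + d_ij * C_jsr ] * d(g_is, g_jr)
# with C_jsr = omega for |s - r| = 1 and 0 otherwise, k node strength,
# m_s layer weight, and 2mu = sum_s 2 m_s + 2 * omega * N * (L - 1).
# The intra-layer null model is the weighted Newman-Girvan strength
# product; community labels are global across layers by construction of
# the supra-graph optimization.

as_layer_list <- function(layers) {
  if (inherits(layers, "connectivity_series")) layers$layers
  else if (is.list(layers)) layers
  else param_error("layers must be a connectivity_series or list of matrices")
}

#' Parameters of the multilayer optimization
#'
#' @param gamma Structural resolution (> 0). Default is the preset value
#'   1.1364 selected for this analysis design.
#' @param omega Temporal (inter-layer) coupling (>= 0), default 0.5.
#' @param n_iterations Ensemble size for repeated detection, default 100.
#' @param seed Master seed.
#' @return A `multilayer_params` list.
#' @export
multilayer_params <- function(gamma = 1.1364, omega = 0.5,
                              n_iterations = 100, seed = 1) {
  if (!is.finite(gamma) || gamma <= 0) param_error("gamma must be > 0")
  if (!is.finite(omega) || omega < 0) param_error("omega must be >= 0")
  if (n_iterations < 1) param_error("n_iterations must be >= 1")
  structure(list(gamma = gamma, omega = omega,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "multilayer_params")
}

# supra modularity matrix B (N*L x N*L, node index fastest) and 2mu
build_supra_modularity <- function(layers, gamma, omega) {
  lay <- as_layer_list(layers)
  L <- length(lay)
  N <- nrow(lay[[1]])
  n <- N * L
  B <- matrix(0, n, n)
  twom_sum <- 0
  for (t in seq_len(L)) {
    A <- as.matrix(lay[[t]])
    if (!all(is.finite(A))) param_error("non-finite weights in layer %d", t)
    k <- colSums(A)
    m2 <- sum(k)
    idx <- ((t - 1) * N + 1):(t * N)
    if (m2 > 0) {
      B[idx, idx] <- A - gamma * outer(k, k) / m2
    } else {
      warning(sprintf("layer %d has zero total weight; null term skipped", t))
      B[idx, idx] <- A
    }
    twom_sum <- twom_sum + m2
  }
  if (L > 1 && omega > 0) {
    for (t in seq_len(L - 1)) {
      i1 <- ((t - 1) * N + 1):(t * N)
      i2 <- (t * N + 1):((t + 1) * N)
      B[cbind(i1, i2)] <- B[cbind(i1, i2)] + omega
      B[cbind(i2, i1)] <- B[cbind(i2, i1)] + omega
    }
  }
  list(B = B, twomu = twom_sum + 2 * omega * N * (L - 1), N = N, L = L)
}

#' Multilayer modularity of a given partition
#'
#' Evaluates Q for an explicit node x layer label matrix.
#'
#' @param layers A `connectivity_series` or list of symmetric matrices.
#' @param labels N x L positive-integer community labels.
#' @param params A [multilayer_params()] (gamma/omega are used).
#' @return The modularity value Q.
#' @export
multilayer_modularity <- function(layers, labels, params = multilayer_params()) {
  if (inherits(labels, "community_sequence")) labels <- labels$labels
  labels <- as.matrix(labels)
  sup <- build_supra_modularity(layers, params$gamma, params$omega)
  if (nrow(labels) != sup$N || ncol(labels) != sup$L)
    param_error("labels (%d x %d) do not match layers (%d nodes x %d layers)",
                nrow(labels), ncol(labels), sup$N, sup$L)
  g <- as.vector(labels)  # node index fastest, matching supra order
  total <- 0
  for (c in unique(g)) {
    idx <- which(g == c)
    total <- total + sum(sup$B[idx, idx])
  }
  total / sup$twomu
}

new_community_sequence <- function(labels, Q, params, node_labels = NULL) {
  if (!is.null(node_labels)) rownames(labels) <- node_labels
  structure(list(labels = labels, Q = Q, params = params,
                 n_nodes = nrow(labels), n_layers = ncol(labels)),
            class = "community_sequence")
}

#' @export
print.community_sequence <- function(x, ...) {
  cat(sprintf("<community_sequence> %d nodes x %d layers, %d communities, Q = %.4f\n",
              x$n_nodes, x$n_layers, length(unique(as.vector(x$labels))), x$Q))
  invisible(x)
}

#' Louvain-style multilayer community detection
#'
#' Greedy node-move plus aggregation passes over the multilayer
#' supra-graph until no single node-layer move increases Q (moves with
#' gain <= 1e-12 are rejected; visit order is randomized by `seed`).
#' Returned labels are globally consistent identifiers across layers:
#' the identity of a community persists through the inter-layer
#' coupling, which is what makes flexibility meaningful.
#'
#' @param layers A `connectivity_series` or list of symmetric matrices
#'   (N >= 2 nodes, L >= 2 layers for dynamics).
#' @param params A [multilayer_params()].
#' @param seed Seed for this run (defaults to `params$seed`).
#' @return A `community_sequence` with `labels` (N x L) and `Q`.
#' @export
louvain_multilayer <- function(layers, params = multilayer_params(),
                               seed = params$seed) {
  lay <- as_layer_list(layers)
  if (nrow(lay[[1]]) < 2) param_error("need N >= 2 nodes")
  sup <- build_supra_modularity(layers, params$gamma, params$omega)
  res <- cpp_louvain(sup$B, as.integer(seed))
  labels <- matrix(res$labels, sup$N, sup$L)
  node_labels <- if (inherits(layers, "connectivity_series")) layers$labels
                 else rownames(lay[[1]])
  new_community_sequence(labels, res$total / sup$twomu, params, node_labels)
}

#' Per-layer node-identity shuffled null stack
#'
#' Each layer's node identities are permuted independently (rows and
#' columns co-permuted per layer), preserving every layer's weight
#' distribution while destroying the alignment of nodes across layers.
#'
#' @param layers A `connectivity_series` or list of matrices, `L >= 2`.
#' @param seed RNG seed.
#' @return Same container type with shuffled layers.
#' @export
shuffled_null <- function(layers, seed = 1) {
  lay <- as_layer_list(layers)
  if (length(lay) < 2)
    param_error("shuffled null needs L >= 2 layers (nothing to de-align)")
  set.seed(seed)
  out <- lapply(lay, function(A) {
    p <- sample.int(nrow(A))
    A[p, p, drop = FALSE]
  })
  if (inherits(layers, "connectivity_series")) {
    s <- layers
    s$layers <- out
    s
  } else out
}

#' Repeated seeded detection ensemble
#'
#' The optimization is susceptible to multiple near-optimal solutions,
#' so it is repeated `params$n_iterations` times with derived seeds and
#' downstream metrics are averaged over the ensemble.
#'
#' @param layers A `connectivity_series` or list of matrices.
#' @param params A [multilayer_params()].
#' @return List of `community_sequence` objects, one per iteration.
#' @export
repeat_detection <- function(layers, params = multilayer_params()) {
  lapply(seq_len(params$n_iterations), function(i)
    louvain_multilayer(layers, params, seed = derive_seed(params$seed, i)))
}

#' Sweep (gamma, omega) against a shuffled null
#'
#' Per grid cell: mean Q over `n_runs` detections on the real stack and
#' over `n_null` independently shuffled stacks, plus the mean community
#' count. The selected cell maximizes `Q_real - Q_null` subject to a
#' mean community count > 1.
#'
#' @param layers A `connectivity_series` or list of matrices.
#' @param gamma_grid,omega_grid Numeric grids (defaults: gamma 0.9 to
#'   1.3 step 0.05; omega `c(0.1, 0.25, 0.5, 0.75, 1)`).
#' @param n_null Number of shuffled null stacks per cell (default 5).
#' @param n_runs Detection repetitions per cell (default 5).
#' @param seed Master seed.
#' @return A `sweep_result`: data frame grid with `q_real`, `q_null`,
#'   `mean_n_communities`, and the `selected` (gamma, omega).
#' @export
sweep_parameters <- function(layers, gamma_grid = seq(0.9, 1.3, by = 0.05),
                             omega_grid = c(0.1, 0.25, 0.5, 0.75, 1),
                             n_null = 5, n_runs = 5, seed = 1) {
  if (!length(gamma_grid) || !length(omega_grid))
    param_error("parameter grids must be nonempty")
  grid <- expand.grid(gamma = gamma_grid, omega = omega_grid)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    g <- grid$gamma[r]
    w <- grid$omega[r]
    p <- multilayer_params(gamma = g, omega = w, n_iterations = 1)
    runs <- lapply(seq_len(n_runs), function(i)
      louvain_multilayer(layers, p, seed = derive_seed(seed, r * 1000L + i)))
    qr <- mean(vapply(runs, `[[`, 0, "Q"))
    nc <- mean(vapply(runs, function(x)
      length(unique(as.vector(x$labels))), 0))
    qn <- mean(vapply(seq_len(n_null), function(i) {
      null <- shuffled_null(layers, seed = derive_seed(seed, r * 2000L + i))
      louvain_multilayer(null, p, seed = derive_seed(seed, r * 3000L + i))$Q
    }, 0))
    data.frame(gamma = g, omega = w, q_real = qr, q_null = qn,
               delta_q = qr - qn, mean_n_communities = nc)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$mean_n_communities > 1
  if (!any(ok))
    param_error("no (gamma, omega) cell produced more than one community on average")
  sel <- tab[ok, ][which.max(tab$delta_q[ok]), ]
  structure(list(grid = tab,
                 selected = c(gamma = sel$gamma, omega = sel$omega),
                 seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cells; selected gamma = %g, omega = %g\n",
              nrow(x$grid), x$selected[["gamma"]], x$selected[["omega"]]))
  invisible(x)
}
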