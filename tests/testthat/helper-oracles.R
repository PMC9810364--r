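# Independent brute-force oracles for the dynamic network metrics.
# Deliberately naive (explicit loops over pairs/layers) so they share no
# code path with the implementations they check.

brute_flexibility <- function(lab) {
  L <- ncol(lab)
  xi <- numeric(nrow(lab))
  for (i in seq_len(nrow(lab))) {
    g <- 0L
    for (t in seq_len(L - 1)) if (lab[i, t] != lab[i, t + 1]) g <- g + 1L
    xi[i] <- g / (L - 1)
  }
  xi
}

brute_allegiance <- function(lab) {
  N <- nrow(lab)
  L <- ncol(lab)
  A <- diag(1, N)
  for (j in seq_len(N - 1)) for (k in (j + 1):N) {
    s <- 0L
    for (t in seq_len(L)) if (lab[j, t] == lab[k, t]) s <- s + 1L
    A[j, k] <- A[k, j] <- s / L
  }
  A
}

brute_intermittence <- function(lab) {
  N <- nrow(lab)
  L <- ncol(lab)
  M <- matrix(0, N, N)
  for (j in seq_len(N - 1)) for (k in (j + 1):N) {
    d <- as.integer(lab[j, ] == lab[k, ])
    s <- 0L
    for (t in seq_len(L - 1)) if (d[t] != d[t + 1]) s <- s + 1L
    M[j, k] <- M[k, j] <- s / (L - 1)
  }
  M
}

# bare dim-only matrix for exact comparisons against oracles
strip_attr <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

random_label_matrix <- function(N, L, K) {
  matrix(sample.int(K, N * L, replace = TRUE), N, L)
}

# small random symmetric weighted layer stack (zero diagonal)
random_layer_stack <- function(N, L, density = 0.6) {
  lapply(seq_len(L), function(t) {
    A <- matrix(0, N, N)
    ut <- upper.tri(A)
    w <- runif(sum(ut)) * (runif(sum(ut)) < density)
    A[ut] <- w
    A + t(A)
  })
}

# connectivity-like stack built directly from a planted schedule:
# same-community edges strong, others weak noise
stack_from_schedule <- function(sched, strong = 0.7, noise = 0.05) {
  lapply(seq_len(sched$n_layers), function(t) {
    same <- outer(sched$labels[, t], sched$labels[, t], "==")
    A <- ifelse(same, strong, 0) +
      matrix(runif(sched$n_nodes^2, 0, noise), sched$n_nodes)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    A
  })
}

as_series <- function(layers, band = band_definition("test", 8, 13),
                      window_seconds = 10) {
  phasecomm:::new_connectivity_series(layers, band, window_seconds,
                                      paste0("n", seq_len(nrow(layers[[1]]))))
}
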