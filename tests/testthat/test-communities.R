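# multilayer modularity, Louvain optimization, null model, sweep

two_cliques <- function(k = 3) {
  A <- matrix(0, 2 * k, 2 * k)
  A[1:k, 1:k] <- 1
  A[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(A) <- 0
  A
}

test_that("two disconnected cliques give Q = 0.5 at gamma 1, omega 0", {
  A <- two_cliques()
  lab <- matrix(c(1, 1, 1, 2, 2, 2), 6, 1)
  q <- multilayer_modularity(list(A), lab,
                             multilayer_params(gamma = 1, omega = 0))
  expect_equal(q, 0.5)
  # and the optimizer finds that partition
  cs <- louvain_multilayer(list(A, A),
                           multilayer_params(gamma = 1, omega = 0.5,
                                             seed = 2))
  expect_equal(adjusted_rand_index(cs$labels[, 1], lab[, 1]), 1)
})

test_that("omega = 0 decomposes Q into weighted per-layer modularities", {
  set.seed(61)
  layers <- random_layer_stack(6, 3)
  lab <- random_label_matrix(6, 3, 3)
  p0 <- multilayer_params(gamma = 1.1, omega = 0)
  q_multi <- multilayer_modularity(layers, lab, p0)
  # independent per-layer Newman-Girvan values, weighted by layer weight
  per_layer <- vapply(seq_along(layers), function(t)
    multilayer_modularity(layers[t], lab[, t, drop = FALSE], p0), 0)
  w <- vapply(layers, sum, 0)
  expect_equal(q_multi, sum(per_layer * w) / sum(w))
})

test_that("one-community Q matches brute-force evaluation on a random graph", {
  set.seed(62)
  A <- random_layer_stack(5, 1)[[1]]
  lab <- matrix(1L, 5, 1)
  q <- multilayer_modularity(list(A), lab, multilayer_params(gamma = 1,
                                                             omega = 0))
  # direct evaluation: (1/2m) sum_ij (A_ij - k_i k_j / 2m)
  k <- colSums(A)
  m2 <- sum(A)
  expect_equal(q, sum(A - outer(k, k) / m2) / m2)
})

test_that("Louvain Q matches exhaustive best-partition on small instances", {
  set.seed(63)
  hits <- 0L
  n_trials <- 24L
  for (i in seq_len(n_trials)) {
    N <- sample(4:6, 1)
    L <- if (N <= 4) sample(2:3, 1) else 2L
    layers <- random_layer_stack(N, L)
    gamma <- runif(1, 0.8, 1.3)
    omega <- runif(1, 0, 0.8)
    sup <- phasecomm:::build_supra_modularity(layers, gamma, omega)
    best <- phasecomm:::cpp_best_partition(sup$B)
    got <- phasecomm:::cpp_louvain(sup$B, seed = i)
    expect_lte(got$total, best$total + 1e-9)
    if (abs(got$total - best$total) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.9)
})

test_that("optimizer beats the trivial reference partitions", {
  set.seed(64)
  layers <- random_layer_stack(8, 3)
  p <- multilayer_params(gamma = 1, omega = 0.3, seed = 5)
  cs <- louvain_multilayer(layers, p)
  q_single <- multilayer_modularity(layers, matrix(1L, 8, 3), p)
  q_singletons <- multilayer_modularity(layers,
                                        matrix(rep(1:8, 3), 8, 3), p)
  expect_gte(cs$Q, q_single - 1e-12)
  expect_gte(cs$Q, q_singletons - 1e-12)
})

test_that("identical layers under strong coupling freeze all labels", {
  set.seed(65)
  A <- two_cliques(4) + 0.01
  diag(A) <- 0
  layers <- lapply(1:5, function(i) A)
  cs <- louvain_multilayer(layers, multilayer_params(gamma = 1, omega = 1,
                                                     seed = 3))
  expect_equal(flexibility(cs)$xi, rep(0, 8), ignore_attr = TRUE)
})

test_that("shuffled null preserves per-layer weights, destroys alignment", {
  set.seed(66)
  layers <- random_layer_stack(6, 4)
  null <- shuffled_null(layers, seed = 2)
  for (t in seq_along(layers))
    expect_equal(sort(null[[t]][upper.tri(null[[t]])]),
                 sort(layers[[t]][upper.tri(layers[[t]])]))
  expect_error(shuffled_null(layers[1]), "L >= 2")
  # planted stack: real beats null at matched parameters
  sched <- simulate_label_sequences(12, 8, 2, 0.05, seed = 8)
  stack <- stack_from_schedule(sched)
  p <- multilayer_params(gamma = 1.1, omega = 0.5)
  q_real <- mean(vapply(1:3, function(i)
    louvain_multilayer(stack, p, seed = i)$Q, 0))
  q_null <- mean(vapply(1:3, function(i)
    louvain_multilayer(shuffled_null(stack, seed = i), p, seed = i)$Q, 0))
  expect_gt(q_real, q_null)
})

test_that("parameter sweep selects sane cells and honors its constraint", {
  set.seed(67)
  sched <- simulate_label_sequences(10, 6, 2, 0.1, seed = 9)
  stack <- stack_from_schedule(sched)
  # degenerate single-cell grid
  sw1 <- sweep_parameters(stack, gamma_grid = 1.05, omega_grid = 0.5,
                          n_null = 2, n_runs = 2, seed = 3)
  expect_equal(unname(sw1$selected), c(1.05, 0.5))
  # gamma grid spanning the planted regime recovers the partition
  sw <- sweep_parameters(stack, gamma_grid = seq(0.8, 1.3, by = 0.1),
                         omega_grid = 0.5, n_null = 2, n_runs = 2,
                         seed = 4)
  p_sel <- multilayer_params(gamma = sw$selected[["gamma"]],
                             omega = sw$selected[["omega"]])
  cs <- louvain_multilayer(stack, p_sel, seed = 11)
  ari <- mean(vapply(seq_len(6), function(t)
    adjusted_rand_index(cs$labels[, t], sched$labels[, t]), 0))
  expect_gte(ari, 0.9)
  expect_error(sweep_parameters(stack, numeric(), 0.5), "nonempty")
})

test_that("repeated detection is seed-deterministic and stable", {
  sched <- simulate_label_sequences(10, 6, 2, 0.05, seed = 12)
  stack <- stack_from_schedule(sched)
  p <- multilayer_params(gamma = 1.1, omega = 0.5, n_iterations = 8,
                         seed = 13)
  e1 <- repeat_detection(stack, p)
  e2 <- repeat_detection(stack, p)
  expect_identical(lapply(e1, `[[`, "labels"), lapply(e2, `[[`, "labels"))
  expect_length(e1, 8)
  # single-iteration ensemble mean equals the single run
  p1 <- multilayer_params(gamma = 1.1, omega = 0.5, n_iterations = 1,
                          seed = 13)
  s1 <- repeat_detection(stack, p1)
  expect_equal(ensemble_mean(lapply(s1, allegiance)),
               allegiance(s1[[1]]), ignore_attr = TRUE)
  # between-run agreement on an easy instance
  aris <- vapply(2:8, function(i)
    adjusted_rand_index(as.vector(e1[[1]]$labels),
                        as.vector(e1[[i]]$labels)), 0)
  expect_gte(min(aris), 0.8)
})

test_that("increasing omega weakly decreases ensemble-mean flexibility", {
  set.seed(68)
  for (rep in 1:5) {
    sched <- simulate_label_sequences(8, 6, 2, 0.3, seed = 100 + rep)
    stack <- stack_from_schedule(sched, strong = 0.5, noise = 0.15)
    fx <- vapply(c(0.1, 0.5, 2), function(w) {
      p <- multilayer_params(gamma = 1, omega = w, n_iterations = 4,
                             seed = 50 + rep)
      ens <- repeat_detection(stack, p)
      mean(ensemble_mean(lapply(ens, function(e) flexibility(e)$xi)))
    }, 0)
    expect_true(all(diff(fx) <= 1e-9))
  }
})

test_that("empty layers are tolerated with a warning", {
  layers <- list(two_cliques(), matrix(0, 6, 6), two_cliques())
  expect_warning(
    q <- multilayer_modularity(layers, matrix(1L, 6, 3),
                               multilayer_params(gamma = 1, omega = 0.1)),
    "zero total weight")
  expect_true(is.finite(q))
})
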