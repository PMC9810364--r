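# bootstrap machinery

test_that("bootstrap of a constant collapses to a point", {
  bt <- bootstrap_mean(c(2, 2, 2), n = 500, seed = 1)
  expect_true(all(bt$replicates == 2))
  expect_equal(unname(diff(bt$ci)), 0)
  expect_error(bootstrap_mean(numeric(0)), "non-empty")
})

test_that("bootstrap replicates are seed-deterministic and order-invariant", {
  v <- rnorm(50)
  b1 <- bootstrap_mean(v, n = 1000, seed = 7)
  b2 <- bootstrap_mean(v, n = 1000, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  d1 <- bootstrap_group_difference(v, v + 1, n = 1000, seed = 7)
  d2 <- bootstrap_group_difference(v, v + 1, n = 1000, seed = 7)
  expect_identical(d1$replicates, d2$replicates)
})

test_that("bootstrap CI coverage is near nominal", {
  set.seed(17)
  hits <- 0L
  n_outer <- 200L
  for (i in seq_len(n_outer)) {
    x <- rnorm(200)
    bt <- bootstrap_mean(x, n = 400, seed = i)
    if (bt$ci[1] <= 0 && 0 <= bt$ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_outer, 0.92)
  expect_lte(hits / n_outer, 0.98)
})

test_that("group difference p-values behave under null, power, symmetry", {
  set.seed(18)
  x <- rnorm(60)
  # identical groups: mostly non-significant across seeds
  ps <- vapply(1:20, function(s)
    bootstrap_group_difference(x, x, n = 500, seed = s)$p, 0)
  expect_gte(mean(ps > 0.05), 0.95)
  # strong planted shift: decisive
  a <- rnorm(200, mean = 5)
  b <- rnorm(100)
  expect_lt(bootstrap_group_difference(a, b, n = 2000, seed = 3)$p, 0.001)
  # antisymmetry: swapping groups negates the distribution, same p
  d1 <- bootstrap_group_difference(a, b, n = 1000, seed = 4)
  d2 <- bootstrap_group_difference(b, a, n = 1000, seed = 4)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$estimate, -d2$estimate)
  # p floored at 1/n, never 0
  expect_gte(d1$p, 1 / 1000)
})

test_that("flexibility comparison flags a planted positive NC-C effect", {
  set.seed(19)
  flex_of <- function(rate, n_subj, seed0)
    t(vapply(seq_len(n_subj), function(s)
      flexibility(simulate_label_sequences(10, 200, 3, rate,
                                           seed = seed0 + s)$labels)$xi,
      numeric(10)))
  flex <- rbind(flex_of(0.3, 12, 100), flex_of(0.1, 12, 200))
  groups <- rep(c("NC", "C"), each = 12)
  res <- flexibility_comparison(flex, groups, n = 2000, seed = 5)
  expect_true(all(res$diff > 0))
  expect_gte(mean(res$significant), 0.5)
  # equal rates: no systematic sign (sign test)
  flex0 <- rbind(flex_of(0.2, 12, 300), flex_of(0.2, 12, 400))
  res0 <- flexibility_comparison(flex0, groups, n = 500, seed = 6)
  n_pos <- sum(res0$diff > 0)
  expect_gt(binom.test(n_pos, nrow(res0))$p.value, 0.05)
  expect_error(flexibility_comparison(flex, rep("X", 24)),
               "'C' or 'NC'")
  # one group entirely absent: sensors skipped with warnings, empty result
  w <- testthat::capture_warnings(
    empty <- flexibility_comparison(flex, rep("NC", 24), n = 100))
  expect_match(w, "skipped", all = TRUE)
  expect_equal(nrow(empty), 0)
})

test_that("intermittence curve thresholds, masks and counts pairs", {
  set.seed(20)
  mk_pairs <- function(group, inter_mean, n = 300)
    data.frame(group = group,
               allegiance = runif(n),
               intermittence = pmin(pmax(rnorm(n, inter_mean, 0.02), 0), 1))
  pairs <- rbind(mk_pairs("NC", 0.30), mk_pairs("C", 0.20))
  cur <- intermittence_curve(pairs, thresholds = seq(0, 0.9, by = 0.1),
                             n = 500, seed = 2)
  defined <- !is.na(cur$significant)
  expect_true(all(cur$diff[defined] > 0))
  expect_equal(attr(cur, "significant_fraction"), 100)
  # identical groups: not everything significant
  null_pairs <- rbind(mk_pairs("NC", 0.25), mk_pairs("C", 0.25))
  cur0 <- intermittence_curve(null_pairs,
                              thresholds = seq(0, 0.9, by = 0.1),
                              n = 500, seed = 3)
  expect_lte(attr(cur0, "significant_fraction"), 30)
  # min_pairs exclusion: single sparse cell
  sparse <- rbind(mk_pairs("NC", 0.3, n = 5), mk_pairs("C", 0.3, n = 300))
  cs <- intermittence_curve(sparse, thresholds = 0.5, n = 100, seed = 4,
                            min_pairs = 10)
  expect_true(is.na(cs$p))
  # one-cell grid: fraction is 0 or 100
  c1 <- intermittence_curve(pairs, thresholds = 0.2, n = 500, seed = 5)
  expect_true(attr(c1, "significant_fraction") %in% c(0, 100))
})

test_that("CoV comparison resamples subjects and flags planted effects", {
  set.seed(21)
  # cells at least as large as the replica size keep the subject-level
  # bootstrap calibrated under the null
  mk_cell <- function(g, ctx, mu, n = 40)
    data.frame(subject_id = paste0(g, ctx, seq_len(n)), group = g,
               context = ctx, value = rnorm(n, mu, 0.05))
  # context effect planted for group C only
  d <- rbind(mk_cell("C", "social_media", 0.60),
             mk_cell("C", "in_person", 0.40),
             mk_cell("NC", "social_media", 0.50),
             mk_cell("NC", "in_person", 0.50))
  res <- cov_comparison(d, n_replicas = 400, replica_size = 30, seed = 3)
  ctx_c <- res[res$comparison == "context within C", ]
  expect_lt(ctx_c$p, 0.05)
  expect_true(ctx_c$stars %in% c("*", "**"))
  # global null: nothing systematically flagged
  d0 <- rbind(mk_cell("C", "social_media", 0.5),
              mk_cell("C", "in_person", 0.5),
              mk_cell("NC", "social_media", 0.5),
              mk_cell("NC", "in_person", 0.5))
  res0 <- cov_comparison(d0, n_replicas = 400, replica_size = 30, seed = 4)
  expect_gte(sum(res0$p > 0.05), 3)
  # replica_size larger than the cell is allowed (with replacement)
  small <- do.call(rbind, lapply(split(d, seq_len(nrow(d))), identity))
  res_big <- cov_comparison(d, n_replicas = 50, replica_size = 100,
                            seed = 5)
  expect_true(all(is.finite(res_big$p)))
  expect_error(cov_comparison(d[1, , drop = FALSE]), "fewer than 2")
})
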