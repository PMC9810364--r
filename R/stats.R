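# Bootstrap machinery for group comparisons of unequal sizes.
#
# Group comparisons resample within each group with replacement (10,000
# draws by default), form replicate means (or mean differences), and
# report percentile 95% confidence intervals. The two-sided p of a
# difference is twice the smaller tail mass of the replicate difference
# distribution at zero, floored at 1/n so it is never exactly 0.

new_bootstrap_result <- function(replicates, estimate, n, seed) {
  ci <- unname(quantile(replicates, c(0.025, 0.975), type = 7))
  frac_le <- mean(replicates <= 0)
  frac_ge <- mean(replicates >= 0)
  p <- max(2 * min(frac_le, frac_ge), 1 / n)
  p <- min(p, 1)
  structure(list(replicates = replicates, estimate = estimate,
                 ci = ci, p = p, n_replicates = n, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> estimate %.4g, 95%% CI [%.4g, %.4g], p = %.3g (%d replicates)\n",
              x$estimate, x$ci[1], x$ci[2], x$p, x$n_replicates))
  invisible(x)
}

#' Bootstrap distribution of a sample mean
#'
#' @param values Non-empty numeric vector.
#' @param n Number of bootstrap draws (default 10000).
#' @param seed RNG seed.
#' @return A `bootstrap_result` (the `p` field tests mean != 0 and is
#'   rarely meaningful for a single group).
#' @export
bootstrap_mean <- function(values, n = 10000, seed = 1) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values))
    param_error("values must be non-empty and NA-free")
  set.seed(seed)
  idx <- matrix(sample.int(length(values), length(values) * n,
                           replace = TRUE), ncol = n)
  reps <- colMeans(matrix(values[idx], ncol = n))
  new_bootstrap_result(reps, mean(values), n, seed)
}

#' Bootstrap distribution of a group mean difference (A - B)
#'
#' Each replicate resamples both groups independently (with
#' replacement, at their own sizes) and records the difference of the
#' replicate means.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param n Number of bootstrap draws (default 10000).
#' @param seed RNG seed.
#' @return A `bootstrap_result` for the difference mean(A) - mean(B).
#' @export
bootstrap_group_difference <- function(group_a, group_b, n = 10000,
                                       seed = 1) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) == 0 || length(group_b) == 0)
    param_error("both groups must be non-empty")
  if (anyNA(group_a) || anyNA(group_b)) param_error("groups contain NA")
  set.seed(seed)
  na <- length(group_a)
  nb <- length(group_b)
  ia <- matrix(sample.int(na, na * n, replace = TRUE), ncol = n)
  ib <- matrix(sample.int(nb, nb * n, replace = TRUE), ncol = n)
  reps <- colMeans(matrix(group_a[ia], ncol = n)) -
          colMeans(matrix(group_b[ib], ncol = n))
  new_bootstrap_result(reps, mean(group_a) - mean(group_b), n, seed)
}

#' Per-sensor bootstrap comparison of flexibility between groups
#'
#' For every sensor, the NC - C difference in mean flexibility is
#' bootstrapped; positive differences indicate increased flexibility
#' for the no-change group.
#'
#' @param flex Subjects x sensors numeric matrix of flexibility values.
#' @param groups Character/factor vector per subject, values `"C"` /
#'   `"NC"`.
#' @param n Bootstrap draws per sensor (default 10000).
#' @param seed Master seed.
#' @param alpha Significance level for the flag (default 0.05).
#' @return Data frame: `sensor`, `diff` (NC - C), `ci_lo`, `ci_hi`,
#'   `p`, `significant`.
#' @export
flexibility_comparison <- function(flex, groups, n = 10000, seed = 1,
                                   alpha = 0.05) {
  flex <- as.matrix(flex)
  groups <- as.character(groups)
  if (length(groups) != nrow(flex))
    param_error("one group label per subject row required")
  if (!all(groups %in% c("C", "NC")))
    param_error("groups must be 'C' or 'NC'")
  sensors <- colnames(flex) %||% paste0("s", seq_len(ncol(flex)))
  rows <- lapply(seq_len(ncol(flex)), function(j) {
    a <- flex[groups == "NC", j]
    b <- flex[groups == "C", j]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) {
      warning(sprintf("sensor %s missing one group; skipped", sensors[j]))
      return(NULL)
    }
    bt <- bootstrap_group_difference(a, b, n, seed = derive_seed(seed, j))
    data.frame(sensor = sensors[j], diff = bt$estimate,
               ci_lo = bt$ci[1], ci_hi = bt$ci[2], p = bt$p,
               significant = bt$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sensor = character(), diff = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(), p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  out
}

#' Allegiance-thresholded intermittence difference curve
#'
#' At each allegiance threshold, the NC - C difference in mean
#' intermittence is bootstrapped using only pairs whose allegiance is
#' strictly above the threshold. Cells where either group retains fewer
#' than `min_pairs` pairs are undefined and excluded from the
#' significant-fraction denominator.
#'
#' @param pairs Data frame with columns `group` (`"C"`/`"NC"`),
#'   `allegiance`, `intermittence` (pooled node pairs).
#' @param thresholds Threshold grid (default 0 to 1 step 0.01).
#' @param n Bootstrap draws per threshold (default 10000).
#' @param seed Master seed.
#' @param min_pairs Minimal pairs per group per cell (default 10).
#' @param alpha Significance level (default 0.05).
#' @return A `threshold_curve`: data frame (`threshold`, `diff`,
#'   `ci_lo`, `ci_hi`, `p`, `significant`, `n_nc`, `n_c`) with
#'   attribute `significant_fraction` (percent of defined cells
#'   significant).
#' @export
intermittence_curve <- function(pairs, thresholds = seq(0, 1, by = 0.01),
                                n = 10000, seed = 1, min_pairs = 10,
                                alpha = 0.05) {
  stopifnot(all(c("group", "allegiance", "intermittence") %in% names(pairs)))
  if (!all(pairs$group %in% c("C", "NC")))
    param_error("pair groups must be 'C' or 'NC'")
  rows <- lapply(seq_along(thresholds), function(k) {
    thr <- thresholds[k]
    a <- pairs$intermittence[pairs$group == "NC" & pairs$allegiance > thr]
    b <- pairs$intermittence[pairs$group == "C" & pairs$allegiance > thr]
    if (length(a) < min_pairs || length(b) < min_pairs)
      return(data.frame(threshold = thr, diff = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                        significant = NA, n_nc = length(a),
                        n_c = length(b)))
    bt <- bootstrap_group_difference(a, b, n, seed = derive_seed(seed, k))
    data.frame(threshold = thr, diff = bt$estimate, ci_lo = bt$ci[1],
               ci_hi = bt$ci[2], p = bt$p, significant = bt$p < alpha,
               n_nc = length(a), n_c = length(b))
  })
  tab <- do.call(rbind, rows)
  defined <- !is.na(tab$significant)
  frac <- if (any(defined))
    100 * sum(tab$significant[defined]) / sum(defined)
  else NA_real_
  structure(tab, significant_fraction = frac, class = c("threshold_curve",
                                                        "data.frame"))
}

#' Bootstrap comparison of session CoV across groups and contexts
#'
#' Replicates are formed at the subject level: each of `n_replicas`
#' replicas draws `replica_size` subjects with replacement from a cell
#' (group x context) and records the replica mean CoV. Comparisons are
#' within-context between groups and within-group between contexts;
#' stars flag p < 0.05 (`*`) and p < 0.005 (`**`). `replica_size`
#' larger than the cell is allowed (sampling is with replacement).
#'
#' @param cov_values Data frame with columns `subject_id`, `group`
#'   (`"C"`/`"NC"`), `context`, `value` (session mean CoV).
#' @param n_replicas Replicas per cell (default 1000).
#' @param replica_size Subjects per replica (default 30).
#' @param seed Master seed.
#' @return Data frame: `comparison`, `cell_a`, `cell_b`, `estimate`,
#'   `p`, `stars`.
#' @export
cov_comparison <- function(cov_values, n_replicas = 1000,
                           replica_size = 30, seed = 1) {
  stopifnot(all(c("subject_id", "group", "context", "value") %in%
                names(cov_values)))
  contexts <- unique(cov_values$context)
  groups <- unique(cov_values$group)
  cell <- function(g, ctx)
    cov_values$value[cov_values$group == g & cov_values$context == ctx]
  for (g in groups) for (ctx in contexts)
    if (length(cell(g, ctx)) < 2)
      param_error("cell (%s, %s) has fewer than 2 subjects", g, ctx)
  replicas <- function(v, s) {
    set.seed(s)
    colMeans(matrix(v[sample.int(length(v), replica_size * n_replicas,
                                 replace = TRUE)], ncol = n_replicas))
  }
  cmp <- list()
  k <- 0L
  add <- function(label, na, nb, va, vb) {
    k <<- k + 1L
    ra <- replicas(va, derive_seed(seed, 2L * k))
    rb <- replicas(vb, derive_seed(seed, 2L * k + 1L))
    d <- ra - rb
    p <- max(2 * min(mean(d <= 0), mean(d >= 0)), 1 / n_replicas)
    p <- min(p, 1)
    cmp[[k]] <<- data.frame(comparison = label, cell_a = na, cell_b = nb,
                            estimate = mean(va) - mean(vb), p = p,
                            stars = if (p < 0.005) "**"
                                    else if (p < 0.05) "*" else "",
                            stringsAsFactors = FALSE)
  }
  if (length(groups) == 2)
    for (ctx in contexts)
      add(paste0("group within ", ctx),
          paste0(groups[1], ":", ctx), paste0(groups[2], ":", ctx),
          cell(groups[1], ctx), cell(groups[2], ctx))
  if (length(contexts) == 2)
    for (g in groups)
      add(paste0("context within ", g),
          paste0(g, ":", contexts[1]), paste0(g, ":", contexts[2]),
          cell(g, contexts[1]), cell(g, contexts[2]))
  do.call(rbind, cmp)
}
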