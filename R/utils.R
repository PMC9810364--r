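#' Round half away from zero
#'
#' Percentages are reported to a fixed number of decimals with half-up
#' rounding (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Adjusted Rand index between two label vectors
#'
#' Chance-corrected agreement between two partitions; 1 for identical
#' partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b Integer/factor label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Two-by-two chi-squared test of independence
#'
#' Utility wired for contingency analyses of change coding; not tied to
#' any specific published table. Continuity correction off by default.
#'
#' @param tab 2x2 integer matrix of counts.
#' @param correct Apply Yates continuity correction.
#' @return `htest` object from [stats::chisq.test()].
#' @export
chisq_2x2 <- function(tab, correct = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)))
  stats::chisq.test(tab, correct = correct)
}

# stop() with a consistent prefix for user parameter errors
param_error <- function(...) stop(sprintf(...), call. = FALSE)

# integer sub-seed derived from a master seed; stays below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 100003L
}
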