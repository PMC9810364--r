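# Node and pair dynamics of a community label sequence.
#
#   flexibility    xi_i = g_i / (L - 1), g_i = # boundaries where node i
#                  changes community
#   allegiance     a_jk = (1/L) sum_t 1[C_j(t) == C_k(t)]
#   intermittence  I_jk = (1/(L-1)) sum_t |d_{t+1} - d_t|, d_t the
#                  shared-community indicator of the pair
#
# Intermittence separates bursty from block-like co-affiliation at
# equal allegiance: a pair together in two long blocks and a pair
# alternating rapidly can both have allegiance 0.5, but the alternating
# pair has intermittence near 1 and the block pair near 0.

get_label_matrix <- function(seq) {
  if (inherits(seq, "community_sequence")) seq$labels
  else if (is.matrix(seq)) seq
  else param_error("expected a community_sequence or label matrix")
}

#' Node flexibility
#'
#' @param seq A `community_sequence` or N x L label matrix (`L >= 2`).
#' @return List with `xi` (per-node flexibility in \[0,1\]), `g`
#'   (per-node switch counts) and `L`.
#' @export
flexibility <- function(seq) {
  lab <- get_label_matrix(seq)
  L <- ncol(lab)
  if (L < 2) param_error("flexibility needs L >= 2 layers, got %d", L)
  g <- rowSums(lab[, -1, drop = FALSE] != lab[, -L, drop = FALSE])
  xi <- g / (L - 1)
  names(xi) <- names(g) <- rownames(lab)
  list(xi = xi, g = as.integer(g), L = L)
}

# stack of per-layer same-community indicator matrices
same_community_stack <- function(lab) {
  N <- nrow(lab)
  L <- ncol(lab)
  lapply(seq_len(L), function(t) {
    onehot <- outer(lab[, t], lab[, t], "==")
    storage.mode(onehot) <- "double"
    onehot
  })
}

#' Pair allegiance matrix
#'
#' @param seq A `community_sequence` or N x L label matrix (`L >= 1`).
#' @return Symmetric N x N matrix in \[0,1\], diagonal 1, with
#'   attribute `kind = "allegiance"`.
#' @export
allegiance <- function(seq) {
  lab <- get_label_matrix(seq)
  S <- same_community_stack(lab)
  A <- Reduce(`+`, S) / length(S)
  dimnames(A) <- list(rownames(lab), rownames(lab))
  structure(A, kind = "allegiance")
}

#' Pair intermittence matrix
#'
#' Fraction of layer boundaries at which the pair's shared-community
#' indicator flips (together <-> apart).
#'
#' @param seq A `community_sequence` or N x L label matrix (`L >= 2`).
#' @return Symmetric N x N matrix in \[0,1\], diagonal 0, with
#'   attribute `kind = "intermittence"`.
#' @export
intermittence <- function(seq) {
  lab <- get_label_matrix(seq)
  L <- ncol(lab)
  if (L < 2) param_error("intermittence needs L >= 2 layers, got %d", L)
  S <- same_community_stack(lab)
  M <- matrix(0, nrow(lab), nrow(lab))
  for (t in seq_len(L - 1)) M <- M + abs(S[[t + 1]] - S[[t]])
  M <- M / (L - 1)
  diag(M) <- 0
  dimnames(M) <- list(rownames(lab), rownames(lab))
  structure(M, kind = "intermittence")
}

#' Element-wise mean of a metric over a detection ensemble
#'
#' Downstream results use the mean of each metric over the repeated
#' detection runs.
#'
#' @param metrics List of numeric vectors/matrices of identical shape
#'   (e.g. `lapply(ensemble, allegiance)`).
#' @return Same shape, element-wise mean.
#' @export
ensemble_mean <- function(metrics) {
  if (!is.list(metrics) || length(metrics) == 0)
    param_error("need a nonempty list of metric values")
  dims <- lapply(metrics, dim)
  lens <- vapply(metrics, length, 0L)
  if (length(unique(lens)) != 1 ||
      !all(vapply(dims, identical, TRUE, dims[[1]])))
    param_error("metric shapes differ across the ensemble")
  Reduce(`+`, metrics) / length(metrics)
}

#' Select pair intermittence values above an allegiance threshold
#'
#' Off-diagonal upper-triangle intermittence values whose paired
#' allegiance is *strictly* greater than the threshold.
#'
#' @param allegiance_m,intermittence_m Symmetric matrices of equal shape.
#' @param threshold Allegiance threshold in \[0,1\].
#' @return Numeric vector of selected intermittence values.
#' @export
threshold_by_allegiance <- function(allegiance_m, intermittence_m,
                                    threshold) {
  if (!all(dim(allegiance_m) == dim(intermittence_m)))
    param_error("matrices must have the same shape")
  if (threshold < 0 || threshold > 1)
    param_error("threshold must be in [0, 1]")
  ut <- upper.tri(allegiance_m)
  intermittence_m[ut][allegiance_m[ut] > threshold]
}

#' Long-format pair metric table
#'
#' Tidy table (one row per unordered node pair) of allegiance and
#' intermittence, the interchange format of the statistics stage.
#'
#' @param allegiance_m,intermittence_m Symmetric matrices of equal shape.
#' @return Data frame with `node_a`, `node_b`, `allegiance`,
#'   `intermittence`.
#' @export
pair_metric_table <- function(allegiance_m, intermittence_m) {
  if (!all(dim(allegiance_m) == dim(intermittence_m)))
    param_error("matrices must have the same shape")
  n <- nrow(allegiance_m)
  labs <- rownames(allegiance_m) %||% paste0("n", seq_len(n))
  ut <- which(upper.tri(allegiance_m), arr.ind = TRUE)
  data.frame(node_a = labs[ut[, 1]], node_b = labs[ut[, 2]],
             allegiance = allegiance_m[ut],
             intermittence = intermittence_m[ut],
             stringsAsFactors = FALSE)
}
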