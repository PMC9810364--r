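# Band-limited phase connectivity: filter -> window -> wPLI stack -> CoV.
#
# The weighted phase lag index between channels i and j is
#   Phi_ij = |E{ Im X_ij }| / E{ |Im X_ij| },
# with X_ij the cross-spectrum of the analytic (Hilbert) signals of the
# band-filtered channels and E{.} the sample mean within one window.
# The absolute value in the numerator makes Phi blind to zero-lag
# (volume-conducted) coupling: symmetric positive/negative imaginary
# parts cancel, while a consistent non-zero lag gives Phi near 1.

#' Band-pass filter a recording (zero phase)
#'
#' Order-3 Butterworth band-pass applied forward and reverse
#' (zero-phase) to every channel.
#'
#' @param rec An [eeg_recording()].
#' @param band A [band_definition()].
#' @return Filtered `eeg_recording`, same shape and labels.
#' @export
bandpass_filter <- function(rec, band) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_definition"))
  if (band$high >= rec$rate / 2)
    param_error("band %s (%g-%g Hz) exceeds Nyquist %g Hz",
                band$name, band$low, band$high, rec$rate / 2)
  f <- butter_bandpass(band$low, band$high, rec$rate)
  out <- rec$data
  for (i in seq_len(nrow(out)))
    out[i, ] <- filtfilt_iir(f$b, f$a, rec$data[i, ])
  eeg_recording(out, rec$rate, rec$labels)
}

#' Cut a recording into non-overlapping windows
#'
#' Consecutive blocks of exactly `window_seconds * rate` samples; a
#' trailing remainder shorter than one window is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param window_seconds Window length in seconds (default 10).
#' @return List of channels x samples matrices.
#' @export
window_signal <- function(rec, window_seconds = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(window_seconds) || window_seconds <= 0)
    param_error("window_seconds must be > 0")
  spw <- floor(window_seconds * rec$rate)
  if (spw < 2) param_error("window holds fewer than 2 samples")
  nwin <- floor(ncol(rec$data) / spw)
  if (nwin < 1)
    param_error("recording (%.1f s) shorter than one %g-s window",
                duration_seconds(rec), window_seconds)
  lapply(seq_len(nwin), function(w)
    rec$data[, ((w - 1) * spw + 1):(w * spw), drop = FALSE])
}

#' Weighted phase lag index matrix of one window
#'
#' @param block Band-filtered channels x samples matrix.
#' @param labels Optional channel labels for dimnames.
#' @return Symmetric N x N matrix of wPLI values in \[0,1\], zero diagonal.
#'   The degenerate case `E{|Im X|} = 0` (pure zero-lag coupling) maps
#'   to 0 by convention.
#' @export
wpli_matrix <- function(block, labels = NULL) {
  block <- as.matrix(block)
  if (nrow(block) < 2) param_error("need at least 2 channels")
  if (!all(is.finite(block))) param_error("non-finite samples in block")
  n <- nrow(block)
  Z <- t(apply(block, 1, hilbert_analytic))
  phi <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      im <- Im(Z[i, ] * Conj(Z[j, ]))
      den <- mean(abs(im))
      phi[i, j] <- phi[j, i] <- if (den == 0) 0 else abs(mean(im)) / den
    }
  }
  if (!is.null(labels)) dimnames(phi) <- list(labels, labels)
  phi
}

#' Windowed wPLI connectivity stacks per band
#'
#' Filter -> window -> wPLI per window, for each requested band. All
#' bands share the same layer count L.
#'
#' @param rec An [eeg_recording()].
#' @param bands List of [band_definition()]s (default [default_bands()]).
#' @param window_seconds Window length in seconds (default 10).
#' @return Named list of `connectivity_series` objects, each holding the
#'   ordered list of L symmetric matrices.
#' @export
connectivity_series <- function(rec, bands = default_bands(),
                                window_seconds = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (inherits(bands, "band_definition")) bands <- list(bands)
  out <- lapply(bands, function(band) {
    filt <- bandpass_filter(rec, band)
    blocks <- window_signal(filt, window_seconds)
    layers <- lapply(blocks, wpli_matrix, labels = rec$labels)
    new_connectivity_series(layers, band, window_seconds, rec$labels)
  })
  names(out) <- vapply(bands, `[[`, "", "name")
  out
}

new_connectivity_series <- function(layers, band, window_seconds, labels) {
  structure(list(layers = layers, band = band,
                 window_seconds = window_seconds, labels = labels,
                 n_layers = length(layers)),
            class = "connectivity_series")
}

#' @export
print.connectivity_series <- function(x, ...) {
  cat(sprintf("<connectivity_series> band %s (%g-%g Hz), L = %d layers of %d x %d\n",
              x$band$name, x$band$low, x$band$high, x$n_layers,
              nrow(x$layers[[1]]), ncol(x$layers[[1]])))
  if (x$n_layers < 2)
    cat("  note: L < 2, unusable for dynamic metrics\n")
  invisible(x)
}

#' Temporal coefficient of variation of connectivity
#'
#' Per edge, CoV = population standard deviation over layers divided by
#' the mean over layers; the session summary is the mean over all
#' off-diagonal edges with non-zero temporal mean. Edges with zero mean
#' are excluded and counted.
#'
#' @param series A `connectivity_series` with `L >= 2`.
#' @return List with `cov_matrix` (NA on excluded edges and diagonal),
#'   `session_mean`, `n_excluded`, `band`.
#' @export
temporal_cov <- function(series) {
  stopifnot(inherits(series, "connectivity_series"))
  L <- series$n_layers
  if (L < 2) param_error("temporal CoV needs L >= 2 layers, got %d", L)
  n <- nrow(series$layers[[1]])
  stack <- array(unlist(series$layers), dim = c(n, n, L))
  mu <- apply(stack, c(1, 2), mean)
  sdev <- sqrt(apply(stack, c(1, 2), function(v) mean((v - mean(v))^2)))
  cv <- matrix(NA_real_, n, n, dimnames = dimnames(series$layers[[1]]))
  ok <- mu > 0
  cv[ok] <- sdev[ok] / mu[ok]
  diag(cv) <- NA_real_
  vals <- cv[upper.tri(cv)]
  n_excluded <- sum(is.na(vals))
  if (all(is.na(vals)))
    param_error("all edges have zero temporal mean; CoV undefined")
  list(cov_matrix = cv, session_mean = mean(vals, na.rm = TRUE),
       n_excluded = n_excluded, band = series$band)
}
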