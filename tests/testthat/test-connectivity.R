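# filtering, windowing, wPLI, temporal CoV

sine_rec <- function(freq, rate = 256, secs = 8, channels = 1) {
  t <- seq(0, secs - 1 / rate, by = 1 / rate)
  eeg_recording(matrix(rep(sin(2 * pi * freq * t), channels),
                       nrow = channels, byrow = TRUE), rate)
}

test_that("band-pass keeps in-band and rejects out-of-band tones", {
  rec <- sine_rec(10)
  filt <- bandpass_filter(rec, band_definition("alpha", 8, 13))
  interior <- 512:(ncol(rec$data) - 512)
  amp_ratio <- max(abs(filt$data[1, interior])) / 1
  expect_lt(abs(amp_ratio - 1), 0.05)
  # 2 Hz tone through gamma: crushed
  rec2 <- sine_rec(2)
  filt2 <- bandpass_filter(rec2, band_definition("gamma", 25, 40))
  expect_lt(max(abs(filt2$data[1, interior])), 0.05)
  expect_error(bandpass_filter(rec, band_definition("bad", 25, 200)),
               "Nyquist")
})

test_that("forward-backward filtering has zero phase at band center", {
  rec <- sine_rec(10.5, secs = 16)
  filt <- bandpass_filter(rec, band_definition("alpha", 8, 13))
  interior <- 1024:(16 * 256 - 1024)
  t <- (interior - 1) / 256
  # project input and output onto the quadrature pair at 10.5 Hz
  phase_of <- function(x) {
    c_ <- sum(x * cos(2 * pi * 10.5 * t))
    s_ <- sum(x * sin(2 * pi * 10.5 * t))
    atan2(c_, s_)
  }
  dphi <- phase_of(filt$data[1, interior]) - phase_of(rec$data[1, interior])
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_lt(abs(dphi) * 180 / pi, 1)
})

test_that("windowing counts and truncation follow the 10-s rule", {
  # 3725 s at 256 Hz -> 372 full 10-s windows
  rec <- eeg_recording(matrix(0, 2, 3725 * 256), 256)
  expect_length(window_signal(rec, 10), 372)
  rec1 <- eeg_recording(matrix(rnorm(2 * 2560), 2), 256)
  w <- window_signal(rec1, 10)
  expect_length(w, 1)
  expect_equal(ncol(w[[1]]), 2560)
  # 19.9 s: remainder dropped
  rec2 <- eeg_recording(matrix(0, 1, round(19.9 * 256)), 256)
  expect_length(window_signal(rec2, 10), 1)
  expect_error(window_signal(rec1, 0), "window_seconds")
  expect_error(window_signal(rec2, 30), "shorter")
})

test_that("wPLI satisfies its sign, convention and invariance contracts", {
  t <- (0:2559) / 256
  x <- cos(2 * pi * 10 * t)
  y <- cos(2 * pi * 10 * t - pi / 2)
  w <- wpli_matrix(rbind(x, y))
  expect_gt(w[1, 2], 1 - 1e-9)
  expect_equal(w[1, 1], 0)
  # zero lag: denominator 0 -> 0 by convention
  expect_equal(wpli_matrix(rbind(x, x))[1, 2], 0)
  # amplitude rescaling invariance
  w2 <- wpli_matrix(rbind(3.7 * x, y))
  expect_lt(max(abs(w2 - w)), 1e-9)
  # symmetry, range
  set.seed(9)
  blk <- matrix(rnorm(4 * 512), 4)
  wm <- wpli_matrix(blk)
  expect_identical(wm, t(wm))
  expect_true(all(wm >= 0 & wm <= 1))
  # channel-permutation equivariance
  p <- c(3, 1, 4, 2)
  expect_equal(wpli_matrix(blk[p, ]), wm[p, p], tolerance = 1e-12)
  expect_error(wpli_matrix(rbind(x, y) * NA), "non-finite")
  expect_error(wpli_matrix(matrix(x, 1)), "2 channels")
})

test_that("independent band-limited channels stay under the null tail", {
  set.seed(41)
  band <- band_definition("alpha", 8, 13)
  f <- butter_bandpass(8, 13, 256)
  one_null <- function() {
    a <- filtfilt_iir(f$b, f$a, rnorm(2560))
    b <- filtfilt_iir(f$b, f$a, rnorm(2560))
    wpli_matrix(rbind(a, b))[1, 2]
  }
  null_draws <- replicate(200, one_null())
  expect_lt(one_null(), quantile(null_draws, 0.95))
})

test_that("connectivity_series separates planted communities", {
  sched <- simulate_label_sequences(8, 3, 2, 0, seed = 6)
  rec <- simulate_eeg(sched, rate = 128, window_seconds = 4,
                      band = c(8, 13), coupling = 0.9, noise_sd = 0.5,
                      seed = 6)
  ser <- connectivity_series(rec, list(band_definition("alpha", 8, 13)),
                             window_seconds = 4)[[1]]
  expect_equal(ser$n_layers, 3)
  same <- outer(sched$labels[, 1], sched$labels[, 1], "==")
  ut <- upper.tri(same)
  for (W in ser$layers)
    expect_gt(mean(W[same & ut]), mean(W[!same & ut]))
  # one series per band, identical L
  multi <- connectivity_series(rec, default_bands()[c("theta", "alpha")],
                               window_seconds = 4)
  expect_equal(vapply(multi, `[[`, 0L, "n_layers"), c(theta = 3L, alpha = 3L))
})

test_that("temporal CoV matches hand computation and its invariances", {
  # edge series [2,4,4,4,5,5,7,9]/10: mean .5, population sd .2 -> CoV .4
  vals <- c(2, 4, 4, 4, 5, 5, 7, 9) / 10
  layers <- lapply(vals, function(v) {
    m <- matrix(c(0, v, v, 0), 2)
    m
  })
  cv <- temporal_cov(as_series(layers))
  expect_equal(cv$cov_matrix[1, 2], 0.4)
  expect_equal(cv$session_mean, 0.4)
  # constant edge -> 0; scale invariance
  const <- lapply(rep(0.5, 6), function(v) matrix(c(0, v, v, 0), 2))
  expect_equal(temporal_cov(as_series(const))$session_mean, 0)
  scaled <- lapply(layers, function(m) 2.5 * m)
  expect_equal(temporal_cov(as_series(scaled))$session_mean, 0.4)
  # degenerate: all-zero edges rejected
  zero <- lapply(1:3, function(i) matrix(0, 2, 2))
  expect_error(temporal_cov(as_series(zero)), "undefined")
  expect_error(temporal_cov(as_series(layers[1])), "L >= 2")
})

test_that("eeg text round-trip preserves data, rate and labels", {
  rec <- eeg_recording(matrix(rnorm(3 * 100), 3), 128,
                       c("Fz", "Cz", "Pz"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eeg_text(rec, path)
  back <- read_eeg_text(path)
  expect_equal(back$rate, 128)
  expect_equal(back$labels, rec$labels)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
})
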