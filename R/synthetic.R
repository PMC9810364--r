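# Synthetic inputs with known ground truth: planted label schedules,
# Bernoulli pair-affiliation indicators, phase-coupled multichannel
# signals whose community membership switches on the window grid, and
# questionnaire records that reproduce requested marginal counts.

#' Simulate a planted community membership schedule
#'
#' Each node starts in a uniformly random community; at every layer
#' boundary each node independently resamples its community (uniformly
#' over the *other* communities, so a resample is always a switch) with
#' probability `switch_rate`. The expected ground-truth flexibility of
#' every node therefore equals `switch_rate` (when `n_communities > 1`).
#'
#' @param n_nodes,n_layers Schedule dimensions (`n_layers >= 2`).
#' @param n_communities Number of planted communities (>= 1).
#' @param switch_rate Per-node per-boundary switch probability in \[0,1\].
#' @param seed RNG seed.
#' @return A `membership_schedule`: list with `labels` (n_nodes x
#'   n_layers positive integer matrix), `switch_rate`, `seed`.
#' @export
simulate_label_sequences <- function(n_nodes, n_layers, n_communities,
                                     switch_rate, seed) {
  if (!is.numeric(switch_rate) || length(switch_rate) != 1L ||
      is.na(switch_rate) || switch_rate < 0 || switch_rate > 1)
    param_error("switch_rate must be a probability in [0, 1]")
  if (n_communities < 1) param_error("n_communities must be >= 1")
  if (n_layers < 2) param_error("n_layers must be >= 2")
  set.seed(seed)
  lab <- matrix(0L, n_nodes, n_layers)
  lab[, 1] <- sample.int(n_communities, n_nodes, replace = TRUE)
  for (t in 2:n_layers) {
    lab[, t] <- lab[, t - 1]
    if (n_communities > 1) {
      flip <- runif(n_nodes) < switch_rate
      if (any(flip)) {
        cur <- lab[flip, t - 1]
        # uniform over the other communities
        draw <- sapply(cur, function(c)
          sample(seq_len(n_communities)[-c], 1L))
        lab[flip, t] <- draw
      }
    }
  }
  structure(list(labels = lab, n_nodes = n_nodes, n_layers = n_layers,
                 n_communities = n_communities,
                 switch_rate = switch_rate, seed = seed),
            class = "membership_schedule")
}

#' @export
print.membership_schedule <- function(x, ...) {
  cat(sprintf("<membership_schedule> %d nodes x %d layers, %d communities, switch_rate %g\n",
              x$n_nodes, x$n_layers, x$n_communities, x$switch_rate))
  invisible(x)
}

#' Simulate an i.i.d. pair-affiliation indicator
#'
#' Bernoulli(a) indicator of "pair in the same community at layer t";
#' the closed forms allegiance -> a and intermittence -> 2a(1-a) make
#' this the oracle harness for the pair metrics.
#'
#' @param a Probability the pair shares a community at any layer.
#' @param L Number of layers (>= 2).
#' @param seed RNG seed.
#' @return Integer 0/1 vector of length L.
#' @export
simulate_pair_affiliation <- function(a, L, seed) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1)
    param_error("a must be a probability in [0, 1]")
  if (L < 2) param_error("L must be >= 2")
  set.seed(seed)
  rbinom(L, 1L, a)
}

#' Simulate phase-coupled multichannel EEG from a planted schedule
#'
#' Each planted community drives a shared band-limited oscillatory
#' source (narrowband-filtered Gaussian noise, not a pure sinusoid, so
#' windowed connectivity fluctuates over time). A channel observes its
#' community's source at a fixed channel-specific phase offset (drawn
#' once per session, uniform on \[pi/8, 3*pi/8\], fixed sign — wPLI
#' rewards consistent non-zero lag and discounts zero-lag coupling),
#' mixed with independent broadband noise. Membership switches are
#' synchronized to window boundaries so the ground truth lives on the
#' same layer grid the analysis uses.
#'
#' @param schedule A `membership_schedule`.
#' @param rate Sampling rate in Hz (default 256).
#' @param window_seconds Seconds per layer window (default 10).
#' @param band Length-2 numeric (low, high) Hz of the source band.
#' @param coupling Source mixing weight in \[0,1\].
#' @param noise_sd Standard deviation of the additive channel noise.
#' @param seed RNG seed.
#' @param phase_offsets Optional per-channel phase offsets (radians);
#'   drawn if NULL.
#' @param labels Optional channel labels (default: 10-20 montage names).
#' @return An [eeg_recording()] of duration `n_layers * window_seconds`.
#' @export
simulate_eeg <- function(schedule, rate = 256, window_seconds = 10,
                         band = c(8, 13), coupling = 0.9, noise_sd = 0.5,
                         seed = 1, phase_offsets = NULL, labels = NULL) {
  stopifnot(inherits(schedule, "membership_schedule"))
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < rate / 2))
    param_error("band (%g, %g) outside (0, Nyquist = %g)",
                band[1], band[2], rate / 2)
  spw <- round(window_seconds * rate)
  if (spw < 2) param_error("window_seconds * rate must be >= 2 samples")
  if (coupling < 0 || coupling > 1)
    param_error("coupling must be in [0, 1]")
  N <- schedule$n_nodes
  L <- schedule$n_layers
  total <- L * spw
  K <- max(schedule$labels)
  set.seed(seed)
  if (is.null(labels)) {
    labels <- if (N <= 20) montage_1020()[seq_len(N)]
              else paste0("ch", seq_len(N))
  }
  filt <- butter_bandpass(band[1], band[2], rate)
  # community sources: band-limited unit-variance noise, analytic form
  zsrc <- matrix(0 + 0i, K, total)
  for (c in seq_len(K)) {
    s <- filtfilt_iir(filt$b, filt$a, rnorm(total))
    s <- s / sd(s)
    zsrc[c, ] <- hilbert_analytic(s)
  }
  if (is.null(phase_offsets))
    phase_offsets <- runif(N, pi / 8, 3 * pi / 8)
  x <- matrix(0, N, total)
  for (i in seq_len(N)) {
    zi <- numeric(total)
    for (t in seq_len(L)) {
      seg <- ((t - 1) * spw + 1):(t * spw)
      c <- schedule$labels[i, t]
      zi[seg] <- Re(zsrc[c, seg] * exp(-1i * phase_offsets[i]))
    }
    x[i, ] <- coupling * zi
  }
  if (noise_sd > 0)
    x <- x + matrix(rnorm(N * total, sd = noise_sd), N, total)
  eeg_recording(x, rate, labels)
}

#' Simulate a two-group, two-context synthetic cohort
#'
#' Stand-in for the change / no-change cohorts in both social contexts:
#' per subject and context, a planted schedule at the group's switch
#' rate plus the corresponding phase-coupled recording. The "no change"
#' group reconfigures faster (higher switch rate), matching the planted
#' direction of the group effect.
#'
#' @param n_per_group Subjects per group.
#' @param switch_rates Named numeric: switch rate per group,
#'   default `c(NC = 0.3, C = 0.1)`.
#' @param contexts Character vector of context tags.
#' @param n_nodes,n_layers,n_communities Schedule dimensions.
#' @param rate,window_seconds,band,coupling,noise_sd Passed to
#'   [simulate_eeg()].
#' @param seed Master seed; every session derives its own sub-seed.
#' @param keep_eeg Generate recordings (set FALSE for schedule-only
#'   cohorts used in metric-level experiments).
#' @return A `synthetic_cohort`: list of session records (subject_id,
#'   group, context, schedule, recording) plus the generation parameters.
#' @export
simulate_cohort <- function(n_per_group = 10,
                            switch_rates = c(NC = 0.3, C = 0.1),
                            contexts = c("social_media", "in_person"),
                            n_nodes = 20, n_layers = 30, n_communities = 2,
                            rate = 256, window_seconds = 10,
                            band = c(8, 13), coupling = 0.9, noise_sd = 0.5,
                            seed = 1, keep_eeg = TRUE) {
  stopifnot(!is.null(names(switch_rates)), length(switch_rates) >= 1)
  sessions <- list()
  k <- 0L
  for (g in names(switch_rates)) {
    for (s in seq_len(n_per_group)) {
      sid <- sprintf("%s%02d", g, s)
      for (ctx in contexts) {
        k <- k + 1L
        sseed <- derive_seed(seed, k)
        sched <- simulate_label_sequences(n_nodes, n_layers, n_communities,
                                          switch_rates[[g]], sseed)
        rec <- if (keep_eeg)
          simulate_eeg(sched, rate, window_seconds, band, coupling,
                       noise_sd, seed = sseed + 1L)
        else NULL
        sessions[[k]] <- list(subject_id = sid, group = g, context = ctx,
                              schedule = sched, recording = rec)
      }
    }
  }
  structure(list(sessions = sessions,
                 params = list(n_per_group = n_per_group,
                               switch_rates = switch_rates,
                               contexts = contexts, n_nodes = n_nodes,
                               n_layers = n_layers,
                               n_communities = n_communities, rate = rate,
                               window_seconds = window_seconds, band = band,
                               coupling = coupling, noise_sd = noise_sd,
                               seed = seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf("<synthetic_cohort> %d sessions (%d/group x %d contexts), %d nodes x %d layers\n",
              length(x$sessions), p$n_per_group, length(p$contexts),
              p$n_nodes, p$n_layers))
  cat("  switch rates:",
      paste(sprintf("%s=%g", names(p$switch_rates), p$switch_rates),
            collapse = ", "), "\n")
  invisible(x)
}

#' Simulate questionnaire records matching requested marginal counts
#'
#' Generates pre/post answers for the three scenarios (travel, murder
#' trial, vaccination) at timepoints T0 (baseline), T1 (post social
#' media) and T2 (post discussion) such that the coded change counts
#' exactly match the requested marginals. Unconstrained cells are filled
#' uniformly at random.
#'
#' Supported marginal keys (all optional, defaults in parentheses):
#' `no_change_after_sm` — subjects with zero T0->T1 changes (half of n);
#' `no_change_after_inperson` — zero T1->T2 changes (half of n);
#' `no_change_both` — subjects in both no-change sets (drawn uniformly
#' consistent with the other two if omitted).
#'
#' @param n_subjects Number of subjects.
#' @param marginal_counts Named list/vector of the keys above.
#' @param seed RNG seed.
#' @return Long data frame, one row per subject x timepoint, with the
#'   answer columns documented in [aggregate_changes()].
#' @export
simulate_questionnaires <- function(n_subjects, marginal_counts = list(),
                                    seed = 1) {
  mc <- as.list(marginal_counts)
  known <- c("no_change_after_sm", "no_change_after_inperson",
             "no_change_both")
  bad <- setdiff(names(mc), known)
  if (length(bad))
    param_error("unknown marginal keys: %s", paste(bad, collapse = ", "))
  set.seed(seed)
  nc_s <- mc$no_change_after_sm %||% round(n_subjects / 2)
  nc_i <- mc$no_change_after_inperson %||% round(n_subjects / 2)
  if (nc_s < 0 || nc_s > n_subjects || nc_i < 0 || nc_i > n_subjects)
    param_error("marginal counts must lie in [0, n_subjects = %d]",
                n_subjects)
  # joint: need max(0, nc_s + nc_i - n) <= nc_both <= min(nc_s, nc_i)
  lo <- max(0, nc_s + nc_i - n_subjects)
  hi <- min(nc_s, nc_i)
  nc_both <- mc$no_change_both %||% if (lo == hi) lo else sample(lo:hi, 1)
  if (nc_both < lo || nc_both > hi)
    param_error("no_change_both = %d inconsistent with marginals (allowed %d..%d)",
                nc_both, lo, hi)
  ids <- sprintf("S%03d", seq_len(n_subjects))
  nc_s_set <- sample(ids, nc_s)
  both_set <- sample(nc_s_set, nc_both)
  rest <- setdiff(ids, nc_s_set)
  nc_i_set <- c(both_set, sample(rest, nc_i - nc_both))

  baseline <- function(id) {
    data.frame(subject_id = id, timepoint = "T0",
               travel_destination = sample(c("France", "Indonesia"), 1),
               travel_volunteer = sample(c("yes", "no"), 1),
               travel_hours = sample(c(0, 5, 10, 20, 40), 1),
               murder_verdict = sample(c("guilty", "not_guilty"), 1),
               murder_sentence = sample(c("10y", "25y", "life", "death"), 1),
               vaccinate = sample(c("yes", "no"), 1),
               stringsAsFactors = FALSE)
  }
  flip_scenario <- function(row, scenario) {
    if (scenario == "travel") {
      what <- sample(c("destination", "volunteer", "hours"), 1)
      if (what == "destination")
        row$travel_destination <- setdiff(c("France", "Indonesia"),
                                          row$travel_destination)
      else if (what == "volunteer")
        row$travel_volunteer <- setdiff(c("yes", "no"),
                                        row$travel_volunteer)
      else
        row$travel_hours <- sample(setdiff(c(0, 5, 10, 20, 40),
                                           row$travel_hours), 1)
    } else if (scenario == "murder") {
      what <- sample(c("verdict", "sentence"), 1)
      if (what == "verdict")
        row$murder_verdict <- setdiff(c("guilty", "not_guilty"),
                                      row$murder_verdict)
      else
        row$murder_sentence <- sample(setdiff(c("10y", "25y", "life", "death"),
                                              row$murder_sentence), 1)
    } else {
      row$vaccinate <- setdiff(c("yes", "no"), row$vaccinate)
    }
    row
  }
  advance <- function(row, tp, change) {
    row$timepoint <- tp
    if (change) {
      # mostly single-scenario changes, like the observed histograms
      k <- sample(1:3, 1, prob = c(0.8, 0.17, 0.03))
      for (sc in sample(c("travel", "murder", "vaccination"), k))
        row <- flip_scenario(row, sc)
    }
    row
  }
  rows <- vector("list", n_subjects * 3L)
  for (s in seq_len(n_subjects)) {
    r0 <- baseline(ids[s])
    r1 <- advance(r0, "T1", !(ids[s] %in% nc_s_set))
    r2 <- advance(r1, "T2", !(ids[s] %in% nc_i_set))
    rows[[3 * s - 2]] <- r0
    rows[[3 * s - 1]] <- r1
    rows[[3 * s]] <- r2
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
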