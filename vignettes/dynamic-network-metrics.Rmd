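---
title: "Dynamic community metrics for phase-based EEG connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic community metrics for phase-based EEG connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasecomm)
```

## The model

This package implements a pipeline for asking whether the *temporal
reorganization* of scalp-level brain networks differs between groups of
people — canonically, between those who did ("C") and did not ("NC")
change an opinion during a recorded task — and between social contexts
(free browsing of a social-media feed vs. an in-person discussion).

The chain of estimators is:

1. **Band-limited connectivity.** Each multichannel EEG recording is
   band-pass filtered (order-3 Butterworth, forward and reverse so the
   net phase response is zero) into the five classical bands — delta
   (1–3 Hz), theta (3–7 Hz), alpha (8–13 Hz), beta (21–30 Hz), gamma
   (25–40 Hz). The 13–21 Hz gap and the 25–30 Hz beta/gamma overlap are
   deliberate: the band table is part of the analysis definition and is
   kept verbatim rather than normalized to a conventional table. The
   filtered record is cut into non-overlapping 10-s windows and, per
   window, every sensor pair gets a **weighted phase lag index**
   $$\Phi_{ij} = \frac{|E\{\Im X_{ij}\}|}{E\{|\Im X_{ij}|\}},$$
   where $X_{ij}$ is the cross-spectrum of the analytic (Hilbert)
   signals and $E\{\cdot\}$ the sample mean within the window. Because
   only the *imaginary* part enters, zero-lag coupling — the signature
   of volume conduction — contributes nothing to the numerator and the
   index rewards a consistent non-zero phase lag. The degenerate case
   $E\{|\Im X|\}=0$ (pure zero-lag coupling) is defined as 0: that is
   exactly the coupling wPLI is designed to discount.

2. **Multilayer community detection.** The ordered stack of $L$ wPLI
   matrices is treated as a temporal multilayer network. A partition of
   node-layer pairs is scored by multilayer modularity
   $$Q = \frac{1}{2\mu}\sum_{ijsr}\Big[\big(A_{ijs} - \gamma\,
   \tfrac{k_{is}k_{js}}{2m_s}\big)\delta_{sr} + \delta_{ij}\,
   \omega\,\mathbb{1}(|s-r|=1)\Big]\,\delta(g_{is},g_{jr}),$$
   with the weighted Newman–Girvan null within each layer (resolution
   $\gamma$) and uniform *ordinal* coupling $\omega$ linking each
   sensor only to itself in adjacent windows. The optimizer is a
   Louvain-style greedy scheme on the dense supra-modularity matrix
   (`cpp_louvain`): randomized node sweeps, aggregation, and — beyond
   the textbook algorithm — repeated full cycles each starting with a
   node-level refinement sweep over the current partition. The
   refinement matters: plain move-and-aggregate systematically freezes
   single node-layers near community switch boundaries into the wrong
   super-node (we observed it plateau below the planted optimum on
   every seed), while the refinement recovers the planted partition
   exactly on benchmark stacks. Labels are global across layers by
   construction, which is what makes node flexibility well defined.
   Because the optimizer is stochastic, detection is repeated
   (`repeat_detection`, default 100 seeded runs) and all metrics are
   averaged over the ensemble.

3. **Dynamics metrics.** From an $N\times L$ label matrix:
   *flexibility* $\xi_i = g_i/(L-1)$, the fraction of layer boundaries
   at which node $i$ switches community; *allegiance*
   $a_{jk} = \tfrac1L\sum_t \delta_{C_j(t)C_k(t)}$, the fraction of
   layers a pair shares a community; and *intermittence*
   $$I_{jk} = \frac{1}{L-1}\sum_{t=1}^{L-1}
   \big[\delta_t(1-\delta_{t+1}) + \delta_{t+1}(1-\delta_t)\big],$$
   the fraction of boundaries at which the pair's shared-community
   indicator $\delta_t$ flips. Intermittence is the novel quantity: two
   pairs can have identical allegiance 0.5 while one is together in two
   long blocks ($I = 1/(L-1)$) and the other alternates every window
   ($I = 1$). It is bounded both by the nodes' flexibilities
   ($I_{jk} \le \xi_j + \xi_k$) and by allegiance
   ($I_{jk} \le \min(2aL,\,2(1-a)L,\,L-1)/(L-1)$) — a pair rarely
   together cannot flip often. Both bounds are enforced as
   property tests.

4. **Group statistics.** Groups are unequal, so comparisons are
   bootstrap-based: 10,000 within-group resamples of the mean (or of
   the NC−C mean difference), percentile 95% intervals, and a
   two-sided p equal to twice the smaller tail mass of the difference
   distribution at zero, floored at $1/n$. Intermittence is compared
   along an allegiance-threshold axis: at each threshold only pairs
   with allegiance *strictly* above it enter, and the summary is the
   percentage of the threshold grid (0 to 1, step 0.01) on which the
   groups differ at p < 0.05. Context effects use the temporal
   coefficient of variation of the wPLI edge series (population SD over
   mean, averaged over edges with non-zero mean) and a subject-level
   bootstrap: 1,000 replicas of 30 subjects drawn with replacement per
   cell.

## Behavioral coding

Opinion answers for three scenarios (travel destination + volunteering,
murder-trial verdict + sentence, vaccination yes/no) are collected at
baseline (T0), after the social-media session (T1) and after the
discussion (T2). A scenario counts as changed when any of its fields
differs from the *previous* questionnaire (T1 vs T0 for the
social-media interval; T2 vs T1 for the in-person interval); the
interval score is the number of changed scenarios (0–3) and any change
puts the subject in the C group for that interval. Whether a change in
offered volunteer *hours* alone counts is genuinely ambiguous in the
rule as stated; both sub-rules are implemented and the default
(`hours_counts = TRUE`) treats the disjunction inclusively.
Percentages are reported to one decimal with half-up rounding.

## The synthetic world

The study's recordings are not publicly available, so the generator
produces every input the pipeline needs, with ground truth planted
where the pipeline is supposed to rediscover it:

* **Schedules** (`simulate_label_sequences`): each node starts in a
  uniform random community and at each layer boundary resamples
  uniformly *over the other communities* with probability
  `switch_rate` — so expected ground-truth flexibility equals the
  switch rate exactly, and the 0 and 1 limits are sharp.
* **Signals** (`simulate_eeg`): each community drives a shared
  band-limited source (narrowband-filtered Gaussian noise, *not* a pure
  sinusoid — a sinusoid would make windowed connectivity constant and
  the CoV stage degenerate). A channel observes its community's source
  at a fixed per-session phase offset drawn once from
  $[\pi/8, 3\pi/8]$ with fixed sign, because wPLI is blind to zero lag
  and rewards consistent non-zero lag; independent broadband noise is
  added. Membership switches are aligned to window boundaries so the
  planted truth lives on the 10-s layer grid the analysis uses.
  Defaults (20 channels at 256 Hz with the standard 10–20 labels,
  coupling 0.9, noise SD 0.5) mirror the acquisition geometry of the
  motivating study at desk scale.
* **Cohorts** (`simulate_cohort`): NC sessions switch at rate 0.3, C
  sessions at 0.1 — the planted direction of the group effect (the
  no-change group reconfigures faster), in both contexts.
* **Questionnaires** (`simulate_questionnaires`): answers are
  constructed so the coded change counts match requested marginals
  *exactly* (75/132 no-change after social media, 97/132 after
  discussion, 56 in both — the joint count implied by the printed
  conditional percentages); every unconstrained cell is filled
  uniformly, and is explicitly arbitrary.

What a green test does **not** establish: the generator has no
artifacts (blinks, EMG), no volume-conduction forward model, no
1/f background, and its group effect is planted directly in the
switching rate. Recovery of the planted structure validates the
estimator chain, not any neuroscientific claim.

## Numerical choices

* Expectation in wPLI = sample mean over the window's samples; the
  cross-spectrum comes from the analytic signal of the already-filtered
  block; no taper, and filter transients are handled by zero-phase
  filtering the full record *before* windowing.
* `filtfilt` uses odd-reflection padding of $3\times(\text{nfilt}-1)$
  samples and steady-state initial conditions (the Matlab/scipy
  convention); the band-pass design was verified coefficient-for-
  coefficient against an independent reference implementation.
* CoV uses the population (divide-by-$L$) standard deviation; the
  choice is arbitrary but fixed and documented, and CoV is invariant
  to positive rescaling of an edge series either way.
* Louvain move gains below $10^{-12}$ are rejected (deterministic
  termination); ties go to the first candidate encountered in the
  randomized sweep. A fixed seed fully determines the visit orders, so
  ensembles are bit-reproducible.
* Windowing truncates: a trailing remainder shorter than one window is
  dropped.
* The sweep grid defaults to $\gamma \in \{0.9, 0.95, \dots, 1.3\}$,
  $\omega \in \{0.1, 0.25, 0.5, 0.75, 1\}$ (the printed range in the
  source analysis is typographically corrupt); the selected preset
  $(\gamma, \omega) = (1.1364, 0.5)$ ships as the default. Cell
  selection maximizes $Q_{\text{real}} - Q_{\text{null}}$ subject to
  more than one community on average, with a per-layer node-identity
  permutation null (the null's topology is our documented choice; the
  source text says only "shuffled").
* Bootstrap p-values are floored at $1/n$; no multiple-testing
  correction is applied across sensors or thresholds by default
  (matching the uncorrected ranges reported in the motivating
  analysis).
* `min_pairs = 10` per threshold cell: a bootstrap of a mean needs
  minimal support; cells below it are excluded from the
  significant-fraction denominator rather than treated as evidence.

## Known limitations

* The supra-modularity matrix is dense, $(NL)^2$ doubles; with 20
  sensors this is comfortable up to a few hundred layers but a
  full-scale 372-layer session ensemble would want a sparse path.
* The CoV bootstrap with fixed replica size 30 is anti-conservative
  for cells smaller than ~30 subjects; keep cells at or above the
  replica size.
* Recordings are exchanged as delimited text with a rate header, not
  EDF (no EDF library is available in the supported environment); the
  reader/writer round-trips losslessly at full double precision.
* The hours-only travel change and the exact unit of pooling in the
  sensor-level bootstrap (subjects, here) are interpretation choices;
  both are surfaced as arguments rather than hard-coded.
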