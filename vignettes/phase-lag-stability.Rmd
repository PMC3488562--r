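---
title: "Phase-lag connectivity and its stability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag connectivity and its stability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(phaselagr)
```

## The problem

Event-related analysis of scalp EEG during movement is dominated by
artifact: a heel strike during treadmill walking injects hundreds of
microvolts into every electrode, two orders of magnitude above the
event-related potentials (ERPs) one hopes to recover by voltage averaging.
Most remedies (channel/epoch rejection, artifact templates, ICA) are
offline, need the full recording, and often need human judgement.

This package implements a phase-based alternative. Movement and
volume-conducted artifacts reach all electrodes essentially
*simultaneously* — at zero phase lag. Genuine inter-regional cortical
coupling, by contrast, shows consistent *non-zero* phase lags, as expected
from a system of coupled oscillators. A statistic that only credits
consistently lagged phase relationships is therefore structurally blind to
the artifact, and — because every operation it needs is causal — it can run
on-line.

## The statistics

**WPLI.** For channels $i, j$, let $\varphi_{i,t}$ be the instantaneous
phase from the analytic signal (Hilbert transform) of the band-passed data,
and $\Delta\Phi_t = \varphi_{i,t} - \varphi_{j,t}$ (wrapped to
$(-\pi,\pi]$). Over a sliding window of $W$ samples the weighted phase lag
index is

$$\mathrm{WPLI} \;=\; \frac{\left|\sum_t \sin \Delta\Phi_t\right|}
{\sum_t \left|\sin \Delta\Phi_t\right|} \in [0, 1].$$

The sine weighting counts a quarter-cycle ($\pm 90^\circ$) lag maximally
and a zero (or half-cycle) lag not at all; the ratio is 1 when the *sign*
of the lag never flips within the window. A common additive source drags
all channels toward one phase, making $\sin\Delta\Phi$ tiny — it
contributes almost nothing to either sum. When every
$\Delta\Phi_t$ is an exact multiple of $\pi$ the denominator vanishes and
the value is defined to be 0: no evidence of lagged coupling. Amplitudes
never enter, so the measure is invariant to channel rescaling.

**WPLIS.** The raw WPLI time course is informative but volatile across
trials and subjects. The stability statistic is its trailing coefficient of
variation: at window index $\tau$,

$$\mathrm{WPLIS}_\tau = \frac{\mathrm{SD}\left(\mathrm{WPLI}_{\tau - 0.5\,\mathrm{s}} \cdots \mathrm{WPLI}_\tau\right)}
{\mathrm{mean}\left(\mathrm{WPLI}_{\tau - 0.5\,\mathrm{s}} \cdots \mathrm{WPLI}_\tau\right)},$$

a scale-free dispersion measure. Low WPLIS means stable, uniform coupling
dynamics; an event-locked *decrease* (stabilisation) is the cognitive
signature the pipeline detects. Because the window is trailing, WPLIS is
computable on-line with a fixed latency. Each value is *timestamped* at the
centre of the span it summarises (the mean of the contributing WPLI window
centres); it becomes available half a stability window later. The
trailing-edge alternative would simply shift every curve a quarter second
to the right, misplacing the dip relative to the stimulus.

## Pipeline and parameters

The canonical processing chain and its defaults:

| Stage | Default | Notes |
|---|---|---|
| high-pass | 1 Hz, order 2, zero-phase | drift/DC removal |
| channel QC | 1000 uV SD; kurtosis 5 SD; r < 0.4 in > 1% of 1 s windows | three independent rules, see below |
| re-reference | average of retained channels | |
| band-pass | 4 ± 2 Hz Butterworth, order 2, zero-phase | theta band; centre/width configurable |
| decimation | by 10 (512 → 51.2 Hz) | sample dropping, no interpolation |
| WPLI window | 25 samples (~488 ms), hop 12 (~234 ms) | ~half-window overlap |
| WPLIS window | 0.5 s (3 WPLI values at default geometry) | trailing |
| epoching | −0.5 … +1.5 s around targets | aligned on nearest window |
| statistics | baseline mean over [−0.5, 0); minimum over (0, 1.5] | z from the se at the minimum |

Design notes on the less obvious choices:

* **Zero-phase filtering by default.** The analysis lives in phase space; a
  causal filter would add frequency-dependent phase shifts. The streaming
  path (`run_pipeline_stream()`) uses the causal variant plus a causal FIR
  Hilbert transformer with group-delay compensation, and chunked processing
  with carried filter state reproduces one-shot causal processing to
  machine precision — the on-line claim made executable. Batch and causal
  outputs differ slightly near edges and by the FIR approximation; the
  equivalence contract is causal-vs-causal.
* **Hop of 12 samples.** A ~50% overlap of a 25-sample window would be 12.5
  samples; 12 keeps window starts on the integer grid. It is a parameter of
  `window_spec()`.
* **Kurtosis rule population.** "5 SD from the mean" is read across
  channels (the convention of the standard EEG toolboxes): a channel is
  rejected when its excess kurtosis is an outlier relative to the
  across-channel distribution. With $N$ channels the largest attainable
  z-score is about $\sqrt{N}$, so the rule is only meaningful for
  high-density montages.
* **Neighbour-correlation rule.** "Uncorrelated with nearby channels for
  more than 1% of the time" is made precise as: Pearson correlation with
  the mean of channels within `neighbor_radius` (default 0.25 on the unit
  disc, appropriate for ~250-channel montages; sparser test montages use a
  larger radius), in non-overlapping 1 s windows, below 0.4 in more than 1%
  of windows. Per-sample correlation is undefined, and windows — not
  samples — are the unit a practitioner inspects. Channels already rejected
  by the amplitude or kurtosis rules are excluded from neighbour
  references, so one gross channel cannot poison its neighbours' screens.
* **Minimum statistics.** The deflection z-score divides the
  baseline-minus-minimum drop by the across-subject standard error at the
  minimum's time bin, and the headline p-value is the two-sided normal
  tail (one-sided also reported). Because the minimum is *selected* over
  the search window, this statistic is anti-conservative under the null —
  the minimum of several noisy bins sits below the mean by construction.
  With homogeneous simulated subjects the false-positive rate is well above
  the nominal 5% (the test suite measures it honestly); real
  between-subject level differences inflate the se at every bin and pull
  the z down, which is presumably why the statistic behaves acceptably in
  practice. Treat the p-values as descriptive, or calibrate them against
  the package's own null simulations.
* **PCA orientation.** For the topography, channel pairs are the variables
  and epoch-mean time points the observations, so the first principal
  component assigns one loading per pair — which the per-channel cumulative
  positive loading needs. The eigenvector sign is fixed so the component's
  dominant extremum is negative: a stabilisation dip then loads
  positively. Covariance scaling is the default; correlation scaling is a
  flag.

## The synthetic-EEG generator

No public dataset accompanies the method, so the package carries a
generator (`sim_config()`, `generate_recording()`) whose every parameter is
known ground truth. It emulates:

* **Oscillators.** Each channel is a 20 uV, 4 Hz oscillator with a slow
  random-walk phase drift (uncoupled channels decohere over seconds).
* **Phase-lagged coupling.** For a coupled pair $(i, j)$, channel $j$'s
  phase is channel $i$'s minus a designed lag plus smooth wrapped-Gaussian
  jitter of SD $\kappa^{-1/2}$. The jitter has a 0.2 s correlation time:
  white per-sample jitter would be annihilated by the analysis band-pass,
  leaving nothing for event modulation to act on. The default concentration
  $\kappa = 1.5$ (jitter SD ≈ 0.8 rad) keeps WPLI in the mid-range, as in
  real recordings; at $\kappa \ge 10$ and a 90° lag the sine sign never
  flips and WPLI saturates at exactly 1.
* **Event modulation.** From 0.3 to 1.0 s after each target stimulus,
  every coupled pair's $\kappa$ is multiplied (default 4): the lag becomes
  more stable, WPLI rises and steadies, and WPLIS dips — the generative
  analogue of the observed stabilisation. With this interval the recovered
  grand-mean dip bottoms out near 0.70 s.
* **The default study network** (in `run_synthetic_study()`) couples
  channels 1–5 to a hub channel 0 at distinct lags (multiples of
  $\pi/6$), so all 15 within-group pairs carry stable, modulated lags —
  a connected cortical network rather than isolated pairings, which is
  also what the first principal component of real pairwise responses
  reflects.
* **Zero-lag contamination.** A common source mixed into all channels with
  configurable gains models volume conduction. The gait-locked artifact of
  the walking condition has two zero-lag parts, both identical on every
  channel: a 0.25 s wave-packet *impact transient* (three adjacent high
  harmonics of the gait frequency, ~14–19 Hz, peak 1000 uV) at each
  heel-strike, and a *continuous in-band pedestal* at the gait harmonic
  nearest the carrier (4.0 Hz for the default 1.25 s cycle, default
  60 uV). The split reflects what the two artifact mechanisms do: impact
  energy is broadband and strike-locked; rhythmic motion contaminates the
  analysis band continuously. It is also what the phase-lag metric can and
  cannot reject: an *always-dominant* common in-band component drags all
  channels toward one phase and is discounted by the sine weighting,
  whereas any large in-band *burst* necessarily sweeps through the
  amplitude range where artifact and signal are comparable, scrambling
  the lag signs while it passes — no burst template survives the
  invariance test, and the package does not pretend otherwise.
* **Bad channels, sensor noise, optional voltage ERP.** Channels can be
  overwritten with high-variance white noise; Gaussian sensor noise (5 uV)
  is always present; a fixed-latency −10 uV half-sine deflection after
  targets exercises the conventional voltage-averaging path that the
  phase pipeline is contrasted against. No generative voltage model of the
  P300 itself is attempted — the simulator models the stability modulation
  the pipeline detects, not the ERP waveform.

What the generator does *not* emulate: 1/f background spectra, realistic
head-model mixing, EMG/EOG waveforms, channel-varying artifact topography.
Passing tests therefore demonstrate correctness of the statistics and
their artifact-rejection mechanism under the stated signal model, not
performance on arbitrary real recordings.

## Worked example

```{r study, warning = FALSE}
st <- run_synthetic_study(n_subjects = 8, n_channels = 8, duration = 60,
                          kappa_multiplier = 4, seed = 1)
st$stats[, c("baseline_mean", "min_value", "min_time", "pct_change", "z", "p")]
```

The grand-mean stability curve dips after the target and recovers:

```{r plot-grand}
autoplot(st$grand)
```

The per-channel cumulative positive PC1 loading separates the coupled
network (channels 0–5) from the uncoupled channels 6–7:

```{r topo}
st$loading_map
```

## Numerical choices and degenerate inputs

* Phases are wrapped to $(-\pi, \pi]$ with `wrap_phase()`; differences are
  never formed by naive subtraction.
* An all-zero channel has no phase: `analytic_phase()` emits `NaN` with a
  warning rather than inventing one.
* `wpli_window()` returns 0 on a zero denominator; `wplis()` returns 0 for
  a non-positive windowed mean (only possible when every WPLI value is 0)
  and clamps floating-point cancellation so constant windows give exactly
  0.
* Epochs are aligned on the window centre nearest each event onset, so all
  epochs share one relative-time axis; events without full context are
  skipped and counted (`n_skipped`).
* Zero-variance rows in `sort_by_corr_to_mean()` get correlation 0 and
  sort first; ties break by original index.
* Degenerate (zero-variance) PCA input is flagged rather than silently
  returning an arbitrary eigenvector.

## Problem sizes used in the tests

The validation suite runs everything at desk scale: 4–32 channels, 30–300 s
recordings, 8 simulated subjects per session, 50 dip-recovery and 200 null
sessions, and 20 topography runs of 8 × 90 s. These sizes were chosen so
the full suite exercises every claim in minutes while leaving the binomial
margins of the rate-based checks meaningful; all of them are parameters,
and scale up without code changes.

## Known limitations

* The deflection p-values inherit the minimum-selection bias discussed
  above.
* The kurtosis rule is ineffective for low channel counts (z capped near
  $\sqrt{N}$).
* The streaming path approximates the Hilbert transform with an FIR
  transformer (default 101 taps ≈ 2 s at 51.2 Hz); its first ~1 s of
  output is warm-up.
* Debiasing of the phase-lag estimator for short windows, graph-theoretic
  summaries of the pair network, and cross-frequency analyses are out of
  scope.
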