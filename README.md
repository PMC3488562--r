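# phaselagr

Artifact-resistant detection of event-locked cognitive dynamics in
multichannel EEG, built on phase-lag functional connectivity.

## The problem

Voltage averaging of scalp EEG fails as soon as the subject moves: a heel
strike during walking drives every electrode by hundreds of microvolts,
two orders of magnitude above the event-related potentials (e.g. the P300
elicited by rare "oddball" stimuli) that the analysis is after. The usual
fixes — channel and epoch rejection, artifact templates, ICA — are offline
procedures over the full recording.

Movement and volume-conducted artifacts share one structural property:
they arrive at all electrodes at (essentially) **zero phase lag**.
Genuine inter-regional cortical coupling shows consistent **non-zero**
lags, as expected of a coupled-oscillator system. `phaselagr` implements
statistics that only credit consistently lagged phase relationships, and
every step is causal, so the whole pipeline can run on-line. It is aimed
at researchers in mobile EEG / cognitive neuroscience and at
brain-computer-interface developers who need an event-locked readout
during movement.

## The statistics

For channels $i, j$, with instantaneous phases $\varphi_{i,t}$ from the
analytic signal of the band-passed data and
$\Delta\Phi_t = \varphi_{i,t} - \varphi_{j,t}$ wrapped to $(-\pi, \pi]$,
the **weighted phase lag index** over a sliding window is

$$\mathrm{WPLI} = \frac{\left|\sum_t \sin \Delta\Phi_t\right|}{\sum_t \left|\sin \Delta\Phi_t\right|} \in [0, 1],$$

maximal for consistent quarter-cycle lags and blind to zero-lag
(artifactual) coupling. Its **stability** is the trailing coefficient of
variation over 0.5 s,

$$\mathrm{WPLIS}_\tau = \frac{\mathrm{SD}(\mathrm{WPLI}_{\tau-0.5\mathrm{s}} \cdots \mathrm{WPLI}_\tau)}{\mathrm{mean}(\mathrm{WPLI}_{\tau-0.5\mathrm{s}} \cdots \mathrm{WPLI}_\tau)} ,$$

whose event-locked *decrease* (coupling stabilisation) is the cognitive
signature. Deflection statistics (baseline mean, post-event minimum,
percent change, z, p) quantify it, and the per-channel sum of positive
first-principal-component loadings over all pairs maps its scalp
topography.

Because no dataset accompanies the method, the package includes a
synthetic-EEG generator with known ground truth — phase-lagged coupled
oscillators, event-locked stability modulation, zero-lag common sources,
gait-locked artifact (impact transient + in-band pedestal), noisy
channels — so every stage is testable end to end.

## Worked example

Simulate an 8-subject oddball study (8 channels, 60 s per subject,
hub-coupled network on channels 0–5, coupling stabilised 0.3–1.0 s after
each target) and recover the stability dip:

```r
library(phaselagr)
st <- run_synthetic_study(n_subjects = 8, n_channels = 8, duration = 60,
                          kappa_multiplier = 4, seed = 1)
st$stats[, c("baseline_mean", "min_value", "min_time", "pct_change", "z", "p")]
#>   baseline_mean min_value min_time pct_change    z        p
#> 1         0.208     0.132    0.703       36.7 10.5 1.03e-25
```

The grand-mean stability drops 36.7% below its pre-stimulus baseline,
bottoming out 0.70 s after target onset — inside the designed 0.3–1.0 s
modulation window (the trailing statistic peaks late in the interval).
`autoplot(st$grand)` draws the curve with its across-subject standard
error. The cumulative PC1 loading separates the coupled network from the
two uncoupled channels:

```r
st$loading_map
#>   channel cum_loading
#> 1       0        0.86
#> 2       1        1.65
#> 3       2        1.20
#> 4       3        1.16
#> 5       4        1.05
#> 6       5        1.31
#> 7       6        0.49
#> 8       7        0.55
```

Single recordings go through `run_pipeline()` (preprocessing → WPLI →
WPLIS → epochs → statistics → topography, with a manifest), and
`run_pipeline_stream()` is the causal, chunked variant whose output
matches one-shot causal processing exactly after filter warm-up. A thin
command-line wrapper with per-stage subcommands lives at
`inst/cli/phaselagkit.R`.

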