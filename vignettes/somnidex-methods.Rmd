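---
title: "Methods: automated overnight slow-wave slope and spike analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated overnight slow-wave slope and spike analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

During NREM sleep the EEG is dominated by slow waves. Under the synaptic
homeostasis view, the *ascending slope* of these waves — the magnitude of the
negative peak divided by the time from that peak to the following
zero-crossing, in uV/s — tracks net synaptic strength, and healthy sleep shows
an overnight slope *decline* of roughly 15% in children. In epilepsies with
sleep-activated spikes, this decline is blunted or reversed. The package
implements a fully automated pipeline that quantifies, per overnight EEG
recording:

* the **overnight slope change** `(LH - FH) / FH`, where FH and LH are the
  mean ascending slopes over the first and last 180 20-s NREM2/3 epochs
  (amplitude-matched; negative values = expected decline), exposed as the
  SOMNIDEX index, and
* the **spike-wave index (SWI)**: the percentage of 10-s NREM intervals
  containing at least one detected epileptic spike, per channel; the channel
  with the highest SWI is the *focus channel* on which all slow-wave analysis
  runs.

Because clinical overnight EEG with expert annotations cannot ship with a
package, a first-class synthetic-EEG generator provides recordings with
complete ground truth, and every downstream stage is validated against it.

## Pipeline stages and their parameters

### Preprocessing (`preprocess_recording`)

Zero-phase (forward–backward) filtering with a 0.3–40 Hz Butterworth bandpass
— realised as a 4th-order high-pass at 0.3 Hz cascaded with a 4th-order
low-pass at 40 Hz, because a direct 8th-order bandpass with a normalized
high-pass edge of 0.0047 is numerically fragile — plus a 2nd-order IIR notch
at 50 Hz (Q = 30). Channels are re-referenced to the contralateral mastoid
(odd/left against M2, even/right against M1, midline against the mastoid
mean — the only symmetric choice), and 256 Hz recordings are decimated to
128 Hz after a 6th-order anti-alias low-pass at 0.8 x the target Nyquist.
Other rates are rejected loudly rather than silently resampled. The order
filter → re-reference → downsample is fixed for reproducibility. Incomplete
trailing 20-s epochs are dropped.

### Spike detection (`train_spike_net`, `detect_spikes`)

A stacked LSTM classifies consecutive non-overlapping 16-sample windows
(125 ms at 128 Hz) of the per-recording standardized signal
(median/IQR, so device gain cancels) as spike vs non-spike; supra-threshold
runs merge into events at the run midpoint. The full-scale architecture is
two LSTM layers of 128 units, each followed by dropout 0.1, a 2-unit dense
softmax head, class-weighted cross-entropy (spikes are ~2% of windows), Adam,
six training epochs. The LSTM (forward pass, backpropagation through time,
Adam) is implemented in vectorised base R and verified against numerical
gradients in the test suite.

### Sleep detection (`train_sleep_net`, `predict_sleep`)

Each 20-s epoch is summarized by 12 features: band power of F3-M2, C3-M2 and
O1-M2 in alpha (8–12 Hz), sigma (12–16 Hz), delta (0.75–4.5 Hz) and an
artifact band (30–40 Hz), from Tukey-tapered (r = 0.5) periodograms of the
five 4-s sub-epochs (0.25 Hz resolution), averaged after excluding
sub-epochs within ±0.25 s of a detected spike. Band edges: alpha/sigma are
half-open (12 Hz belongs to sigma), delta and artifact include both edges.
An 11-epoch context window (edge-replicated at the night's boundaries) feeds
two LSTM layers of 64 units (dropout 0.1, 20 training epochs) that label the
centre epoch NREM2/3 vs everything else.

**Feature normalization.** Features are `log10` band power relative to the
recording's mean broadband power. This removes amplifier and montage gain
*exactly* while preserving the absolute spectral shape. A per-feature
z-score — the more common choice — was rejected after it failed a degenerate
but diagnostic case: a recording containing only wake has no internal stage
contrast, so z-scored features collapse to noise around zero and the
classifier's output is arbitrary; gain-relative features keep such a night
looking wake-like.

### Slow-wave analysis (`sw_filter`, `detect_slow_waves`, `amplitude_match`)

The focus channel is band-passed with a Chebyshev Type II filter (pass
0.5–4 Hz, stop edges 0.1 and 10 Hz, 40 dB stop-band attenuation; the order —
4, i.e. an 8th-order bandpass — comes from the standard design equation on
the prewarped edges), applied forward–backward. Negative deflections between
a downward and the next upward zero-crossing separated by 0.25–1.0 s are slow
waves; zero-crossing times are linearly interpolated between samples (which
stabilizes slopes at 128 Hz), the peak is the most negative sample, and no
amplitude floor is applied by default (configurable). Waves whose `[zc1, zc2]`
interval overlaps `[t_spike, t_spike + 0.5 s]` are excluded (interval overlap
is the conservative reading of "occurring in a window of 0.5 s after the
spike"; a peak-in-window rule is available via `post_spike_rule = "peak"`).

First- and last-hour wave sets (first/last 180 NREM2/3 epochs, chronological
NREM order regardless of contiguity) are amplitude-matched in shared 10 uV
bins from 0, keeping `min(count_FH, count_LH)` waves per bin with seeded
uniform subsampling of the larger side. Fewer than 250 matched waves flags
the recording as excluded. Hourly slope summaries are arithmetic means
(median available). Category cut-offs for decrease / no change / increase
default to ±2.5% and are purely cosmetic — reports always carry the raw
index.

### Screening (`screen_recording`)

A recording enters slope analysis when it lasts at least 4 h and at least
360 NREM2/3 epochs were detected — the minimum for disjoint first/last-hour
sets, and this pipeline's operational proxy for "at least 4 h of sleep"
(exact sleep time would require full staging, which the binary detector does
not provide).

## The synthetic-EEG generator

`simulate_recording()` emulates the data regime the pipeline targets:

* **Hypnogram**: a deterministic cycle template (W → N1 → N2 → N3 → N2 → REM,
  90-min cycles, N3-rich early cycles, growing REM share) with seeded jitter;
  presets for N2-only, wake-only and NREM-dominant compact nights.
* **Background**: per-channel 1/f (pink) noise, 8 uV SD by default — a
  realistic floor for pediatric sleep EEG where slow waves of 100–300 uV
  dominate the delta band; mastoids carry attenuated noise only.
* **Slow waves**: full slow oscillations — a negative half-sine of duration
  `d` (drawn uniformly ±20% around 0.55 s) followed by a DC-balancing
  positive lobe of duration `1.5 d` — at 8 waves per NREM epoch,
  non-overlapping on a jittered grid, amplitudes ~N(150, 30) uV. The
  zero-integral morphology matters: an isolated negative half-sine has DC
  content that the analysis filters smear into crossing shifts, while the
  balanced oscillation passes the Chebyshev filter with its slope nearly
  intact.
* **Slope injection**: the overnight change is injected through the half-wave
  *duration* at a fixed amplitude distribution (slope = amp / (d/2)), with
  factor 1 over the first 180 NREM epochs, `1 + slope_decline_frac` over the
  last 180, and a linear ramp between. Injecting through duration rather than
  amplitude is deliberate: amplitude matching must *not* remove the injected
  change, exactly as a physiological slope change at matched amplitude.
* **Spikes**: biphasic transients (20 ms negative lobe at 150 uV, 50 ms
  positive at half amplitude) followed by a 300 ms slow after-wave, at
  per-channel Poisson rates (defaults: focus F3 at 0.2 Hz, others 0.02 Hz).
  The after-wave is itself detectable as a slow wave, so the post-spike
  exclusion rule is exercised by construction. Ground-truth spike time is
  the negative apex.
* **Stage signatures**: 13 Hz spindle bursts in N2 (3 per epoch), continuous
  10 Hz alpha in wake.

What it does **not** emulate: eye movements, EMG and movement artifacts,
electrode pops, inter-patient amplitude and morphology variability beyond
the configured distributions, true microarchitecture (K-complexes, arousals)
and multi-night effects. Passing tests therefore demonstrate correctness of
the algorithms and recoverability of injected effects under realistic SNR —
not clinical-grade performance on hospital data.

## Desk-scale study sizes

The validation studies are sized to run on one CPU: spike training on three
synthetic patients' 10-min focus-channel segments (~14k windows) with
2 x 12-unit LSTMs; sleep training on three 1.5-h nights with 2 x 16-unit
LSTMs (the full-scale defaults of 2 x 128 / 2 x 64 remain the configuration
defaults); parameter recovery on 2.3-h NREM-dominant nights (>= 360 NREM
epochs each), ten seeds per injected value in {-0.15, 0, +0.10}. Training at
these small sizes is initialisation-sensitive, so `train_spike_net()` and
`train_sleep_net()` accept `n_restarts`: several independently seeded
trainings of which the best by final validation kappa is kept — selection on
validation data, evaluation always on held-out patients. With 3 (spike) and
2 (sleep) restarts, held-out window/epoch kappas exceed 0.85 across seeds
and the recovered overnight change is within ±0.03 of the injected value,
seed-averaged.

## Numerical notes and known limitations

* Detected absolute slopes sit ~5–8% below the analytic injected values —
  zero-phase Chebyshev filtering redistributes wave energy — but the effect
  is common to both hours, so the *relative* overnight change is recovered
  essentially unbiased; this is why the index is a ratio.
* In dense wave trains (8+ waves per epoch) filter ringing between adjacent
  oscillations can merge crossings past the 1.0-s gate; at the default
  density ~15–20% of ground-truth waves are lost this way, uniformly across
  the night, without biasing the slope ratio. Detector fidelity itself
  (recall/precision >= 0.9, peak error <= 50 ms) is established on sparse,
  low-noise inventories.
* The slow-wave detector reports peaks at sample resolution (zero-crossings
  are sub-sample); peak-time accuracy is therefore limited to ~2 samples.
* Spike-detector false positives at posteriors barely above 0.5 appear when
  network capacity is cut too far (2 x 8 units); 2 x 12 units restores clean
  separation at the default 0.5 threshold.
* The SWI follows the percent convention (share of 10-s NREM intervals with
  at least one spike); the raw mean spike count per interval is reported
  alongside for transparency.
* The rank-sum comparison of FH vs LH slopes is implemented unpaired, as in
  the study design it mirrors; a paired alternative would be more powerful
  but is deliberately not substituted.
* `select_fh_lh` takes the chronologically first/last 180 NREM epochs
  regardless of fragmentation; with exactly 360 NREM epochs FH and LH are
  adjacent but disjoint, below that the recording is flagged
  `insufficient_nrem`.
* There is no on-disk stage cache: a full rerun of a recording takes tens of
  seconds at these problem sizes, and every report embeds the configuration
  hash and model seeds needed to reproduce it exactly, which we consider the
  safer provenance contract than cache reuse.
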