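---
title: "Methods: familiar-face breakthrough analysis for RSVP EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: familiar-face breakthrough analysis for RSVP EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fringep3)
```

## The problem

In the Fringe-P3 concealed-information paradigm, faces are presented in a
rapid serial visual presentation (RSVP) stream at one screen location, one
item every 133 ms. Most items are unfamiliar distractors; occasionally a
critical face appears — a task-relevant **Target** the participant searches
for, a personally familiar **Probe** the participant is not told about, or
an unfamiliar **Irrelevant** matched to the Probe. At this presentation
rate, only salient items "break through" into awareness. Breakthrough of
the Probe, indexed by EEG, is evidence that the face is familiar to the
observer — the basis of a concealed-information test that needs no overt
response about the Probe.

Two signatures carry the inference at parietal midline sites: a muted
face-related negativity around 400 ms (N400f) and a late positivity around
600 ms (P600f); the Probe additionally shows a slow (~3–4 Hz) multi-cycle
stimulus-locked oscillation within roughly 280–620 ms, which motivates
time-frequency measures — event-related spectral perturbation (ERSP, the
trial-average power change against the pre-stimulus baseline, in dB) and
inter-trial coherence (ITC, the resultant length of per-trial unit phase
vectors, in [0, 1]).

The package implements the full inference chain — preprocessing,
contrast-orthogonal window placement, per-participant Monte-Carlo
randomisation tests, time-frequency inference, and group-level paired
tests — together with a synthetic cohort generator so that every stage is
testable without access to recorded data.

## The analysis chain

### Preprocessing

Continuous recordings are band-pass filtered 0.5–45 Hz and notch filtered
7–9 Hz (removing the steady-state visual evoked potential, SSVEP, that the
~7.5 Hz stream sets up), resampled to 512 Hz, re-referenced to the average
of the mastoids, and cut into −200…1200 ms epochs time-locked to the
critical face. All filters are zero-phase (forward–backward Butterworth:
order-2 high-pass, order-4 low-pass, order-2 band-stop), because causal
filtering would shift exactly the slow component latencies the method
measures. Trials with any EOG sample beyond ±100 µV or any EEG sample
beyond ±50 µV are rejected; the thresholds are applied to the signal as it
stands at that stage (filtered, not yet detrended — the source analyses do
not state the order, so the package fixes one and records it in the
rejection report).

Data that enter the pipeline already epoched (synthetic cohorts) receive
the SSVEP notch at the epoch level (`notch_filter_epochs()`), with each
trial reflection-padded before filtering because an order-2 notch rings
longer than a 1.4 s epoch's edges can absorb.

### Detrending and baseline

Slow drift is poison for extreme-window selection: a drifting record puts
the "most positive 100 ms" at the end of the epoch regardless of any
component. Instead of stronger high-pass filtering (which distorts slow
components), a line is fitted by ordinary least squares to the **combined**
Probe+Irrelevant trial average over the full epoch, per channel, and that
same line is subtracted from every trial of both conditions
(`detrend_pair()`). Baseline correction (mean of −100…0 ms per trial)
follows **after** detrending; the reverse order would tilt the data the
line is fitted to. The Target condition is baseline-corrected only — the
detrend is defined on the contrasted pair.

### Contrast-orthogonal window placement

Measuring a component in a window chosen to favour one condition biases
the contrast. The package therefore places every analysis window on
aggregates that are symmetric in the conditions:

* per participant, the **aERPt** — the average of all Probe and Irrelevant
  trials pooled (trial-weighted, so unequal post-rejection counts weight
  accordingly);
* at group level, the **AGAT** — the aggregated grand average of all
  trials of all participants and both conditions.

`find_extreme_window()` scans every start sample in 0–1200 ms for the
100 ms interval with the maximal mean (P600f) or minimal mean (N400f);
ties break to the earliest start. Because the aggregate is invariant to
permuting condition labels, so is the window — a property the test suite
checks directly. A narrower a-priori late-positivity search band
(300–900 ms) can be supplied through `search_bounds_ms`.

### Per-participant randomisation test

For one participant, with `m` the smaller post-rejection trial count, `m`
trials are drawn from each condition without replacement; their per-trial
windowed means form a 2m-row matrix. The observed statistic is the mean
difference between the condition halves. On each of `n_iter` iterations
(1000 by default) the rows are permuted and re-split, and both components'
surrogate differences are computed **from the same permutation**. The
p-value is directional by component polarity — the proportion of
surrogates at or above the observed value for the maximal component, at or
below for the minimal one — with ties counted as exceeding, which makes
the estimator conservative and bounds p away from 0 at 1/`n_iter`.
Add-one smoothing `(b+1)/(n_iter+1)` is available but off by default.

### Time-frequency analysis

`tf_decompose()` computes a sliding Hann-tapered Fourier transform per
trial (512 ms taper, one frame per ~12 ms, phase referenced to epoch time).
Two numerical choices matter and are deliberate:

* **Reflection padding.** Frames near the epoch edges — including the
  −100…0 ms baseline frames — would otherwise carry truncated tapers.
  Truncation widens the low-frequency bins exactly where the 1/f
  background is steepest, so edge frames over-collect power and the
  aggregated ERSP time course tilts toward the trailing edge, where the
  window scan would then lock on. Each trial is instead reflected by half
  a taper at both ends so every frame sees a full-length taper.
* **No per-trial baseline subtraction before the transform.** Subtracting
  a trial's −100…0 ms mean removes a DC constant that the tapered
  transform would ignore at ≥2 Hz, but it is *correlated* with the signal
  in frames overlapping the baseline window, suppressing their power —
  and those frames are what the ERSP dB baseline is computed from.
  Time-frequency analysis therefore runs on detrended, non-baselined
  trials; the ERP chain keeps its baseline correction.

Frequencies whose period exceeds the taper (below ~2 Hz for the default
512 ms) are dropped with a warning, so the "0.5–7 Hz" narrow band is
realised as 2–7 Hz on the default grid; the full band is 2–45 Hz.

ERSP divides trial-mean power by the per-frequency mean baseline power and
takes 10·log10; zero baseline power is floored with a warning. ITC takes
the modulus of the mean unit phasor; zero-magnitude coefficients
contribute zero and are counted. ERSP is invariant to a global amplitude
scale, ITC to per-trial scales — both are tested properties.

Window placement pools both conditions' trials, computes the aggregated
measure, collapses the band by an unweighted mean over frequency bins, and
runs the same earliest-tie 100 ms scan. The test statistic in the fixed
window is the **positive sum** — the sum of values above zero over band ×
window bins, per condition — and the contrast is Probe minus Irrelevant.
The permutation test shuffles trial labels exactly as in the time domain
and recomputes both conditions' measures per permutation from cached
per-trial coefficients (the coefficients themselves are label-free, so
caching changes nothing statistically and keeps the 10000-iteration
narrow-band default affordable). The window is held fixed across
permutations; since its placement is label-invariant, re-deriving it per
permutation would be a no-op in expectation.

### Group level and behavior

Group inference on any per-participant measure pair (windowed mean
amplitudes, positive sums, ratings) is a two-tailed paired t-test:
`t = mean(d)/(sd(d)/sqrt(n))` on `n − 1` degrees of freedom, with the
effect size in the pooled-condition-SD form
`d = mean(d) / sqrt((sd_Probe² + sd_Irrelevant²)/2)`. This form is used
because it reproduces the published group rows from their printed
condition summaries to four decimal places; `paired_t_from_summary()`
exposes the (M, SD, n) → t mapping directly. With all differences equal
the variance is degenerate and the functions refuse rather than return
±Inf.

Behavioral measures: d′ = z(hit rate) − z(false-alarm rate), with extreme
rates adjusted by the 1/(2N) rule (logged; the adjustment never fires on
interior group-mean rates); recognition ratings on the 1–5 scale map to
percent-of-scale by `(r − 1)/4 × 100`, and the Probe-vs-Irrelevant rating
comparison uses the same paired machinery (t is invariant to the affine
map, so raw ratings are used). A Holm step-down utility is provided for
families of group tests, with no claim that any published correction used
exactly that procedure.

## The synthetic cohort generator

`sim_params()` fixes the cohort conditions: 14 participants, 75 trials per
condition at 512 Hz over −200…1200 ms, channels Pz/Cz/Fz (+ VEOG/HEOG)
with parietal-dominant gains (1, 0.8, 0.7). Per condition the trial is a
deterministic template — Probe: a Hann-windowed 3.5 Hz sinusoid confined
to 280–620 ms plus a Gaussian late positivity at 500 ms; Irrelevant: a
negative Gaussian peaking at 300 ms; Target: a positive Gaussian peaking
at +8.5 µV around 550 ms — jittered in latency per trial, scaled by
per-trial and per-participant amplitude factors, and buried in 1/f + white
+ 10 Hz alpha noise with a stimulus-locked SSVEP at 1000/133 Hz, a linear
drift, and optional blink artifacts whose VEOG transients exceed the
rejection threshold by construction.

Latency jitter is the ITC dial: at jitter SD σ the phase of an f Hz
component disperses by 2πfσ, so band ITC in the burst window falls
monotonically with σ — a tested invariant. The RNG is stream-stable:
every stochastic element draws standard normals scaled by its parameter,
so setting a variance parameter to zero leaves all other draws unchanged,
and each participant/condition/stage has its own seed derived from the
master seed by a fixed counter scheme (`derive_seed()`).

**Calibration.** The sources never quantify the Probe burst or deflection
amplitudes in µV, so these are free parameters. They were calibrated
against the published *group* statistics — the time-domain late-positivity
t/d, and the narrow-band ERSP and ITC effect sizes — by simulating default
cohorts at several seeds and adjusting three knobs once: burst amplitude
(4.5 µV) raises both power change and coherence, latency jitter (40 ms)
trades coherence against power, and the late-positivity amplitude (2.4 µV,
whose sub-2 Hz spectral content barely enters the analysis band) sets the
time-domain effect independently. At these defaults a default cohort
reproduces the published ordering and approximate magnitudes: parietal
late positivity strongest, narrow-band ERSP effect ~d 1.2–2, ITC effect
present but weaker, face negativity near null. Per-participant
significance rates land below the published 57–71% (around 35–45% at Pz);
pushing them up would overshoot the group effect sizes, which are the
harder anchors, so the group statistics won the trade-off.

**What the generator does not emulate.** No volume conduction (channel
gains are fixed scalars, so topography is caricature); no trial-to-trial
autocorrelated state changes (fatigue, vigilance); noise is stationary
Gaussian 1/f + white + alpha rather than real EEG's nonstationary mixture;
blinks are stereotyped Gaussians; behavioral responses are independent
Bernoulli draws. Passing calibration therefore shows the *inference
machinery* behaves correctly on data with the assumed structure — it is
not evidence about any particular recording.

## Degenerate inputs and numerical conventions

Epochs are half-open sample grids `[start, end)` with 0 ms always on the
grid; windows are half-open in time and sized in samples
(`round(width · rate / 1000)`). Empty conditions, windows outside the
epoch, mismatched axes, fewer than two trials per condition, out-of-range
ratings or p-values, and zero-variance group differences all raise typed
errors naming the offending quantity. Ties in window scans break earliest;
ties in permutation tests count as exceeding. The text containers
round-trip epoch arrays at ~1e−8 µV (ASCII decimal), which is far below
any threshold in the chain.

## Problem sizes in the test suite

The suite exercises the machinery at sizes chosen to make each property
visible: oracle equivalence on 100+100 random inputs; type-I calibration
of the randomisation test on 200 null datasets of 60+60 trials at 500
iterations; group calibration on one default 14 × 75 cohort (effect on)
and twenty replicate null cohorts (condition differences off); the jitter
grid {0, 20, 40, 80} ms at 75 trials with the between-participant factor
fixed at 1 so the comparison is single-factor. The acceptance script
recomputes the published effect sizes from their printed summary inputs,
which takes no appreciable time.

## Known limitations

* The narrow band starts at 2 Hz, not 0.5 Hz: resolving 0.5 Hz would need
  a ≥2 s taper, longer than the epoch.
* The per-participant significance rates of the synthetic cohort are not
  a quantitative match to the published tables (see Calibration).
* Continuous-input support expects the in-memory container or the text
  format; there is no EDF reader in this implementation.
* The paired t at a data-driven (contrast-orthogonal) window is exact
  under Gaussian exchangeable conditions; with unequal post-rejection
  trial counts it is only asymptotically exact, and large null
  simulations suggest its size is within a few points of nominal.
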