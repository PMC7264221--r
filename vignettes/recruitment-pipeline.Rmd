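---
title: "From fluorescence movies to recruitment statistics: the methods behind spikepeel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fluorescence movies to recruitment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikepeel)
library(dplyr)
```

## The problem

Epileptiform network activity in neuron–astrocyte co-cultures is commonly
probed with a potassium-channel blocker (4-aminopyridine, 4-AP) while the
population is imaged with a calcium-sensitive dye at a modest magnification
(whole-field view, 20 frames/s).  Two distinct phenomena have to be
separated: neurons that were already firing may fire *faster*, and neurons
that were silent may be *recruited* into activity.  The read-outs are
therefore per-neuron firing rates, the number/fraction of active neurons,
and the global firing rate of the culture (total spikes per unit time,
summed over neurons), each collapsed to one value per culture ("one
experiment, one observation") before any group statistics.

`spikepeel` implements that entire chain — movie → ROIs → traces →
%ΔF/F → classified neuronal traces → inferred spikes → culture summaries →
two-factor ANOVA — together with a seeded synthetic-data generator that
emulates the basal → 4-AP protocol, so every stage is testable without any
recordings.

## The synthetic generator: what it emulates

A culture is `n_neurons` units.  A fraction `silent_fraction` (default
0.5) fires not at all at baseline; the rest fire as homogeneous Poisson
processes at `basal_rate_hz` (default 0.05 Hz).  In the 4-AP window,
active neurons multiply their rate by `fourap_rate_multiplier` (default
3), and each silent neuron is independently recruited with
`recruitment_prob` — the parameter whose genotype-dependence is the
scientific question.  Spikes drive a non-saturating single-exponential
fluorescence transient (amplitude 1 %ΔF/F, decay τ = 3 s) superposed on a
slow sinusoidal baseline drift (default 5 % of the baseline level with a
300-s period — smooth enough to be spline-recoverable) plus white Gaussian
noise (default 0.2 %ΔF/F, i.e. an amplitude-to-noise ratio of 5).
Recordings default to 10-min windows.  Artifact (non-neuronal) traces of
three stylised classes — flat low-variance, slow large-amplitude waves,
and step discontinuities — can be appended for classifier training,
10 % of traces by default.

What it does *not* emulate: calcium-indicator saturation and buffering,
photobleaching, photon-shot (signal-dependent) noise, motion, overlapping
somata, or correlated network bursting.  Passing tests therefore
demonstrate the correctness of the analysis chain under its stated model,
not robustness to every property of real movies.  Culture-to-culture
variability magnitudes are free parameters, not fitted values.

All randomness flows from one integer seed; per-culture and per-stage
sub-seeds are derived deterministically, so an identical configuration
reproduces bit-identical spike trains, traces and movies.

```{r generator}
cfg <- sim_config(n_neurons = 6, duration_s = 120, seed = 1)
st  <- simulate_spike_trains(cfg, "basal")
raw <- render_traces(st, cfg)
raw
```

## ROI detection and trace extraction

Cell bodies are found on the time-averaged movie.  No particular
detection operator is canonical for this preparation, so the package
uses a parameter-free and auditable choice: Otsu's global threshold on the time average, 8-connected
components, and an area filter (defaults 20–600 px, suited to a ×10-like
field).  Traces are the spatial mean of each ROI's pixels, which is linear
in the movie — a property the tests exploit.

## Baseline correction and normalization

Each trace is smoothed with a centered moving average (default 5 frames =
0.25 s at 20 Hz; edge windows truncate).  The smoothed trace is cut into
50-s blocks; in each block the sample whose value is nearest the 10th
fluorescence percentile (linear-interpolation convention; earliest sample
on ties) becomes a reference point at its own time coordinate.  A cubic
spline through the reference points, held constant beyond the first and
last of them, is the baseline F₀; the *original* (unsmoothed) trace is
then normalized to 100 × (F − F₀)/F₀.  With roughly a dozen reference
points per 10-min trace an interpolating spline is already smooth, so the
default spline passes through the points; a penalised fit is available via
`spar`.  A trailing partial block keeps its own reference point when it
holds at least a quarter of a block, and is merged into the previous block
otherwise.  Reference points are picked on the smoothed trace (the raw
option is exposed), because percentile picking on raw noise biases F₀
downward by the full noise quantile rather than the smoothed one.

Two consequences worth knowing.  First, the 10th-percentile rule biases
F₀ low by about 1.3 noise standard deviations of the *smoothed* trace;
after normalization this appears as a small positive offset (~0.1 %ΔF/F at
default noise).  Second, constant extrapolation outside the reference span
can leave an uncorrected drift segment of up to half a block at each end
of the recording.  Both motivated a detection-stage design choice
described below.

## Trace classification

Traces are selected as "neuronal activity" by discrete AdaBoost over
depth-1 decision stumps (50 rounds, deterministic exhaustive stump
search), trained from manually labelled examples, with initial sample
weights inverse to class frequency.  The seven features (SD, skewness,
excess kurtosis, maximum amplitude, excursion count above 0.5 %ΔF/F, 1-s
autocorrelation, low/high spectral power ratio split at 0.5 Hz) are
deliberately few and interpretable: the classifier is an auditable filter,
not a contribution.  A refinement loop (`refine_training_set()`) lets
corrections override labels, increments a round counter and keeps an audit
trail, mirroring iterative visual curation.  One generator-specific
caveat: a *silent* neuron's trace and a flat artifact trace differ only in
noise scale, so the generator gives flat artifacts half the neuronal noise
sd; in real data this distinction would rest on morphology or indicator
localisation instead.

## Peeling spike inference

The transient kernel is k(j) = A·exp(−j/(τf)) with A = 1 %ΔF/F, τ = 3 s,
f the frame rate, truncated where it falls below 1 % of A (≈ 13.8 s at
20 Hz).  Peeling is greedy detect-and-subtract: find the onset with the
largest implied event amplitude, and if it reaches the threshold (default
A/2), record a spike there, subtract *one* unit template, and repeat on
the residual.  Superposition is linear, so several spikes may share a
frame and there is no refractory constraint.  Spike time is the template
onset frame; no sub-frame interpolation is attempted.  By construction the
sum of subtracted templates plus the residual reconstructs the input
exactly, and at termination no location passes the detection criterion.

The implied amplitude is, by default, the least-squares amplitude of one
template *jointly with a local constant (DC) offset* over the template
support, rather than the raw matched-filter projection.  The reason is the
baseline paragraph above: residual slow-baseline error — especially the
constant-extrapolation segment at the recording edges — projects strongly
onto a one-sided decaying kernel and, at the generator's default drift,
turns into dozens of spurious events per trace under the plain filter.
Orthogonalising against a local constant removes that failure mode while
leaving noiseless recovery exact; the plain filter remains available
(`local_dc = FALSE`).  The price is identifiability: onsets so close to
the end of the recording that the DC-orthogonalised template retains less
than 25 % of its energy (the last ~4.5 s at 20 Hz) are excluded from
detection.  A noise-adaptive threshold (3 × MAD of the first-difference
noise estimate) is available as `threshold_pct = "mad"`.  The safety cap
`max_iter` defaults to 10 events per second of trace.

```{r peel}
k <- transient_template(calcium_transient(), 400, 20)
x <- numeric(400); x[100 + seq_along(k) - 1] <- k
peel_trace(x, calcium_transient(), 20)$spike_frames
```

A whole recording is peeled once; spikes are then assigned to analysis
windows (basal / 4-AP) by onset time, and frames in the stabilization gap
between windows belong to no window.

## Metrics and statistics

Per window and culture: mean per-neuron firing rate (over *all*
classifier-accepted neurons, including silent ones), active-neuron count
(≥ 1 inferred spike) and fraction (denominator = classifier-accepted
neurons), and global firing rate (total spikes / window duration, not
divided by neuron count; a per-neuron variant is a flag, since "average
number of total spikes per unit time" is ambiguous).  These culture-level
rows — not neurons — are the statistical units.

The comparison stage is a two-factor ANOVA (genotype × treatment) with
Type II sums of squares, chosen because the reference design is unbalanced
(10/10/5/5 cultures) and Type II reduces to the classical decomposition
when balanced; treatment is modelled as a between-culture factor, matching
the 26-residual-degrees-of-freedom layout of a 30-culture design rather
than a repeated-measures model.  Bonferroni post hoc comparisons use pooled-MSE
two-sample t statistics with p multiplied by the number of comparisons and
capped at 1.  Residual normality (Shapiro–Wilk) is reported as a
diagnostic only — published branching rules to non-parametric tests are
not algorithmic, so the package does not branch.  Incidence counts are
compared with the Pearson 2×2 chi-square (optional Yates correction).
One documented discrepancy: for event counts 8/18 vs 8/21 the Pearson
statistic is 0.1615 (p ≈ 0.69), whereas the value printed alongside those
counts in the literature this design follows is 0.255 (p = 0.613); the
variant behind the printed value is unstated, and the package reports the
formula-derived number.

```{r stats}
smry <- run_recruitment_experiment(
  recruitment_design(c(4, 4, 3, 3)),
  sim_config(n_neurons = 60, duration_s = 300, seed = 2)
)
tidy(two_way_anova(smry, "n_active", "genotype", "treatment"))
```

## Problem sizes and numerical choices

The validation suite runs at deliberately chosen desk scales: peeling
accuracy is scored on 20-trace cultures of 10 minutes at 20 Hz (F1 against
ground truth at ±1 frame); baseline recovery on 6 traces; and the
recruitment power analysis on 100 replicate experiments of the full
10/10/5/5 × 200-neuron design simulated at the spike-train level (the
generator → metrics → ANOVA chain).  Running each of those 100 replicates
through trace rendering and peeling (6 000 traces × 12 000 frames each)
adds nothing statistically — recruitment detection depends only on the
presence of ≥ 1 spike, and the trace stages are validated separately by
the peeling F1 benchmark and by a direct check that peeled and
ground-truth metrics agree culture by culture — so the replicate loop uses
ground-truth spike trains by design.

Other numerical choices: percentile type 7 (linear interpolation) for
reference points; natural cubic splines; ties in percentile matching
resolve to the earliest sample; which-max ties in peeling resolve to the
earliest onset; all seeds are 32-bit integers derived by a fixed
congruential mix so that sub-streams are reproducible independently of R's
global RNG state.

## Known limitations

* The "modified" peeling variant and detection threshold of the original
  analysis software are unpublished; spike-count equivalence with it
  cannot be claimed, only the stated properties of this implementation.
* The classifier's feature set is an artifact choice; with the generator's
  stylised artifact classes its held-out accuracy (≥ 95 % in tests) says
  little about curation effort on real movies.
* Baseline estimation assumes drift varies slowly relative to 50-s blocks
  and that transients occupy a minority of each block; dense bursting
  violates the lower-envelope assumption and will bias F₀ upward.
* The DC-orthogonalised detector is blind in the last few seconds of a
  recording (see above); for 10-min windows this is < 1 % of the data.
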