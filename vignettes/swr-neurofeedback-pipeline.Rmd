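---
title: "Closed-loop SWR neurofeedback: models, detectors, and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop SWR neurofeedback: models, detectors, and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the online and offline sharp-wave-ripple (SWR) detectors,
the closed-loop neurofeedback task, the clusterless state-space
decoder, the replay-content analyses, and the statistics layer — all
exercised on synthetic multi-tetrode data with known ground truth.

## The problem

Hippocampal SWRs are transient 150–250 Hz bursts in CA1 local field
potentials, prominent during immobility. In an SWR neurofeedback
paradigm, a rat holding its nose at a center port is rewarded the
moment an online detector sees a sufficiently large SWR; yoked "delay"
trials reward after a matched elapsed time with no SWR contingency.
Downstream analyses ask whether feedback changes SWR rates, sizes,
their replay content, and task behavior. This package reproduces the
*procedures* of such an experiment on simulated data; it makes no
claims about any recorded animal.

## Online detection

Per tetrode, the ripple-filtered (causal 4th-order Butterworth,
100–400 Hz, 1500 Hz sampling) trace `x` feeds two iterative
estimators. The baseline mean and deviation (smoothing constant
`N = 10^4` samples) are

```
mu'    = mu * (N-1)/N + |x| / N
sigma' = (||x| - mu| - sigma) / N + sigma
```

with the sigma update using the *previous* mu. During calibration
(rest-box data, 60 s by default) these run freely and are then frozen;
the detection threshold is `mu + k * sigma`. The envelope estimator is
asymmetric so that power increases are tracked quickly:

```
v' = v + g * (|x| - v)
```

where `g = 0.2` while the envelope is decreasing and otherwise the
mean of 1.2 and the last 19 gains. We read the envelope update with
the dropped parentheses restored (`v + g*(|x|-v)`, not `g*|x| - v`),
since only the former is a smoother; the literal last-step-gain
variant is available via `literal_gain`. The gain history starts
filled with 0.2 and the envelope seeds from the first sample, so
startup transients do not dominate calibration. A trigger fires when
at least two tetrodes' envelopes are above threshold at the same
sample (1500 Hz); the streaming core carries filter and estimator
state so that any chunking of the input is bit-identical to a single
pass. The trial ends at the trigger, so the default lockout is zero;
free-running use should set one.

## Offline detection

Ripple filtrates (zero-phase, 150–250 Hz) are squared, summed over
tetrodes, smoothed with a 4 ms SD Gaussian kernel, and square-rooted,
giving the consensus trace. Events are intervals exceeding
`epoch_mean + 2 * epoch_sd` for at least 15 ms, extended to the
nearest epoch-mean crossings; overlapping extended events are merged
(extension makes overlap otherwise ill-defined). Event *size* is the
maximum threshold at which the event would still be detected — the
peak height above the epoch mean in epoch-SD units — and *length* the
extended duration. Epoch statistics include event samples (the
simplest reading of "epoch mean"); an exclude-events iteration is not
applied by default.

## The synthetic world

`gen_background_lfp()` produces pink (1/f) plus white noise per
tetrode in equal parts: the 1/f component gives the spectrum its
LFP-like tilt while the white component keeps a nonzero ripple-band
floor, so SD-unit thresholds are meaningful. `inject_ripple()` adds a
Gaussian-windowed sinusoid (envelope SD = duration/4, frequency drawn
from the ripple band) scaled by a two-stage calibration: a quadrature
solve against mean background power, refined by root-finding on the
realized local consensus maximum, so the offline measure of the event
on the otherwise-clean background equals the requested size. Because
every event is calibrated against the clean background, injections
commute and are sample-wise additive.

Event times are inhomogeneous Poisson draws with per-state rates and a
100 ms minimum gap (thinning), preventing ground-truth overlap that
would make recovery scoring ambiguous. Sizes follow a shifted
lognormal (default `2 + lognormal(meanlog 1.6, sdlog 0.7)`, median
about 7 SD), long-tailed so that larger events are rarer. Together
with a stable-period task threshold of 8 SD this keeps the mapped
online operating point above the online noise floor (so that every
completed NF trial's trigger is attributable to a ground-truth event)
while keeping event sizes moderate enough that they do not inflate the
offline epoch statistics and mask small-event recovery. Durations are uniform on 40–120 ms —
a free choice, since no duration distribution is prescribed by the
emulated design.

Place cells tile the linearized track with Gaussian tuning (width 8
cm, peak rates 15–25 Hz); their 4-D mark means sit on a randomized
lattice whose spacing guarantees at least 6 Mahalanobis units of
separation (rejection sampling is hopeless in 4-D at realistic cell
counts). Movement spiking is inhomogeneous Poisson along a trajectory
that cycles maze endpoints in shuffled blocks, giving even arm
coverage for encoding. Replay spiking traverses a chosen bin path at
`compression` (default 20×) times run speed with rates scaled by the
compression factor, preserving spikes-per-distance.

What the generator does *not* emulate: biophysical LFP (no theta,
gamma, or spike leakage), bursty non-Gaussian background, electrode
drift, cell non-stationarity, or sorting artifacts. Passing tests
therefore demonstrate internal consistency of the analysis chain and
parameter recovery under the stated statistical assumptions, not
performance on recorded animals.

## The closed-loop task

The trial machine runs: home poke → travel → center poke → pre-reward
period → reward (feedback delay 75 ms default) → post-reward dwell →
arm choice, with goal blocks that redraw the rewarded arm after a
4–12-visit quota. Neurofeedback trials stream fresh synthetic LFP
through the online detector until the coincidence trigger; delay
trials draw their duration uniformly from the last 8 NF latencies
(yoking), or from 2–10 s before any history exists. The day-maximum
threshold ramps linearly from 4 SD to the configured maximum across
the ramp days; within an epoch the threshold steps linearly to the day
maximum over the first 10 NF trials.

Thresholds are configured in offline consensus-SD units and mapped to
the online envelope scale by `online_size_map()`: injections over an
amplitude grid are streamed through the detector and the per-sample
second-largest envelope (exactly the statistic the same-sample
two-tetrode coincidence rule thresholds) is summarized by per-
amplitude medians made monotone. The closed-loop latency experiment
(`closed_loop_latency_experiment()`) instead applies thresholds
directly on the online envelope scale — the scale on which the
real-time system expresses them — with a stationary generator whose
size distribution spans the tested thresholds through the inverse
calibration map; predicted waits are `1/(rate * P(size >= threshold))`
on that scale. On the synthetic background the online and offline SD
scales differ by roughly a factor of five (the consensus trace's
multi-tetrode averaging and 4 ms smoothing shrink its SD), so offline
2–4 SD events sit near the online noise floor; this scale split is a
property of the Gaussian background, documented rather than hidden.

Segments are generated with hidden 0.3 s padding on each side, so the
event process runs at full rate up to segment edges (waveforms spill
into the discarded padding); without padding, per-chunk margins
depress effective rates and bias waiting times upward.

The wait-time prediction analysis bins center-port event sizes (1 SD
bins, at least 10 events per bin), converts counts to occurrence
rates by total port time, and predicts each trigger's wait as the
reciprocal of the cumulative rate of all tabulated bins at or above
the trigger's bin — a threshold trigger fires on the first event at or
above threshold, so the cumulative tail is the default and the per-bin
variant a switch. A 200-trial trailing moving average smooths actual
and predicted series.

## Clusterless decoding

Position is linearized onto a track graph (home 60 cm, center 30 cm,
eight 80 cm arms fanning from the junction; 5 cm bins) by projecting
2-D samples to the nearest segment, ties to the lower-indexed segment,
samples beyond 20 cm flagged off-track. The encoding model is a
kernel-density joint mark–position intensity per tetrode (product
Gaussian kernels; mark bandwidth 20 uV, position bandwidth 5 cm,
geodesic distance on the graph), built only from movement samples
(speed > 4 cm/s), with ground intensity = spike density / occupancy.

Decoding runs in 2 ms bins: the Poisson marked-point-process
likelihood `exp(-dt * sum(ground)) * prod(joint at observed marks)`
(with a 1e-10 uniform intensity floor against zero-likelihood
collapse) drives a two-state hidden Markov model. The continuous
state moves with equal probability over a bin's graph neighbors and
itself (junction bins include all neighbors); the fragmented state
jumps uniformly over all other bins. The discrete state matrix is
diagonally dominant (stay 0.98) by default: a truly uniform 0.5/0.5
matrix makes sustained-state classification meaningless, so the
uniform variant is exposed as an option rather than the default.
Forward filtering with backward smoothing yields the joint posterior,
normalized per time bin; a causal-only mode exists. Movement
validation always excludes the decoded spike from the kernel sums
(leave-one-spike-out); the spike's contribution to the ground
intensity (one of thousands) is left in place, a deliberate 1/n
simplification.

## Replay content

An event is *interpretable* when the time-averaged probability of the
continuous state strictly exceeds 0.8 (the time-average reading of
"during the event"; a pointwise-minimum variant is exposed) and at
least 30% (inclusive) of the time-averaged position posterior falls in
one maze segment. Interpretable events are *local* when the dominant
segment is the animal's segment and *remote* otherwise — dominance
doubles as the "majority" rule, avoiding a second threshold. Remote
replay rates divide remote counts by period durations per trial;
interpretable fractions are per epoch; trigger SWRs are excluded from
rate metrics by default, consistent with the timewise-rate rules.

The arm-category generalized linear model regresses per-arm,
per-trial remote replay counts on three binary predictors — previous
arm (the arm of the immediately preceding trial), future arm (the
current trial's choice), previous goal arm (the previous block's
goal) — with a Poisson likelihood; trials from the second goal block
onward contribute eight rows each so every trial has a valid previous
goal. Coefficients exponentiate to fold changes with Wald intervals;
an arm in two categories carries both indicators (effects add on the
log scale).

## Statistics layer

Reward-aligned timewise rates use 0.5 s bins fully inside the port
interval, at least 100 contributing trials per shown bin, and exclude
the NF trigger SWR. Period metrics count events by peak time in
pre-reward (poke → reward) and post-reward (reward → exit) windows;
the suprathreshold exclusion removes events at or above the trial's
threshold from both NF and delay trials, countering the structural
guarantee of exactly one suprathreshold event per completed NF trial.
Speed controls compare the fastest NF quartile against the slowest
delay/control quartiles (rank selection, index tie-break; speed
smoothed with a 250 ms SD Gaussian). Within-subject NF-vs-delay
contrasts use two-sided Wilcoxon rank-sum tests with
Benjamini-Hochberg step-up correction across the comparison family;
groupwise contrasts use mixed models (lme4/lmerTest) with fixed group
effects against the control cohort and a subject random intercept —
linear families for rates, dwell, size, and proportions (the
boundedness of proportions is a documented simplification), Poisson
for counts. Sign tests are exact binomial; pre/post correlations are
Pearson with t-based p-values.

## Numerical choices and problem sizes

Filtering uses `signal`'s Butterworth designs — causal single-pass in
the loop, zero-phase forward-backward offline. Gaussian smoothing
reflects at the edges so constants map to themselves. The
forward-backward smoother normalizes each step, keeping posterior
columns at 1 within 1e-9; the 10-bin enumeration oracle agrees to
1e-10. Default study sizes keep everything on one core: 180 s encoding
trajectories with 30 cells, 10-minute detector sessions with 150
events, 60–110 closed-loop trials per threshold, 50+50 replay
classification events, 100-run GLM coverage loops, and a 3+3-subject
two-cohort experiment with 24–30 trials per subject. These sizes were
chosen so the full suite completes comfortably on a laptop while
leaving the statistical checks adequately powered.

## Known limitations

The online/offline SD-scale split discussed above means task
thresholds quoted in offline units compress on the online scale.
Aborted NF trials (no trigger within 300 s) are capped rather than
discarded. The agent is a parametric policy, not a learner: behavioral
metrics have controllable ground truth but no acquisition dynamics.
Session serialization stores LFP as float32, so round-trips are exact
only to single precision.
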