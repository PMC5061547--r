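---
title: "Models and methods: neural progress coding in sequential save-spend tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: neural progress coding in sequential save-spend tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saveseq)
library(dplyr)
```

## The task and its value model

`saveseq` studies a sequential economic choice task in which a subject
chooses, trial by trial, to *save* an available liquid reward — letting it
grow at an interest rate — or to *spend* (consume) the accumulated amount,
which ends the current saving sequence. On the n-th trial of a sequence the
amount at stake is the geometric sum

$$x_n = b \sum_{i=0}^{n-1} q^i,$$

with base rate $b$ (ml) and interest rate $q$; `accumulate_reward()`
implements this (with the closed form $b(q^n-1)/(q-1)$ for $q \ne 1$,
verified against term-by-term summation in the tests). Sequence lengths are
self-determined, so the central behavioral variable is *sequence progress*:
the cumulative number of completed correct trials since the sequence began.

Subjective values derive from the subject's own length preferences. With
$P_i$ the probability of producing a length-$i$ sequence and $M_i = x_i$ the
objective amount at step $i$, the spend value is $SV^{spend}_i = P_i M_i$
and the save value at step $n$ is the mean future spend value
$\frac{1}{m-n}\sum_{i=n+1}^{m} SV^{spend}_i$, with $m$ the maximal observed
length. $P_i$ is the raw relative frequency per interest rate (no
smoothing; unobserved lengths get zero), and the value realized at a
sequence's actual length serves as that sequence's value. At step $m$ no
future spend exists; the save value there is defined as 0 so the full
multiple-regression design is complete on every trial.

## What the synthetic-data generator emulates

`generator_config()` + `generate_behavior()` produce complete sessions:
sequence lengths drawn i.i.d. from a per-interest-rate distribution
(defaults: lengths 2–5 peaked short at $q = 0.5$, lengths 3–7 peaked long at
$q = 1.5$, mirroring the preference shift toward longer sequences at higher
interest; the minimum length is 2 because one save choice is required before
spending); per-trial error probability 0.1 (errors repeat the pending step
and never advance progress — accumulated reward is retained); trial timing
with a 1 s pre-fixation epoch, 2 s fixation-to-cue epoch, a saccade latency,
a 1.5 s delay and a 0.5 s outcome epoch, giving the five standard analysis
windows room on every trial. Key-release reaction times follow a linear
model with a negative progress slope and a progress-by-inverse-length
interaction (reaction times adapt to the planned length), plus Gaussian
noise; saccade latencies carry a small positive progress slope. Imperative
control sessions reuse the free-choice sequence lengths so save/spend
statistics match across tasks.

Spike trains are inhomogeneous Poisson processes: a constant baseline over
the whole trial plus `gain * f(trial)` inside each target period, where `f`
encodes one of eight ground-truth tuning models (length-normalized
progress, raw progress, a weighted mixture of the two, accumulated reward
magnitude, elapsed within-sequence time including errors, step-indicator
tuning, a progress-blind within-trial reward-expectation ramp, or nothing).
The modulation is a constant increment across the whole target period — the
simplest form consistent with fixed-window counting — rather than a shaped
kernel. Tuning can be restricted to free choices (`free_only`) and
attenuated on error trials (`error_attenuation`). Two scale conventions
keep default rates physiological: the elapsed-time drive is normalized by
its session maximum, and the reward-expectation ramp is a per-period
position factor; both are monotone transforms that leave the corresponding
regression models' ability to fit them unchanged.

Deliberately *not* emulated: truncated-exponential fixation timing (fixed
mean only), shaped response kernels, cross-neuron noise correlations
(pseudo-populations ignore them by construction), licking and eye signals,
and any anatomical structure beyond a categorical region label. Passing
tests therefore certify the statistical machinery on data satisfying the
generative assumptions, not the biology of any particular recording.

For analyses that only consume the five fixed windows,
`simulate_window_counts()` draws the Poisson window counts directly from the
window-integrated rate — distributionally identical to generating spike
times and counting, and much faster for large rosters; the equivalence of
the two paths is itself under test. Sliding-window analyses always use the
spike-time path.

## Single-neuron statistics

Counting windows are half-open `[start, start + duration)`, anchored to
trial events: pre-fixation (control, 1000 ms before fixation onset),
fixation (1775 ms from +25 ms), cue (300 ms from +20 ms), delay (1500 ms
from +25 ms post-choice) and outcome (500 ms from +50 ms post-reinforcer).
Task-relatedness screening compares each task period against the control
period with a paired two-sided Wilcoxon test at strict p < 0.0083
(Bonferroni-style); the control period itself is never screened, and
neurons with fewer than 20 correct trials are excluded.

The tuning-model suite regresses trial-by-trial rates on: raw progress
(eq2), length-normalized progress (eq3), reward magnitude (eq4), elapsed
time (eq5), step indicators without intercept (eq6), the full multiple
regression with choice, values, length, cue position and action side (eq7),
and partial adaptation with both progress regressors (eq8). All fits are
OLS via a shared QR engine that also reports standardized slopes
$\beta_i s_i / s_y$, two-sided slope t-tests (significance p < 0.05), raw
and adjusted $R^2$, and BIC; the engine is pinned to a normal-equations
oracle at 1e-10 in the tests. Reward magnitude on save trials uses the
accumulated amount at the current step (the prospective spend amount is an
alternative reading; the accumulated value is the one the geometric rule
defines trial by trial).

Stepwise selection of the eq7 regressor set uses p-to-enter 0.05 and
p-to-remove 0.10 — the classical defaults of the tooling era, since the
method is named without thresholds — and a forced simultaneous fit is
available. Perfectly collinear value regressors drop in entry order.

Two model-contest interfaces exist because the candidate set mixes nested
and non-nested models. `compare_models()` reproduces the published style of
pairwise contest between one-regressor models: higher-raw-$R^2$ wins among
responses significant for both models (exact ties count for neither), a
dependent-proportions z on the discordant (significant-for-one-only)
responses, and a one-sample t-test on the $R^2$ differences.
`best_fit_model()` answers "which tuning form generated this response" and
defaults to BIC, because the step-indicator and partial-adaptation models
nest raw progress: raw $R^2$ can never prefer the smaller model, and at
realistic trial counts (hundreds) adjusted $R^2$'s penalty is weak enough
that the nesting model wins on noise in roughly half of truly linear
responses. BIC restores a dominant diagonal in the tuning-recovery
confusion matrix while leaving non-nested contests essentially unchanged.

The sliding-window detector moves a 200 ms window in 25 ms steps across
event-aligned segments (fixation-, cue-, choice- and outcome-aligned) —
stitching segments avoids smearing windows across variable-latency gaps —
and records a per-window OLS p-value (zero-variance windows score p = 1).
Because adjacent windows share 175 ms of data, isolated chance
significances come in runs; the run-length criterion is therefore
calibrated on trial-shuffled data: the regressor is permuted across trials,
the longest significant run per shuffled series is recorded, and the
criterion is the smallest L with fewer than 5% of shuffled series exceeding
it. With the default geometry this calibration lands at L = 8, and a neuron
is flagged only when its observed run strictly exceeds L.

## Population analyses

Population activity is z-normalized per neuron against the control period
(session-wide normalization is available); neurons with zero control
variance are excluded with a message. Sign correction flips responses whose
progress slope is negative so population averages aggregate coherently —
making the population mean slope non-negative by construction, which the
tests assert as an invariant rather than a finding.

`adaptation_by_length()` fits pooled trial-level activity against progress
separately per sequence length (lengths with at least 10 sequences by
default; a per-neuron-then-average variant is provided because the pooling
level is ambiguous in the source analyses) and regresses the slopes on
inverse length: a fully adaptive population with unit gain gives slope(L) =
1/L exactly and $R^2 = 1$. `predict_sequence_length()` regresses the final
length on activity at a fixed step; `consecutive_adaptation()` regresses
slope differences of adjacent same-interest-rate sequences on differences
in inverse length, recovering the population gain under full adaptation.
Spend-trial activity is included in per-length fits (an exclusion option
exists). `error_trial_coding()` compares progress slopes on pre-error,
error and post-error trials with dependent-samples t-tests and reports the
pooled on/pre slope ratio with a delta-method standard error, which is how
a configured attenuation is checked against its estimate.

## Decoding

Pseudo-populations stack z-normalized single-trial rates from one task
period. Progress groups are per-neuron terciles (quantile type 7; boundary
values go to the lower group; quartiles are supported). Neurons need at
least 5 trials in every group; all group matrices share one row count m —
the minimum over neuron-group cells — so chance is exactly 1/n_groups.
Within-group trial matching is random and repeated (150 matchings by
default; the tests and examples use fewer, which stabilizes only the
summary, not any single accuracy). Classifiers are leave-one-out
nearest-neighbor (Euclidean; distance ties resolve to the earliest trial in
a stable row order) and a linear-kernel SVM ("linear max-margin"; nonlinear
kernels are deliberately not offered), with an 80/20 split option.
Accuracy is percent correct, fold-averaged within a matching and then
summarized across matchings. Shuffled-label nulls permute the group labels
without replacement and are compared to real accuracies with a two-sided
rank-sum test; neuron-count curves and fixed-size subset analyses
(significant / random / non-significant rosters, with a covariate
regression of accuracy on mean rectified slope, slope dispersion and
centromedial fraction) reuse the same machinery with small per-draw
matching counts.

## Numerical choices and problem sizes

Seeds: one master integer seed; per-neuron substreams are derived by
hashing the neuron id with the seed, so editing a roster does not perturb
other neurons' spike trains. All stochastic tests fix seeds. Degenerate
inputs are handled explicitly: rank-deficient designs are flagged rather
than fitted, zero-variance windows record p = 1, constant-rate neurons are
excluded from normalization with a message, and empty stepwise models
return an intercept-only row.

The test suite works at sizes chosen to make each statistical claim sharp
but cheap: 300 shuffled null series for the run-length calibration, 200
neurons per tuning class for the recovery confusion matrix, 2000 null
responses for the type-I calibration, 100 neurons at 10% error rate for the
attenuation recovery, and a few dozen neurons for decoding calibrations.
These are the package's own verification scales; the analysis functions
themselves accept arbitrarily larger inputs.

## Limitations

Real recordings violate several generator assumptions — non-Poisson
dispersion, slow drifts, correlated noise, kernel-shaped responses — so
green tests here certify correctness of the statistics, not robustness to
those violations. The elapsed-time and raw-progress regressors are nearly
collinear when errors are rare; distinguishing them needs sessions with a
realistic error rate and enough trials, and the recovery tests quantify
exactly that regime. Published real-data headline numbers (fractions of
significant neurons, absolute decoding accuracies) depend on the recorded
population and are out of scope for reproduction.
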