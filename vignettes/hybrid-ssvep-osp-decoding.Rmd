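---
title: "Hybrid SSVEP + omitted-stimulus-potential decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid SSVEP + omitted-stimulus-potential decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepOSP)
```

## The paradigm

Four discs flicker black/white on a 60 Hz display for 2.5 s per trial:
discs 1/3 at 12 Hz and discs 2/4 at 10 Hz. A steady flicker above ~6 Hz
drives a steady-state visually evoked potential (SSVEP) at the flicker
frequency (and its harmonics) over occipital cortex. Every third flicker
period is *omitted* — held at constant luminance for exactly one period
(1/frequency, the shortest omission that still works) — and each omission
elicits a "fast" omitted-stimulus potential (OSP): a tri-phasic transient
(positive P1, negative N2, and the largest positive P2) at about 160, 210
and 290 ms after the omission onset. Discs sharing a frequency differ only
in *when* their omissions occur: the first omissions fall at 467, 450, 633
and 650 ms (frame-aligned), i.e. the paired discs are offset by exactly two
flicker periods. A fixated disc is therefore identified in two stages:

1. **Frequency stage** — which frequency pair? Canonical correlation
   analysis (CCA) between the EEG segment and sinusoidal references.
2. **Time stage** — which disc of the pair? Omission-onset-locked epochs
   are averaged and classified by a windowed linear-SVM bank fused with a
   naive-Bayes likelihood ratio.

With N = 4 targets, accuracy Acc and a decision transfer interval DTI
(seconds per command), performance is summarized by the information
transfer rate

$$\mathrm{ITR} = \frac{60}{DTI}\Big[\log_2 N + Acc\,\log_2 Acc +
  (1-Acc)\log_2\frac{1-Acc}{N-1}\Big] \;\mathrm{bits/min}.$$

## Frame scheduling

The display quantizes everything to 1/60 s frames. Frames per flicker
period are `round(refresh/frequency)`; on odd counts the white (visible)
phase receives the extra frame, so 12 Hz renders as 3 white + 2 black
frames and 10 Hz as 3 + 3. A requested frequency is rejected when the
nearest frame-aligned rate differs by more than 5 %. The flicker phase is
anchored so that the first omission starts exactly on a period boundary;
omissions recur every `intervalFlickers` periods and only complete
omissions are scheduled. Two pattern variants exist: `missing_white` holds
the omitted period black (the disc disappears against the black
background) and `missing_black` holds it white (the disc pauses). Onsets
are stored in seconds, frame-aligned, 0-based from stimulation start; all
time windows in the package are half-open `[start, end)`.

The frequency-to-disc assignment (12 Hz on discs 1/3, 10 Hz on 2/4) is a
design choice: the published onset lags between paired discs — 166.7 ms
(discs 1→3) and 200 ms (discs 2→4) — equal two periods of 12 and 10 Hz
respectively only under this assignment. Whether the one-frame stagger
between 467 and 450 ms is deliberate is unknown; the scheduler simply
reproduces it.

## The forward model

`simulateTrial()` generates microvolt-scale EEG as

$$x_{ch}(t) = g_{ch}\sum_{d=1}^{4} a_d\,[\,\mathrm{SSVEP}_d(t) +
  \mathrm{OSP}_d(t)\,] + \varepsilon_{ch}(t),$$

with $a_d = 1$ for the fixated disc and `nonattendedGain` (default 0.1)
otherwise — peripheral, non-fixated flickers drive only weak responses.
$\mathrm{SSVEP}_d$ is a harmonically weighted sinusoid at the disc's
flicker rate (fundamental weight 1, second harmonic 0.4 — second-harmonic
SSVEP responses are well documented, exact ratios are not), amplitude 4 µV,
gated off during the disc's own omissions. $\mathrm{OSP}_d$ places a
template at each omission onset: three Gaussian-windowed deflections of
+1.0, −1.5 and +2.0 µV (widths 20/25/30 ms) at 160/210/290 ms, P2 largest.
Under `missing_white` the template is scaled by 1.25, reflecting the larger
deflection after a bright-phase omission. No absolute amplitudes for these
components are published; these defaults produce realistic signal-to-noise
ratios and are treated as free parameters of the simulator.

The channel topography $g_{ch}$ is 1.0 on O1, Oz, O2, POz, PO4 and PO8 —
the six electrodes where the occipital response is strongest and which all
decoding uses — and 0.3 on PO3, PO7, Pz and Cz. Noise is 1/f ("pink",
spectrally shaped Gaussian noise, default SD 2 µV per channel; a white
option exists for calibration tests) plus 50 Hz line interference (1 µV)
which is then removed by a zero-phase 48–52 Hz notch, emulating the
acquisition chain of a biosignal amplifier. Every trial is reproducible
from an integer seed; sessions derive per-trial seeds deterministically
from a master seed.

Session structure follows the reference protocols: training = 4 fixation
tasks × 7 runs × 16 trials (448 trials, 112 per disc, labels in task
order), online = 10 runs × 16 trials with balanced randomized labels.
Trial timing is dark 2 s, cue 0.5 s, stimulation 2.5 s, inter-trial 0.5 s;
the simulator renders the stimulation window plus the 0.5 s dark tail (so
late omission epochs stay inside the recording) and does not synthesize
the uninformative dark/cue periods.

What the simulator deliberately omits: volume conduction and realistic
head geometry, eye-blink/EMG artifacts, inter-subject variability, latency
jitter of the evoked components, and any attention modulation. Passing
tests therefore demonstrate that the *decoding pipeline* is correct and
self-consistent under the stated signal model — not that human online
accuracies are reproducible; the published per-subject results ship as
data (`publishedResults()`) and only their ITR arithmetic is recomputed.

## Preprocessing

A 4th-order Butterworth band-pass (1–45 Hz) is applied forward-backward
(`filtfilt`), giving zero phase shift — any causal filter would bias the
160/210/290 ms latencies the classifier feeds on. The filter family and
order are not published; zero-phase IIR is the standard ERP choice.
Onset-to-sample mapping rounds to the nearest sample with ties toward
−∞. Epochs are cut on half-open windows; onsets whose window leaves the
recording are skipped with a warning. Averaging n onset-locked epochs
leaves the time-locked response untouched and shrinks additive zero-mean
noise by √n.

## Frequency identification

The first canonical correlation between the 6-electrode segment and a
reference set of sin/cos pairs at the fundamental and second harmonic is
computed per candidate frequency (10, 12 Hz); the argmax wins, ties going
to the lower frequency. The implementation centers both matrices, takes
thin-QR orthonormal bases and the largest singular value of
$Q_x^\top Q_y$; rank-deficient segments (e.g. noise-free simulations where
all channels are scaled copies) are truncated to numerical rank, which is
the regularized solve. The analysis uses the full 2.5 s stimulation window
and the same six electrodes as the time stage; whether the original system
used 6 or all 10 electrodes is unstated, and using one montage for both
stages keeps the hardware requirement minimal. Tests verify the solver
against a direct covariance-eigen oracle and `stats::cancor` at 1e-8.

## Omission-onset recognition

Ten contiguous 25 ms windows span [125, 375) ms after an omission onset —
the interval where the fast OSP lives. At 1200 Hz each window holds 30
samples, so each electrode contributes a 10 × 30 feature vector per
averaged epoch; electrodes are treated as independent samples, so a full
448-trial training session yields 6 × 448 = 2688 target-aligned samples.
The negative class is built from the same trials epoched at the *partner*
disc's onsets (the disc sharing the flicker frequency), which is exactly
the alternative hypothesis the online decision faces.

Window k feeds a linear SVM; the penalty C is chosen per window from a
logarithmic grid by seeded 10-fold cross-validation (ties to the smaller
C). The default grid spans 10^−3 to 10^1: on these noisy, non-separable
features the cross-validated optimum consistently sits at small penalties,
and quadratic-programming solvers converge poorly at extreme C without any
accuracy gain; a wider grid can be passed explicitly. Trained weights are
extracted from the support-vector expansion into a plain weight vector and
bias (decision d = 1 iff w·x + b > 0; exact zero maps to 0), which makes
the bundle JSON-serializable and decisions exactly reproducible.

The ten binary decisions are fused by a naive-Bayes likelihood ratio

$$P = \prod_{k=1}^{10} p_{k01}^{(1-d_k)}\,p_{k11}^{d_k} \Big/
      \prod_{k=1}^{10} p_{k00}^{(1-d_k)}\,p_{k10}^{d_k},$$

where $p_{kmn} = P(d_k = m \mid c = n)$ is estimated from training
decisions with Laplace (+1/+2) smoothing — raw frequencies can be exactly
zero, which would make the ratio degenerate. $P$ is computed in log space.
At test time each candidate onset set is epoched, averaged, and scored;
per-electrode log-ratios are summed (electrodes as independent evidence,
mirroring their role in training — the reference system does not state its
test-time pooling) and the candidate with the largest summed log-score is
the decision.

Averaging counts of 2, 4, 6 and 8 are swept with DTI map
{2 → 2.5 s, 4 → 3.0 s, 6 → 3.5 s, 8 → 4.0 s}. The 3.0/3.5 values
regenerate every published per-subject ITR from its accuracy exactly
(verified by closed-form inversion), although the narrative elsewhere
implies 2–2.5 s per command; the table is taken as authoritative and the
other two values extend its +0.5 s per +2 averages pattern. Within one
2.5 s trial a 10 Hz disc offers at most 7 omissions (a 12 Hz disc 8), so at
`nAvg = 8` the decision layer truncates to the epochs available, applied
symmetrically across candidates; spilling epochs across trial boundaries
would mix non-contiguous stimulation and is not done. `averageEpochs()`
itself keeps the strict contract and errors on a shortfall.

## Numerical and degenerate-input choices

* Flicker specs whose frame-aligned rate deviates > 5 % are rejected; the
  white phase gets the extra frame on odd frame counts.
* CCA clips correlations to [0, 1] and truncates rank with a 1e-10 QR
  tolerance, with a message on rank deficiency.
* SVM decision value exactly 0 → class 0; CV ties → smaller C; sweep
  ties → smaller averaging count; frequency ties → lower frequency.
* `itr()` defines 0·log₂0 = 0; it is 0 at chance and positive elsewhere.
* EDF interchange quantizes to 16 bits over ±200 µV (≈ 0.006 µV per
  digit); events travel in a CSV sidecar because EDF annotation dialects
  vary.

## Problem sizes used in tests and the acceptance script

The bundled checks run on deliberately compact instances chosen to keep
the full pipeline exercised: the feature-bookkeeping check simulates the
complete 448-trial training session; decoder-property checks train on
64-trial sessions (2 runs of 8 trials per task) and decode 64-trial online
blocks per noise level at 0, 15 and 40 µV; oracle comparisons use all 1024
fusion vectors and repeated random CCA instances. Accuracies quoted by the
acceptance script are Monte-Carlo estimates under fixed seeds at exactly
these sizes.

## Known limitations

* Synthetic EEG only; no claim that human accuracies are reproduced.
* The forward model's component amplitudes are plausible but free
  parameters; published figures show them only graphically.
* The decoder assumes the stimulus schedule (onset times) is known
  exactly — true for a screen-locked BCI, but rendering jitter is not
  modeled.
* Electrode pooling at test time and the 6-vs-10-electrode CCA montage are
  design decisions where the reference system is silent.
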