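---
title: "Preictal-state discrimination from slow-wave/gamma phase-amplitude coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preictal-state discrimination from slow-wave/gamma phase-amplitude coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcpredict)
```

## The scientific problem

A third of people with focal epilepsy have seizures that resist medication.
If the minutes-to-hours before a seizure (the *preictal* state) are
physiologically distinct from the seizure-free (*interictal*) state, a
warning system watching the intracranial EEG could anticipate seizures.
`cfcpredict` implements one candidate index of that transition: the spatial
reorganization of *phase-amplitude cross-frequency coupling* across an
ensemble of intracranial contacts, evaluated with a strict prospective
train/test protocol and validated against an analytically defined chance
level.

The physiological observation behind the index is that bursts of gamma
activity (40–140 Hz) "nest" at a preferred phase of slow cortical rhythms
(delta 0.5–3 Hz or theta 3–8 Hz). In long recordings most contacts sit at a
stable preferred phase for hours; tens of minutes before some seizures, the
preferred phase of many contacts drifts to a different value. The pipeline
turns that drift into an alarm series.

## The measurement chain

**Mean coupling phase per contact and minute.** Each channel is band-pass
filtered in a slow band and a gamma band with an 8th-order Butterworth
filter applied forward and backward (zero phase, squared magnitude
response), realized in second-order sections because the expanded
transfer-function polynomial is numerically singular at a 0.5–3 Hz band on
a 256 Hz record. Instantaneous slow-band phase and gamma-band envelope come
from the Hilbert analytic signal (phase 0 at the positive peak of the slow
wave). In consecutive non-overlapping 1-minute windows the gamma envelope
is averaged in 40 equal phase bins over $(-\pi, \pi]$, and the resulting
unimodal distribution is summarized by the mean of a Von Mises fit — the
amplitude-weighted circular mean

$$\varphi_c = \arg \sum_i \langle A \rangle_i \, e^{i\varphi_i},$$

with the resultant length (in $[0,1]$) kept as a concentration index. No
statistical threshold is applied to individual windows; windows whose
histogram carries no amplitude are flagged undefined instead. Empty bins
are excluded from the mean rather than zero-filled.

**Ensemble occupancy, smoothing, alarms.** The circle is divided into 11
equal intervals of width $2\pi/11$, anchored at $-\pi$ and half-open so the
grid partitions the circle exactly. For one interval, the *occupancy* of a
window is the fraction of contacts whose $\varphi_c$ lies inside it
(undefined contacts leave both numerator and denominator). The occupancy
series is smoothed by a causal first-order random-walk Kalman filter and an
alarm fires when the smoothed proportion crosses a threshold, after which
alarms are suppressed for a refractory period equal to the assumed preictal
duration.

**Prospective evaluation.** The first `n_train` seizures (default 4, with a
10-hour floor) define the training span, on which an exhaustive grid —
4 band pairs × 11 intervals × preictal durations {10, 30, 60} min ×
thresholds 5–50 % in 1 % steps — is scored by sensitivity (SS, fraction of
seizures with an alarm in the preceding preictal window) and false
prediction rate (FPR, false alarms per hour of time in which a false alarm
could occur: the span minus preictal windows and time already under false
warning). The selected configuration minimizes the distance to the ideal
$d = \sqrt{(1-SS)^2 + (FPR/FPR_{ref})^2}$ and is then frozen and applied
once to the test span.

**Chance level.** A random predictor raising alarms as a Poisson process at
the observed FPR predicts a single seizure with probability
$P = 1 - e^{-FPR \cdot SOP}$; the number it predicts out of $K$ is
binomial, and the critical sensitivity $\sigma_{rand}$ is the smallest
$k/K$ whose upper-tail probability is below $\alpha = 0.01$. A patient
whose test sensitivity exceeds $\sigma_{rand}$ at matched FPR and preictal
duration beats chance; across $N$ patients the count of such individually
significant patients is itself binomial under the null, giving the
group-level probability computed by `group_significance()`.

**Band-power baseline.** To check that coupling carries information beyond
band power, the same alarm machinery is driven by the channel-averaged
relative power of delta (0.1–4 Hz), theta (4–8 Hz) or gamma (30–140 Hz),
from Burg autoregressive spectra (order 16) on 5-second windows, normalized
by the power over the whole analyzed range (0.1 Hz to 140 Hz, capped at
90 % of Nyquist). The baseline thresholds the raw series directly; the
smoothing step is specific to the occupancy pipeline. When the two
detectors are contrasted, the comparison is made *at matched FPR*: the
band-power detector is given every threshold in the quantile range of its
series (including a silent, zero-alarm setting) and reports the best
sensitivity it can achieve without exceeding the coupling detector's
false-prediction-rate budget. This is deliberately generous to the
baseline — it may pick its threshold in hindsight — so a sensitivity gap in
favor of coupling cannot be an artifact of threshold selection.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| window length | 60 | s | coupling-phase estimation window |
| phase bins | 40 | – | amplitude-over-phase histogram |
| phase intervals | 11 | – | occupancy grid, width $2\pi/11$ |
| Kalman `q`, `r` | 1e-4, 1e-2 | – | process/observation variance |
| thresholds | 0.05–0.50 | proportion | occupancy alarm grid |
| preictal durations | 10, 30, 60 | min | alarm horizon = refractory |
| `n_train` seizures | 4 (2–4 accepted) | – | training-span rule |
| minimum training | 10 | h | training-span floor |
| $\alpha$ per patient | 0.01 | – | random-predictor level |
| AR order | 16 | – | Burg spectra on 5-s windows |
| $FPR_{ref}$ | 1 | /h | distance normalization |

The Kalman variances are a design choice: the ratio $q/r = 10^{-2}$ gives a
steady-state gain near 0.1, i.e. an effective memory of a few tens of
minutes, which matches the smoothness the occupancy trace needs for the
threshold rule to respond to sustained shifts rather than single-window
noise. The source description of the procedure fixes neither value, so both
are exposed as arguments. Likewise the closest-to-ideal distance and the
Poisson single-alarm probability are the standard closed forms for their
stated roles, with $FPR_{ref}$ configurable.

Two theta conventions coexist deliberately: the coupling analysis defines
theta as 3–8 Hz while the band-power baseline uses 4–8 Hz; each module uses
the band stated for it.

## Numerical choices

* **Filtering.** Second-order sections from a zero-pole-gain Butterworth
  design with bilinear pre-warping; forward-backward application with odd
  edge extension. The squared-magnitude response is checked in the tests
  against the closed-form prototype magnitude $1/\sqrt{1 + \Omega^{16}}$.
* **Long records.** Filtering and the analytic signal commute into a single
  frequency-domain multiplication by $2\,|H(\omega)|^2$ on the positive
  frequencies. On multi-hour records the package applies that multiplier on
  overlapping chunks (64 s, one-eighth overlap each side, odd reflection at
  the record edges) and inverse-transforms only the occupied band onto a
  decimated grid — exact sample picking for a band-limited analytic signal.
  The decimated rate always exceeds the widest band by 25 %, and skirts
  below $10^{-8}$ of the peak squared response are dropped. The tests
  verify that this fast path agrees with the plain whole-record path to
  well under the pipeline's 0.15 rad recovery tolerance (typically
  0.006 rad). The first and last 5 s of a record are excluded from
  histogramming to avoid edge transients.
* **Circular conventions.** Phases live in $(-\pi, \pi]$; histogram bins
  and occupancy intervals are half-open $[lo, hi)$ with the last interval
  closed at $\pi$; phases are binned by direct arithmetic on
  $(\varphi + \pi)\,/\,$binwidth.
* **Degenerate cases.** Constant-zero signals have amplitude 0 and
  undefined phase; all-empty histograms are an error; occupancy windows
  with no defined contact are missing and skip the Kalman update
  (prediction propagates, variance inflates); grid configurations whose
  warnings blanket an entire span have no time left for false alarms and
  are ranked last rather than raising an error mid-search.
* **Ties.** Equal optimization distances break by lower FPR, then higher
  SS, then enumeration order (pair, interval, preictal duration,
  threshold) — fully deterministic.
* **PSD integration.** AR spectra are evaluated on a 1025-point grid
  (0.125 Hz at 256 Hz); a coarser grid visibly mis-integrates sharp
  low-frequency AR peaks against the 0.1–4 Hz delta band.
* **EDF.** 16-bit samples with symmetric per-channel physical scaling over
  the symmetric digital range ±32767 so that 0 µV is exactly
  representable; 1-second records; a CSV sidecar (`onset_s,label`) carries
  seizure annotations, all timestamps in seconds from record start.

## What the synthetic generator emulates — and what it does not

`generate_patient()` builds: a narrowband stochastic slow oscillation
(filtered white noise, so its instantaneous phase is nondegenerate), shared
coherently by all contacts as slow cortical waves are; per-contact
independent gamma carriers (filtered noise) whose envelope is
$1 + m\cos(\varphi_{slow} - \varphi_c)$, floored at 0; and white
measurement noise. Interictally every contact couples at its assigned
phase; during the preictal window before each annotated onset a fixed,
randomly chosen fraction of contacts couples at the preictal phase instead.

The reference patient used throughout the tests is 16 contacts at 256 Hz
for 12 h with 6 seizures (onsets at 2.0, 3.7, 5.4, 7.1, 9.1 and 10.9 h,
all spaced > 1.5 h), interictal phase 0.81 rad, preictal phase 0.24 rad,
60 % of channels shifting, modulation depth 0.8, slow/gamma/noise
amplitudes 50/10/5 µV. Twelve hours is the smallest duration that
accommodates the 10-hour training floor plus a test span containing a
seizure with its full preictal hour; 256 Hz is the lowest clinically used
rate and exercises the reduced 70–120 Hz high-gamma band. The
ground-truth manifest records every planted parameter including the
shifted-channel set.

What passing tests on this generator show: the estimator chain recovers
planted coupling phases to < 0.15 rad; the grid search recovers the planted
band pair, phase interval and preictal duration; scoring matches a
brute-force oracle; and a phase shift with flat band powers is visible to
the coupling detector but not to the spectral baseline. What they cannot
show: performance on real iEEG, which has nonstationary sleep/wake power
modulation, artifacts, ictal morphology, heterogeneous per-contact coupling
and drifting baselines. The per-patient performances in the packaged cohort
table are reporting data, not something the synthetic pipeline reproduces.

A boundary note on that table: its ten regularly spaced preictal phase
centers (−2.62 … 2.52) differ by the grid spacing 0.571 rad, but the value
2.86 rad listed for two patients is not on that lattice, and the lattice
itself is offset from a grid anchored at $-\pi$ (whose centers are
−2.856 … 2.856). The package uses the uniform 11-interval grid anchored at
$-\pi$ and keeps the table values verbatim as published data.

## Problem sizes used by the tests and acceptance script

The test suite runs the full prospective pipeline on ten seeded reference
patients (12 h × 16 channels each) for the parameter-recovery study,
shares those runs across test files through a memoised helper, and uses
minutes-long recordings everywhere else. The acceptance script re-derives
the cohort aggregates from the packaged table, re-runs phase recovery on
ten 5-minute recordings, re-runs the end-to-end recovery on five 12-h
patients, and computes the coupling-versus-power contrast on the first of
them. These sizes were chosen so one complete run stays in the tens of
minutes on a single CPU while keeping every estimate comfortably away from
its acceptance margin.

## Known limitations

* The refractory rule for the band-power baseline is applied identically to
  the coupling detector for comparability; with no smoothing its alarms are
  more volatile.
* With two or fewer test seizures the random predictor demands
  $\sigma_{rand} = 1$ at $\alpha = 0.01$ unless the FPR is 0, so
  single-test-seizure patients effectively cannot reach individual
  significance — a property of the statistic, not a bug.
* The generator does not model ictal waveforms, sleep cycles, artifacts or
  inter-contact heterogeneity of coupling strength.
* EDF support covers the single-rate, 16-bit core of the format (what the
  pipeline needs), not the full EDF+ annotation stream; annotations travel
  in the CSV sidecar.
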