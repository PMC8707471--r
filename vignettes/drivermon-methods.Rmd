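---
title: "Models and methods behind drivermon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind drivermon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivermon)
```

`drivermon` implements an in-cabin, non-contact driver monitoring chain:
synthetic physiological signal generation, signal conditioning, spectral
analysis, vital-sign estimation, thermal surveillance, alert fusion and
an e-Call payload. This vignette explains each model, its assumptions,
the tunable parameters and why their defaults are what they are, and
what the synthetic benchmarks do and do not demonstrate.

## Why synthetic data is a first-class module

Capacitive ECG/EEG recordings of drivers are clinical-grade personal
data and no public corpus matches this sensor geometry. The package
therefore treats the generator as part of the product, not as a test
fixture: every generator writes its ground truth into the object it
returns (heart rate, saturation, state label, regime), and every
downstream estimator is judged by parameter recovery against that truth.
Two properties make this meaningful rather than circular:

* estimators are checked against *independent oracles* in the test
  suite (direct-summation spectral reference, FFT-masked band variance,
  brute-force inner products, closed-form slopes), never against the
  code paths they exercise; and
* the oximetry generator inverts whatever calibration table is
  configured, so its round-trip holds for user tables too — it tests the
  pipeline's algebra, not a particular calibration.

What passing these benchmarks does **not** show: robustness to motion
artifacts, electrode repositioning, perspiration-dependent coupling,
inter-subject morphology variation, or pathological rhythms. The
generators emulate textbook morphologies under stationary conditions
with seeded stochasticity; claims about real cabins require real
recordings.

## The capacitive coupling channel

Non-contact acquisition couples the body to the electrode through
clothing layers. Each insulating layer is modelled as a series LC
impedance $Z_i = j\omega L_i + 1/(j\omega C_i)$, summed to
$Z_\mathrm{tot}(\omega)$ and placed in a voltage divider against the
amplifier input impedance $Z_\mathrm{in}$ (default 100 MΩ, a typical
high-impedance front end):
$H(\omega) = Z_\mathrm{in} / (Z_\mathrm{in} + Z_\mathrm{tot}(\omega))$.
The divider is applied in the frequency domain with conjugate gains on
negative-frequency bins, so the output is exactly real and the operator
is linear; a channel with no layers and no noise is the identity by
construction. No tabulated $L_i/C_i$ values exist for real clothing, so
the default single 10 nF layer is illustrative — the point of the model
is its high-pass character (capacitive layers block DC) and the
hum/spike environment, not layer-accurate electromagnetics. Vehicle
noise is 50 Hz mains hum plus Poisson-timed biphasic voltage spikes
(ignition/inductive transients), both seeded.

## Signal generators

**ECG.** One Gaussian bump per wave per beat (P, Q, R, S, T) with
per-class amplitude multipliers for normal, hypotensive and hypertensive
morphologies. The classes are deliberately stylized (globally low
voltages for hypotension; tall R, deep S, inverted T for hypertensive
strain) — they are distinct templates for exercising classification and
detection, with no claim of clinical fidelity. Beat times carry seeded
RR jitter (default 2 % fractional SD; 25 % is used in tests to provoke
the arrhythmia flag).

**EEG.** A state is a mixture of a narrow-band alpha component
(8–12 Hz), a narrow-band beta component (14–25 Hz) and white broadband
noise. Each narrow-band component is a carrier at the band centre with
slow frequency wander confined to the band and a waxing/waning envelope
at a spindle-like 0.35 Hz. The envelope rate matters: an 8-second
analysis epoch then averages several envelope cycles, so per-epoch band
power is stable and the alpha/beta ratio of a stationary state does not
swing across epochs (an earlier, slower envelope made eyes-open epochs
flicker past the drowsiness threshold). Default amplitudes per state
(alpha, beta, noise, µV): eyes_open (15, 25, 5), eyes_closed_relaxed
(40, 10, 5), drowsy (60, 8, 5), stress (8, 45, 5), emotion (22, 35, 5),
distraction (10, 12, 25). Relaxed/drowsy states are alpha-dominant and
all active states beta-dominant — every state has a definite,
documented ordering so the label-consistency property is well-defined;
alpha amplitudes are constrained to the physiological 5–150 µV range.

**PPG.** Each channel is a DC level with a sinusoidal pulsatile
component. The infrared modulation depth is fixed at 4 % and the red
depth solved from the log ratio-of-ratios formula against the
configured calibration table, so the generated pair encodes its own
saturation. A pure sinusoid is used deliberately: the AC extractor
measures beat-wise peak-to-trough amplitude, and a harmonic-rich pulse
shape would change the peak-to-trough/DC relation and break the exact
inversion.

**Thermal.** 8×8 frames at 10 Hz (the array's native rate): ambient is
a constant baseline plus i.i.d. Gaussian pixel noise (default
σ = 0.3 °C; the data sheet gives no noise figure, this is the order of
magnitude of consumer thermopiles); warming ramps a 2×2 sub-region at
0.08 °C/s (a closed cabin on a hot day reaches the 40 °C critical level
within minutes); flame adds a flickering hot core at 200–350 °C that
appears a third of the way into the sequence.

## Conditioning

The interference chain is: 50 Hz notch (second-order IIR, Q = 30 — the
narrowest width that still removes hum after forward–backward
application), optional centred moving average (default 5 samples), and
a Butterworth band-pass to the 0.5–35 Hz band of interest (order 4;
the lower edge is 0.5 Hz rather than 0 because a true DC-inclusive
band-pass is a low-pass, which `apply_filter` selects automatically in
that case). All IIR filters run forward–backward, so the net response
has zero phase and R-peak latencies are preserved.

Wavelet denoising uses the stationary (undecimated) Haar transform at 3
levels with soft thresholding. Numerical choices:

* **Boundary handling is periodic.** The stationary transform with
  circular convolution is *exactly* equivariant to circular shifts,
  which is the property that makes SWT preferable to the decimated
  transform for denoising; reflection padding would hold it only
  approximately. Signals whose length is not a multiple of $2^J$ are
  extended by symmetric reflection to the next multiple and cut back
  after reconstruction.
* **Thresholds.** Hand-tuned per-level thresholds are supported
  (`threshold_rule = "fixed"`), but the default is the universal
  threshold $\hat\sigma\sqrt{2\ln N}$ with $\hat\sigma$ the
  median-absolute-deviation of the finest-level details divided by
  0.6745 — a principled default that needs no tuning and is what the
  denoising benchmark uses.
* At zero threshold the analysis–synthesis round-trip is the identity
  to floating-point accuracy, which the suite asserts at 1e-8.

The decimated `dwt_coeffs` is kept alongside the SWT because its
coefficients are exact inner products with the orthonormal Haar family
(`haar_basis`), giving Parseval energy preservation and a brute-force
cross-check of the filter-bank implementation.

## Welch spectral estimation

The estimator is written out explicitly rather than delegated, because
its definition is the package's reference for everything spectral:
segments $x_i[n] = x[n + iD]$, $i = 0..K-1$,
$K = \lfloor (N-M)/D \rfloor + 1$; taper $w$; modified periodograms
$|\mathrm{DFT}(x_i w)|^2 / (M U)$ with $U = \frac1M\sum w^2[n]$; their
arithmetic mean, scaled to a one-sided density (divide by $f_s$, double
all bins except DC and Nyquist). Conventions the package fixes where
the definition is silent: the taper is a periodic Hann window by
default (rectangular reproduces the plain periodogram exactly), the
default segment is 8 s with 50 % overlap ($D = M/2$), and the density
normalization is chosen so the trapezoidal integral over $[0, f_s/2]$
recovers the signal variance — the property the white-noise benchmark
checks within 10 %. A literal direct-summation transcription of the
same definition lives in the test helpers and must agree to 1e-10.

Drowsiness scoring is the alpha/beta band-power ratio of an 8-s epoch
against a personal baseline ratio. The threshold multiplier (default
1.5) and the 2-epoch persistence are engineering defaults: the
underlying physiology gives only the direction (alpha up, beta down
with relaxation), not a universal cut-off, which is why the score is
always relative to the driver's own calibration epoch. The monitor
averages the baseline over the first three epochs; single-epoch
baselines proved noticeably noisier.

## Heart rate and oximetry

R-peak detection follows the derivative–square–integrate recipe:
band-pass 5–15 Hz, differentiate, square, 150 ms moving integration,
local maxima at least 250 ms apart (physiological refractoriness),
then an adaptive acceptance threshold that tracks running signal and
noise levels (accept above noise + ¼ of the signal–noise gap, with
1/8-weight exponential updates). The earlier design — half the running
median of all candidate heights — failed on clean ECG, where P/T-wave
residues outnumber QRS complexes and drag the median down; level
tracking is the standard cure. Detections are refined to the largest
band-passed excursion within ±50 ms, which makes the detector exactly
invariant to positive amplitude scaling. The arrhythmia flag is an RR
coefficient of variation above 0.15 over the evaluation window.

SpO₂ uses the log form of the ratio of ratios,
$R = \log(I_{AC,R}/I_{DC,R}) / \log(I_{AC,IR}/I_{DC,IR})$, implemented
exactly in this form. Note this differs from the more common plain
$(AC/DC)/(AC/DC)$ ratio; for small modulation depths the two are
related monotonically, and since the calibration table is defined
*over this R*, the choice is internally consistent. The default table
is the textbook linear approximation SpO₂ = 110 − 25R sampled at 2.5 %
knots — real devices burn an empirically fitted table into firmware,
which users can supply as CSV (`R,spo2`); all round-trip guarantees are
table-independent because the generator inverts whatever table is in
use. A lost pulse (zero AC) yields an indeterminate flag, never an
exception: clinically, "no reading" and "wrong reading" must be
distinguishable. Window-level estimates are median-smoothed over 3
windows before alerting. Normal-band bounds (95–100 %) are treated as
inclusive.

## Thermal classification

Labels follow the precedence flame > overheat > warming > ambient:
flame on a frame-to-frame pixel increase ≥ 15 °C or an absolute pixel
temperature ≥ 80 °C; overheat at ≥ 40 °C; warming when a pixel's
least-squares slope reaches 0.04 °C/s *and* exceeds four standard
errors of the fitted slope. The significance guard exists because a
plain slope threshold fires spuriously on short windows: with
σ = 0.3 °C pixel noise and a 20-frame window, the maximum of 64 noisy
slope estimates routinely exceeds 0.04 °C/s. The monotonicity guarantee
is stated for *heating a pixel* — adding a positive offset to a pixel's
whole trajectory never downgrades the label, since offsets leave jumps
and slopes unchanged while raising temperatures. (Raising a pixel in a
single frame is not monotone for any jump-based detector: it can erase
the very transition that triggered the flame rule. No differential
detector can satisfy that stronger form.)

## The five-phase alert machine

Phases: 1 training, 2 normal (green), 3 one metric outside its normal
band sustained (yellow), 4 at least two metrics in maximal bands
sustained (red), 5 collision (sticky, overrides everything). Default
bands: pulse normal 70–90 bpm with maximal bands 40–60 and 100–120
(and beyond); SpO₂ normal 95–100 %, yellow 90–94 %, red below 90 %;
drowsiness, arrhythmia and thermal overheat/flame each count as one
maximal-band metric. Design decisions:

* The heart-rate bands overlap (yellow "over 100" vs maximal
  "100–120"). The resolution follows the two-metric rule: inside
  100–120 a rate is classified maximal, but a *solo* maximal metric
  still yields only phase 3 — escalation to red requires a second
  violated metric. A lone pulse of 110 is therefore a yellow alert.
* "Sustained" means continuously violated for `persistence_s`
  (default 10 s — the scheme requires persistence "over a declared
  period" without quantifying it). A violation shorter than the window
  can never escalate beyond phase 2.
* De-escalation is hysteretic: a phase drops only after its trigger
  has been absent for the same persistence window, preventing
  oscillating alarms at band edges.
* Calibration (phase 1) learns each continuous metric's normal band as
  mean ± 3 SD from the baseline stream, clipped to the default bands'
  outer yellow limits, and falls back to the defaults with a warning
  when the baseline is too short.
* Phase-3 acknowledgement suppresses rather than resets alerts (the
  evaluation is a pure function of the history, so suppression is the
  only mode consistent with replay equivalence; a reset would make the
  decision depend on interaction state).

Evaluation is a pure function of (history, config): the per-snapshot
fold is exposed as the decision attribute, so streaming and batch
evaluation coincide by construction. The pre-impact ring buffer retains
snapshots within 30 s of the newest, boundary inclusive (a 1 Hz stream
keeps 31 snapshots). The e-Call payload carries vehicle identity,
occupant count, the buffered snapshots in time order, dynamics
placeholders (explicit nulls when the vehicle bus feed is absent),
position and the collision timestamp, under a versioned schema.

## The cognitive-state classifier

The pipeline is: per-epoch standardization (removing the gain and
offset artifacts of capacitive coupling), a fixed band-power feature
map (alpha power, beta power, their log-ratio, spectral entropy up to
45 Hz), z-scoring by training statistics, `K` prototype centres by
seeded k-means (default 12 for 4 classes), Gaussian RBF activations
$\exp(-\gamma\|x - c\|^2)$ with $\gamma$ defaulting to the inverse of
twice the median pairwise squared distance, and a single-hidden-layer
softmax MLP head (8 units, weight decay 1e-3, 300 iterations). An
optional exponential smoothing of scores across consecutive epochs
stabilizes state sequences the way a recurrent read-out would; it is
off by default so single-epoch behaviour is transparent. Training rows
are put into a canonical order before fitting, so the result is
invariant to how the training set was assembled, and all randomness is
governed by one seed.

The 4-class benchmark (relaxation / stress / emotion / distraction,
distinct alpha-beta-noise signatures with 15 % log-normal amplitude
jitter, 50 epochs per class, 35/15 split) must reach 90 % held-out
accuracy. This is a self-imposed floor demonstrating that the pipeline
learns the intended structure on data whose generating process is
known; it says nothing about accuracy on real EEG, where class
signatures overlap far more.

## Problem sizes and reproducibility

The test suite and the reference script run at desk scale by design:
60 s ECG records at 500 Hz for rate recovery, 8 s EEG epochs at 250 Hz
for spectral work (1 kHz for the headline alpha-bound check), 10 s PPG
windows at 250 Hz, 5–30 s thermal sequences at 10 Hz, and 240 epochs
for the classifier benchmark. These sizes were chosen as the smallest
at which each statistical claim is stable across seeds; everything
regenerates in seconds. Every stochastic element — generators, channel
noise, k-means, the MLP — draws from an explicit seed, and seeded runs
are bit-reproducible, including byte-identical event logs from repeated
monitor runs.

## Known limitations

* The channel model is a lumped LC divider; it ignores motion-induced
  capacitance changes, electrode saturation and ESD events, which
  dominate real capacitive recordings.
* The ECG classes are morphology templates, not hemodynamics; no
  blood-pressure estimation is attempted or implied.
* The drowsiness score relies on a single occipital-style channel and
  a personal baseline; it has no notion of eye closure, blink rate or
  behavioural ground truth.
* The calibration table defaults are a linear approximation; accuracy
  of absolute SpO₂ values depends entirely on supplying a real device
  table.
* Occupant counting and presence detection are configuration inputs,
  not measurements; the thermal grid's person-detection potential is
  reduced to region statistics.
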