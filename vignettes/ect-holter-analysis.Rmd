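---
title: "Night-window ECG and HRV analysis for electrochemotherapy safety"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Night-window ECG and HRV analysis for electrochemotherapy safety}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecthrv)
```

## The problem

Electrochemotherapy of liver metastases delivers trains of 100 µs
high-voltage electroporation pulses through needle electrodes in tissue that
is electrically well coupled to the heart. Even with R-wave-synchronized
delivery, the question remains whether the procedure perturbs cardiac rhythm,
repolarization or autonomic heart-rate control in the hours that follow.
`ecthrv` implements the analysis chain that addresses this from paired
~24-hour Holter recordings — one night before and one night after treatment —
by comparing, per patient, beat-level abnormality and ST statistics, the
rate-corrected peak-to-peak QT interval, and thirteen heart-rate-variability
(HRV) measures computed on carefully selected night-time 5-minute segments,
together with the delivered electrical dose per tumor and patient.

Because clinical Holter recordings of this kind are not publicly available,
the package pairs every analysis stage with a synthetic generator whose
ground truth is known analytically. All statements of correctness in the
test suite are made against that ground truth or against independent
brute-force oracles.

## The synthetic recordings

`generate_ecg()` renders each heartbeat as a sum of five Gaussians (P, Q, R,
S, T) whose centers, widths and relative amplitudes are fixed in a built-in
per-lead table; the R amplitude ranges from 400 µV (aVR) to 1200 µV (lead
II). Because the template is analytic, the true Q, R and T peak times are
exact, which turns detector validation into an equality check rather than an
approximate benchmark. The RR series is

> RR(t) = mean_rr + a_LF sin(2π f_LF t) + a_HF sin(2π f_HF t) + ε,

with one sinusoid in the LF band (0.04–0.15 Hz), one in the HF band
(0.15–0.4 Hz) and white jitter ε. A sinusoid of amplitude *a* ms contributes
*a*²/2 ms² of RR variance concentrated at its frequency, giving closed-form
expectations for the spectral measures (LF ≈ a_LF²/2, LF/HF ≈ a_LF²/a_HF²).

Ectopic (premature-ventricular-like) beats occur with a configurable
per-beat probability: the beat is shifted 20–40% early, the following beat
stays in place (compensatory pause), the QRS widens 2.5-fold and the T wave
inverts — exactly the rhythm and morphology signatures the classifier must
catch. ST shifts add a constant offset over [R+40, R+120] ms on a
configurable fraction of beats; broadband white noise is optional. Defaults
used as "study conditions" in the validation suite are a 200 Hz sampling
rate, 800 ms mean RR, 5 ms jitter, LF/HF amplitudes of tens of ms and
ectopic rates below a few percent — magnitudes typical of resting night-time
recordings.

What the generator does **not** emulate: realistic 12-lead morphology,
baseline wander and electrode-motion artifacts, non-stationary autonomic
drift, or arrhythmia beyond isolated ectopy. Passing tests therefore
demonstrate correctness of the computational chain under controlled
conditions, not clinical performance of the detector on pathological
recordings.

EP pulse trains (`generate_ep_waveforms()`) are rectangular voltage pulses
across a resistive load with optional exponential droop and multiplicative
noise; pulse edges fall on sample boundaries, so the trapezoidal energy of
an ideal pulse equals V²τ/R to machine precision.

## Beat detection and classification

The detector is Pan–Tompkins in structure: zero-phase 5–15 Hz Butterworth
band-pass, squared derivative, 150 ms moving-window integration, adaptive
signal/noise thresholds with a 200 ms refractory period, and refinement of
each detection to the local extremum of the band-passed signal. Q is the
signal minimum in [R−80, R−10] ms; T the extremum relative to the PQ
baseline in [R+120 ms, R+0.6·RR]. These windows contain the template peaks
by construction and are standard physiologic ranges.

A beat is labelled abnormal when QRS width exceeds 1.5× the running median
width, when the preceding RR falls outside 0.8–1.2× the running median of
the last eight normal-to-normal intervals, or when correlation with the
running normal-beat template drops below 0.9. Q and T of abnormal beats are
discarded as unreliable. A deliberate consequence of the RR rule is that the
compensatory pause after an ectopic also flags the following (morphologically
normal) beat; this is conservative in the right direction, since intervals
adjacent to an ectopic must be edited out of the NN series anyway.

The study's manual verification step is modelled by
`apply_ground_truth()` — a non-interactive hook that substitutes reference
annotations for detector output — rather than by an editing GUI.

Counting conventions, pinned by reconciling the published per-patient table:
the abnormal-beat percentage divides by all beats (100·A/(N+A)), while the
ST percentage divides by normal beats only (100·ST/N). Of the forty
published percentage cells, thirty-eight reproduce exactly at printed
precision under these conventions; the remaining two differ by one unit in
the last printed digit and are treated as source rounding slips.

## Night window and subsegment selection

All windows are half-open `[start, end)` and defined in clock time; sample 0
of a record carries its start-of-recording clock time. The 00:00–04:00
window is cut from each record, split into twelve 20-min segments, and each
segment is scanned from its start in 1 s steps (the scan step is a package
choice; anything finer than the beat spacing gives identical results) for
the first 5-min subsegment with an abnormal fraction strictly below the
threshold that also starts ≥ 10 min after the end of the previously accepted
subsegment. The threshold starts at 1% and escalates in 1% steps to 5%.
A segment infeasible at 5% is returned with `accepted = FALSE` and silently
omitted downstream — the source does not specify this case, and an explicit
flag keeps the omission auditable. A window containing no beats is given
abnormal fraction 0; such a window cannot arise from a usable recording and
would fail at the HRV stage regardless. The selector is verified against an
exhaustive brute-force scanner on randomized annotation streams.

## HRV processing

Per accepted subsegment, RR intervals adjacent to an abnormal beat are
replaced by a natural cubic spline through the normal (time, RR) points
(`edit_rr()`, gated at ≤ 5% abnormal beats). For spectra, the edited NN
series is spline-fitted on a 1 kHz grid over the subsegment and decimated to
4 Hz (1200 samples per 5-min subsegment); no additional anti-alias filter is
applied before decimation, a deliberate simplification justified by the
smoothness of the fitted spline relative to the 2 Hz Nyquist limit for
physiologic NN series. The least-squares line is removed before the
dispersion and spectral measures; mean NN and the Poincaré descriptors use
the non-detrended series.

Conventions where the source is silent, chosen once and documented here:

* SDNN and SDSD use the sample (1/(n−1)) standard deviation; the Poincaré
  closed forms SD1² = Var(ΔNN)/2 and SD2² = 2·Var(NN) − Var(ΔNN)/2 use
  population (1/n) variances, the usual convention that makes
  SD1 = RMSSD/√2 when successive differences have zero mean.
* pNN50 counts successive differences strictly above 50 ms on the
  **non-detrended** series and divides by the total number of NN intervals.
  Counting on raw differences keeps the printed definition exact; for a
  5-min segment the difference against counting after detrending is
  negligible (the removed slope shifts each difference by ~slope·RR).
* SD1/SD2 and LF/HF are reported as `NA` when their denominator is zero,
  never as an error.
* Medians of even-length sets are the mean of the middle two, everywhere in
  the package.

Welch parameters are 256-sample (64 s) Hamming windows with 50% overlap and
per-window mean removal, scaled so the integrated one-sided PSD matches the
series variance up to window loss. The AR spectrum uses Burg reflection
coefficients at fixed order 16 (`stats::ar.burg`), evaluated on a 1024-point
0–2 Hz grid **plus local refinement of 801 points around each spectral
peak** before trapezoidal band integration: with nearly pure sinusoidal
modulation the AR poles approach the unit circle and the peaks become far
narrower than the base grid, so an unrefined trapezoid loses most of the
band mass. Band powers integrate [0.04, 0.15) and [0.15, 0.4) Hz with
interpolated band edges; nHF is computed as 100 − nLF so the normalization
identity holds exactly, which also forces the change-table rows for nLF and
nHF to be exact mirror images.

Per patient and session, each measure is summarized as the median over the
accepted subsegments. ppQTc = ppQT/√RR (RR in seconds, both neighbours
normal) is aggregated the same way — over the selected subsegments, not the
raw 4-hour series, so every reported statistic refers to the same data; the
source is ambiguous on this point.

## EP dose

Pulse plateaus are maximal runs with |V| ≥ 10% of the waveform peak, merged
across sub-10 µs gaps. The representative voltage/current of a pulse is its
plateau mean (the per-pulse reduction is unspecified in the source); a
train's value is the median over its pulses, a tumor's the median over its
trains, and a patient carries the summed energy and the per-tumor maxima of
voltage and current. Energy integrates V·I by trapezoid over detected pulses
only, making it exact for ideal rectangular pulses and insensitive to
sampling rate above ten samples per pulse. The published per-tumor energies
come from real device waveforms and cannot be recomputed from printed
averages; only the per-patient totals, which are sums of printed per-tumor
values, are used as arithmetic anchors.

## Statistics

The paired Wilcoxon signed-rank test drops zero differences (Wilcoxon's
original treatment, matching common statistics-package defaults), assigns
average ranks to tied absolute differences, and computes the exact two-sided
p-value by convolution over doubled ranks — doubling keeps average ranks
integral, so exactness survives ties, which the reference routine in
`stats` abandons. All-zero differences report p = 1 with a note instead of
erroring. Quartiles of changes use linear interpolation between order
statistics (R's default type 7). Dose–response association is ordinary
least-squares regression with a two-sided t-test on the slope. No multiple
testing correction is applied, mirroring the original analysis; the report
flags raw p < 0.05.

## Calibration strategy and problem sizes

Type-I error and power of the change-table stage are calibrated on
per-patient summary vectors drawn by `simulate_cohort_measures()` — a
cohort-level model with between-patient and within-patient (night-to-night)
variabilities of magnitudes typical for post-operative night recordings —
rather than by re-synthesizing full raw-ECG cohorts per replicate, which
adds nothing to the calibration of the statistical stage itself. The suite
uses 500 null replicates of 10-patient cohorts (the exact size of the
two-sided n = 10 signed-rank test at α = 0.05 is 0.0488) and 200 replicates
with an injected −150 ms mean-NN shift for power. The full raw-signal
pipeline is exercised end to end on small cohorts with a 40-minute
analysis window (two 20-min segments), and spectral recovery uses
320-second records; these sizes are the package's own validation choices
and scale linearly if larger studies are simulated.

## Known limitations

* The detector and classifier are validated on synthetic morphology only;
  clinical deployment would require benchmarking on annotated databases.
* The abnormal/normal dichotomy ignores arrhythmia taxonomy, and P waves are
  not analyzed.
* The ST operator is a fixed-window level difference, not a clinical ST
  algorithm; QT analysis uses peaks, deliberately avoiding T-end detection.
* Spectral measures inherit the usual short-segment caveats; no Lomb–Scargle
  or nonlinear (DFA, entropy) measures are provided.
* WFDB support covers the format-16 signal pair this package writes;
  annotations are exchanged as CSV.
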