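---
title: "Methods: short-term HRV analysis for early autonomic neuropathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: short-term HRV analysis for early autonomic neuropathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and rationale

Early diabetic cardiovascular autonomic neuropathy (DCAN) tends to
impair the vagal limb of cardiac control first. Because vagal modulation
dominates heart-rate variability (HRV) during supine rest, depressed
short-term HRV indexes measured supine are candidate early markers,
whereas the classical autonomic test battery — which largely probes
sympathetic or mixed responses — may stay normal. This package
implements the complete analysis chain needed to study that hypothesis
on short laboratory recordings in two postures (supine rest, SUP, and
head-up tilt, HUT): beat detection, NN-interval cleaning, time-,
frequency- and complexity-domain indexes, ECG-derived respiration,
transfer-function baroreflex sensitivity, autonomic-test scoring, and
ROC-based patient/control discrimination. Group-level model fitting
(linear mixed-effects contrasts) is intentionally out of scope: the
pipeline emits tidy long-format index tables ready for any external
mixed-model routine.

## From ECG to NN intervals

R peaks are found by a derivative-and-threshold detector: the squared
first difference of the ECG is smoothed over 25 ms and compared with an
adaptive threshold (a configurable fraction, default 0.3, of the local
10-s maximum, floored at 2% of the global maximum so silent stretches
stay silent). Each candidate peak is refined by fitting a parabola to
the three samples around the local maximum and taking the vertex, which
gives sub-sample timing (at 1000 Hz, well below 1 ms) and a refined
amplitude; exactly three samples are used because it is the minimal,
standard choice matching the stated interpolation.

Interactive artifact editing is replaced by a deterministic, reviewable
rule: an RR interval is rejected when it is shorter than 0.75x or longer
than 1.5x the running median of the last 11 accepted intervals (the
global RR median seeds the rule before any acceptance). The beat ending
a too-short interval is labeled premature and both intervals touching it
are dropped — this removes the premature beat *and* its compensatory
pause in one pass; a too-long interval is dropped as a missed-beat gap.
Contiguity flags record every gap, and all pairwise statistics
(pNN50, RMSSD) use contiguous pairs only. The 0.75/1.5 thresholds are
configurable defaults, not asserted clinical constants, and a manual
override list (`override_artifact`) preserves the possibility of expert
review. Times are seconds from record start, intervals milliseconds, and
all windows half-open `[start, end)`.

## Time domain

pNN50+ and pNN50− count successive NN pairs differing by at least +50 ms
or at most −50 ms; the comparison is inclusive ("at least 50 ms") and
the denominator is the number of valid successive pairs, which keeps the
statistic well-defined across gaps. The SDNN index averages the sample
(n−1) standard deviation over running 5-min windows; the window step
defaults to 60 s (the running step is not standardized in the
literature, so it is exposed as a parameter), and windows with fewer
than 30 intervals are skipped with a warning.

## Frequency domain

The tachogram assigns each NN value to its onset time and is linearly
interpolated onto a uniform 5-Hz grid, bridging flagged gaps. Spectra
use the Welch periodogram with 50%-overlapped 120-s Hann windows; each
segment is mean-removed only — no linear detrending — because power down
to 0.005 Hz must survive. The one-sided PSD is normalized so its
integral over [0, fs/2] equals the series variance (checked to within 2%
by the Parseval tests). An optional frequency-domain moving average
("wideband smoothing") defaults to a 0.01-Hz bandwidth: with a 120-s
window the native resolution is 0.0083 Hz, so the default smooths
minimally and cannot blur the band edges; the bandwidth of the original
smoothing technique is not recoverable, hence it is left configurable.
Band powers integrate half-open bands (VLF 0.005–0.04, LF 0.04–0.15, HF
0.15–0.40, total 0–0.5 Hz) by trapezoid with interpolated edges, and
LF/HF is flagged undefined (NA) rather than infinite when HF is zero.

## Complexity domain

Sample entropy uses the Richman-Moorman convention: N−m overlapping
templates, Chebyshev distance, self-matches excluded, ties (distance
exactly r) counting as matches, with m = 1 and r = 15% of the series SD
as defaults. The pair counting is compiled (Rcpp); an O(n²) brute-force
enumeration lives in the test suite and must agree exactly.

Multiscale entropy coarse-grains the NN series at integer beat scales.
The default is *overlapping* coarse-graining (stride-1 moving average)
with the tolerance fixed at 15% of the *original* series SD at every
scale; the classical non-overlapping, m = 2 variant is available as the
`"costa-replication"` preset so both conventions can be contrasted on
the same data. Scales map to seconds through the mean NN interval
(tau = s x NNI_m), and the HF (2.5 ≤ tau < 6.7 s) and LF
(6.7 ≤ tau < 25 s) band averages are unweighted means over tau — in
seconds, not beats, so a fast heart rate shifts which beat scales enter
each band. Tolerance is computed per analyzed segment (i.e., per
condition), since indexes are reported per condition.

Multiscale DFA integrates the mean-removed series, detrends first-order
polynomials in non-overlapping boxes on a log-spaced grid (8 points per
octave from 4 beats to n/8 — covering 5–61 s for 10–16-min records at
normal heart rates), and estimates the scale-dependent exponent
alpha(tau) as the local slope of log F vs log n by centered finite
differences (one-sided at the edges) — the simplest defensible estimator
of a scale-dependent exponent. The detrending order is exposed because
order 1 vs 2 is not recoverable from the source material; order 1
(standard DFA-1) is the default. `dfa_exponent` provides the classical
single-slope fit used by the exponent-recovery tests (0.5 for white
noise, 1.5 for integrated white noise). alpha_short averages the closed
band [5, 11] s and alpha_long the open band (17, 61) s, as stated.

## ECG-derived respiration

The R-peak amplitude series is interpolated to 5 Hz, high-pass filtered
at 0.05 Hz with a zero-phase (forward-backward) 4th-order Butterworth —
zero-phase so the respiratory peak is not displaced; only the cutoff is
prescribed — and the breathing rate is the frequency of the highest
Welch spectral peak. The peak search is restricted to frequencies at or
above the cutoff: content below it is by construction non-respiratory,
and this makes the behavior for sub-cutoff modulation exact (it is never
reported) rather than dependent on filter leakage.

## Baroreflex sensitivity

Resonance in the baroreflex loop produces LF blood-pressure oscillations
to which the reflex responds by modulating heart rate at the same
frequency. Both beat-domain series are resampled at 5 Hz; the gain
|S_xy(f)|/S_xx(f) (SBP auto-spectrum in the denominator — the only
reading dimensionally consistent with ms/mmHg; the alternative √S_xx
reading would carry units of ms) is averaged over 0.04–0.15 Hz, and the
squared coherency |S_xy|²/(S_xx S_yy) over the same band indexes the
coupling strength. Welch settings are inherited from the spectral module
for consistency. At least three segments are required: single-segment
coherency is identically 1. Because the modulus discards phase, reflex
delays of a couple of seconds do not bias the gain.

## Autonomic tests and questionnaires

Each traditional test is an extremum-minus-baseline (or ratio) contract
on annotated windows; baselines are summarized by their mean because a
single reference value is implied. The tilt 30:15 windows default to
beats 25–35 and 10–20 post-tilt ("around" the 30th and 15th beat has no
standardized width, so the windows are parameters). The cold-pressor
immersion window is clamped to 90 s. Ewing scoring (0/0.5/1 per test,
five tests) reads its borderline/abnormal cut-offs from an editable
table whose defaults follow the classical battery literature — the
schema, not the values, is the tested surface, because the cut-offs are
conventions external to this package. The SCOPA-AUT score is the item
sum as a percentage of the achievable maximum, with missing items
prorated by default.

## Statistics

The AUC is computed through the Mann-Whitney identity with midranks, so
it equals exhaustive pair counting exactly (a property the tests
assert). The standard error defaults to Hanley-McNeil with DeLong as an
option — which estimator produced the reference numbers is unknown, so
one had to be the default and both are provided. The p-value against
AUC = 0.5 uses the Mann-Whitney test (exact for small tie-free samples).
Youden cut-offs scan midpoints between adjacent pooled values, break
ties toward specificity, and are reported only when the AUC is
significant at the configured level, mirroring standard reporting
practice; classification uses the strict inequality in the case
direction, which makes sensitivity/specificity invariant under monotone
transforms. HRV indexes default to `case_low` (neuropathy depresses
them); symptom scores to `case_high`. `normal_model_rate` links a
reported mean/SD to a reported cut-off sensitivity via the normal CDF.
Pointwise multiscale comparisons run a Mann-Whitney test per abscissa
with 5%/1% masks and optional Benjamini-Hochberg correction, switching
to the exact U distribution below 8 subjects per group.

## The synthetic-data generator

The generator exists so every stage is testable without restricted
clinical data. It emulates, with seeded determinism:

* **RR tachograms** as one sinusoid per band (VLF/LF/HF) plus a 1/f^beta
  Gaussian background (beta defaults to 1, matching the near-unity
  self-similarity of resting heart rate), sampled in the *beat domain* —
  oscillators are evaluated at beat onsets and the next beat follows
  after the current interval. Integral pulse-frequency modulation is not
  simulated: the analysis operates on the resampled tachogram, and the
  configured powers are defined as the band powers *of that tachogram*.
  Because linear interpolation of a beat-rate-sampled sinusoid
  attenuates it by sinc²(f·NNI_m), the generator pre-compensates the
  oscillator amplitudes so the configured power is what the spectral
  module measures (verified to within 10% at one 16-min realization).
* **Respiratory QRS modulation**: a Gaussian QRS template per beat,
  amplitude-modulated by (1 + depth·sin(2π f_resp t)), closing the loop
  with the EDR estimator.
* **Baroreflex coupling**: an LF pressure sinusoid plus broadband
  beat-to-beat pressure variability, both coupled into RR through a
  linear gain (the delay applies to the LF oscillation; the broadband
  component couples within the beat), plus additive RR noise. With no RR
  noise the transfer method recovers the gain within 5%; the broadband
  pressure term gives the SBP spectrum a realistic noise floor so a
  zero-gain configuration yields a near-zero gain estimate instead of a
  0/0 artifact.
* **Index cohorts**: per-subject index values drawn independently per
  index and condition from the reference marginal mean/SD table
  (`table2_reference`). Only marginals are reported in the reference, so
  no inter-index correlation is imposed. Two shapes are offered —
  Gaussian and moment-matched log-normal — because the underlying
  distributional shape beyond mean (SD) is unknown; several indexes have
  SD of the order of the mean, for which the log-normal avoids negative
  draws. Gaussian draws are *not* truncated by default: truncation would
  bias the sample moments away from the configured values (by about
  1.5% for supine RMSSD), breaking the generator's convergence contract;
  zero-clamping is available as an option for analyses that require
  nonnegative values.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: ectopy and artifact morphology
beyond simple premature/missed-beat patterns, nonstationarity within a
condition, respiratory sinus arrhythmia's frequency wander, closed-loop
cardiovascular dynamics, inter-index correlation within subject, and
any ECG morphology beyond a single Gaussian QRS.

The signal-level cohort runner (`run_signal_cohort`) draws per-subject
tachogram parameters around the reference values (log-normal for powers,
normal for the mean NN, with a coefficient of variation of 0.5 chosen as
a realistic between-subject spread) and synthesizes a pressure series
consistent with a subject-specific baroreflex gain. Its default problem
size — 16-min supine plus 10-min tilt records, with the test suite
exercising 20 subjects per group — matches the recording protocol the
pipeline targets.

## Numerical choices and degenerate inputs

* Oscillator-free, noise-free RR configs produce exactly constant
  series; a 250-ms floor guards against non-physiological intervals.
* An all-constant ECG yields an empty beat series with a warning, not an
  error; fewer than two surviving NN intervals after cleaning is an
  error.
* Zero HF power flags LF/HF as NA; zero SBP LF variance flags BRS as NA;
  constant QRS amplitudes flag the breathing rate as NA; SampEn with no
  template matches is NA. All are warnings carrying the reason.
* MSE profiles truncate (with a warning) at scales leaving fewer than 50
  coarse-grained points; DFA box grids are clipped to feasible sizes.
* `run_subject` marks indexes whose preconditions fail (240 s for
  spectra, 300 s for the SDNN index, 250 beats for MSE, 500 for DFA) as
  unavailable with an explicit reason instead of failing the record.

## Known limitations

The detector is tuned for clean single-lead ECG at laboratory quality;
it does not classify QRS morphology or handle pacemaker spikes. The
cleaning rule is deliberately simple and conservative; heavily ectopic
recordings should be reviewed via the override mechanism. Autoregressive
and Lomb-Scargle spectra are intentionally absent (the resampling route
is the one implemented). Recurrence quantification analysis is out of
scope. The cohort generator's independence across indexes means joint
(multi-index) classifiers built on it will understate real-world
correlation structure.
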