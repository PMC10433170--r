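---
title: "Methods: temporal contrast sensitivity from SSVEPs"
author: "ssvepTCSC"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the parameters that matter, the
synthetic-data generator, and the design choices behind `ssvepTCSC`. It
states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

# The measurement problem

A luminance flicker at frequency $F$ (Hz) and Michelson modulation depth
$\mathrm{MD} = (L_{max}-L_{min})/(L_{max}+L_{min})$ is consciously visible
only above a frequency-dependent threshold. Two observers can be asked the
same question: the participant ("did you see flicker?") and the participant's
EEG (is there an SSVEP — a spectral response at $h \cdot F$?). The package
derives a temporal contrast sensitivity curve (sensitivity $=$ 1/threshold
as a function of $F$) from each and compares them.

The pipeline assumes:

* square-wave luminance modulation, $L(t) = \mathrm{AvgLL}\,(1 +
  \mathrm{sgn}(\sin 2\pi t F)\,\mathrm{MD})$, with only odd Fourier
  components $C_m = (4/\pi)\,\mathrm{MD}/m$ relative to DC;
* trials of 3 s constant light (baseline) followed by 3 s of flicker
  (stimulation), so that each trial yields a matched epoch pair;
* SSVEP energy confined to harmonic bins $h\cdot F < 128$ Hz at 1 Hz
  resolution, with possibly dominant *even* harmonics at low $F$ (a
  non-linearity of the visual system; a linear system would show only odd
  harmonics of a square wave);
* detection probabilities that are monotone in MD, so a probit psychometric
  model applies.

# Detection statistics

Epoch spectra are FFT amplitude spectra of three non-overlapping 1-s
rectangular windows (no detrending), averaged and $\log_{10}$-transformed;
at 256 Hz this gives integer bins 1..128 Hz. Per condition (one subject,
$F$, MD):

$$d(f) = \frac{\bar{x}_S(f) - \bar{x}_B(f)}{\sigma_{SB}(f)}, \qquad
z_i(f) = \frac{x_{Si}(f) - \bar{x}_B(f)}{\sigma_B(f)},$$

with $\sigma_{SB}$ the pooled SD
$\sqrt{((n_S{-}1)s_S^2 + (n_B{-}1)s_B^2)/(n_S{+}n_B{-}2)}$. The *best
harmonic* for a frequency maximises $d(h\cdot F)$ over $h \in 1..10$,
$h\cdot F < 128$ (ties to the smaller $h$), estimated only from trials the
flicker visibility measure predicts visible, so sub-threshold conditions do
not dilute the contrast. A trial is a detected SSVEP iff $z > 0$ at the best
harmonic bin. Note the rule's two structural properties, both load-bearing
later: under the null its detection probability is 0.5 (a coin flip against
the baseline mean), and the log-transform makes $z$ and $d$ invariant to
multiplicative rescaling of the raw signal.

Frequency-level QC mirrors judgment-based exclusion of unanchored
conditions: a frequency is kept only if at least a fraction 0.25 of subjects
have their global argmax of $d$ (bins 3–127) exactly on an expected harmonic
bin, and the mean best-harmonic $d$ is at least 0.05. Both thresholds are
package inventions (the original exclusion was a judgment call) and are
exposed as configuration.

# Psychometrics and the TCSC

Detection probabilities per MD are fitted with a binomial GLM, probit link,
linear predictor in raw MD (log-MD is available as an option; the default
matches fitting on linear axes). The 50% threshold is $-\beta_0/\beta_1$. A
record is invalid if the slope is non-positive, the threshold non-positive,
the fit degenerate (complete separation: every cell at 0% or 100%), or the
residual deviance against the saturated model is $\ge 1$. The deviance rule
is read literally as *total* deviance below one, not per degree of freedom —
a strict gate: for a well-specified 5-cell binomial fit the residual
deviance is roughly $\chi^2_3$, so most honest fits fail it, and a single
lapse in a saturated cell (observer pressing "no" on a clearly visible
trial) usually blows it. Low validity rates are therefore expected
behaviour, not a defect; pooling compensates with cohort size.

Valid sensitivities are pooled per frequency (single-pass exclusion of
values beyond 2 SD from the mean, then the arithmetic mean; at least 3
records by default) and fitted with the cubic/linear rational curve

$$\mathrm{TCSC}(f) = \frac{p_1 f^3 + p_2 f^2 + p_3 f + p_4}{f + q_1}$$

by Levenberg–Marquardt. Initialisation solves the linearised system
$S(f)\,(f+q_1) = p_1f^3 + \dots + p_4$ by ordinary least squares over the
candidate grid $q_1 \in \{1, 5, 10, 20, 40\}$ and starts from the best
candidate. $R^2$ is reported against the mean sensitivities and also on the
reciprocal (threshold) scale, because the scale on which the original
goodness of fit was computed is ambiguous; both are in the fit object.
95% prediction bounds are observation-level delta-method bounds
$\hat{S}(f) \pm t_{0.975,\,df}\sqrt{\hat\sigma^2 + g^\top \Sigma g}$ with
$g$ the coefficient gradient. The peak is located on a 0.01 Hz grid and
refined by golden-section search; for acceptance-style comparisons it is
rounded to integer Hz. Curves from the two sources are compared per
frequency with two-sided Wilcoxon rank-sum tests and Storey q-values
($\lambda = 0.5$, $\hat\pi_0$ clamped to $(0,1]$; $\hat\pi_0 = 1$ recovers
Benjamini–Hochberg), flagged at $q < 0.005$ and $q < 0.001$.

## The reference curve's scale

Evaluating the published psychophysical coefficients
($p_1 = -0.0008,\ p_2 = -0.409,\ p_3 = 40.68,\ p_4 = 121.50,\ q_1 = 10.75$)
gives a curve peaking at 18.28 Hz with a maximum near 25, an order of
magnitude below the reported peak sensitivity of 309 (the electrophysiological
set behaves the same relative to 258). The peak *location* is therefore
trustworthy while the printed coefficients' absolute scale is not
reconstructible. `defaultReferenceCurve()` keeps the printed shape and
multiplies it so the maximum equals 309; every threshold derived from it
inherits that anchoring. Users with tabulated reference curves (e.g. classic
flicker-sensitivity tables) can supply them via `tabulatedCurve()` /
`readCurve()`; interpolation is log-log linear, and queries outside a
curve's domain are errors, never silent extrapolation.

## Flicker visibility measure

$\mathrm{FVM} = \sqrt{\sum_m (C_m/T_m)^2}$ with $T_m$ the threshold at the
component frequency from the reference curve (sine-threshold semantics: the
curve itself defines $T$). Components above the curve domain (harmonics
beyond 60 Hz by default) contribute nothing — sensitivity is vanishing there
and no reference values exist. The Minkowski exponent defaults to 2 and is
configurable for sensitivity analyses.

# The synthetic cohort

The generator replaces unavailable raw recordings; its defaults are the
study conditions: four experiments with cohorts 10/12/24/16, the published
condition grids (experiment 1: five frequencies × multipliers 0.6–1.4 of a
reference threshold; experiment 2: absolute MDs 0.002–0.026; experiment 3:
six frequencies × 0.6–1.4; experiment 4: five low frequencies with
multipliers up to 12.8), 10 repetitions, acquisition at 2048 Hz
(`rate = 256` generates analysis-ready epochs directly and is what the test
suite uses for speed). Experiment 1 carries no subjective reports. Seeds
form a master → subject → trial hierarchy, so any single trial is
reproducible in isolation.

Per subject: background EEG is random-phase noise with amplitude spectrum
$\propto 1/f^{\alpha}$ ($\alpha = 1$) for $f \ge 1$ Hz plus a Gaussian alpha
bump (8.5–11.5 Hz, SD 2 Hz, 4 µV), overall scale 10 µV at 1 Hz — RMS around
15–20 µV, a realistic resting posterior EEG amplitude. Thresholds follow the
reference curve with a per-subject log-normal jitter (SD 0.1).
Psychophysical reports are Bernoulli draws from
$\gamma + (1-\gamma-\lambda)\,\Phi((\mathrm{MD}-\theta_{psy})/\sigma)$ with
lapse and guess rates $\gamma = \lambda = 0.02$ and $\sigma = 0.25\,
\theta_{psy}$. The electrophysiological threshold is
$\theta_{eeg}(f) = \kappa(f)\,\theta_{psy}(f)$ with $\kappa = 1.8$ below
45 Hz falling linearly to 0.7 at 60 Hz, emulating the empirical crossing:
EEG less sensitive than behaviour at low frequencies, more sensitive at
60 Hz (SSVEPs without a percept).

SSVEP amplitude follows a log-contrast law,
$A = a_s \max(0,\ \log_{10}(\mathrm{MD}/\theta_{eeg}) + c_0)$, distributed
over harmonics with the dominant weight (0.6) on the fundamental for
$F \ge 20$ Hz and on the even harmonic nearest 40 Hz for lower frequencies
(ties to the smaller harmonic), the remainder spread $\propto 1/h$.

## Calibrating the amplitude law (gain and $c_0$)

Two generator constants have no external anchor and were fixed by a
calibration study *before* the acceptance suite was written (the scripts are
not part of the package):

* **Onset offset $c_0 = -0.15$.** The $z>0$ rule has a 0.5 detection floor
  under the null, and the pipeline's probit has no floor parameter, so the
  fitted 50% point systematically precedes the amplitude-onset knee — across
  gains it lands at ≈ 0.73× the knee. Defining $\theta_{eeg}$ as *the MD at
  which the fitted detection probability crosses 50%* (i.e. the measurand of
  the pipeline) therefore requires the onset knee slightly *above*
  $\theta_{eeg}$: $c_0 = -0.15$ puts it at $10^{0.15} \approx 1.4\,
  \theta_{eeg}$. With a positive offset (onset at half-threshold) the stored
  ground truth would not be the quantity the procedure estimates, and
  recovery tests would measure a constant bias instead of estimator quality.
* **Gain $a_s = 8$ µV/decade.** Small enough that detection rises over, not
  below, the sampled MD range; large enough that the rise completes within
  it. Recovery quality is flat over gains 6–14, so the value is not a
  sensitive tuning.

Threshold-recovery tests sample MDs at log-spaced multipliers
$\{0.7, 1.0, 1.4, 2.0, 2.8\}$ of $\theta_{eeg}$ so the detection rise lies
inside the sampled range — the same logic by which the original fourth
experiment extended its multipliers to 12.8× at low frequencies. Recovery
is evaluated on the raw probit estimates (positive slope, positive
threshold); the deviance gate is a pooling filter, not part of the
estimator, and at 10 trials per condition it passes too few fits to define a
median at test scale.

## What the generator does and does not emulate

Emulated: 1/f background with alpha activity; harmonic SSVEP structure with
even-harmonic dominance at low frequencies; amplitude growth with log
contrast; probit observers with lapses; the psychophysical/
electrophysiological sensitivity crossing near 50 Hz; multichannel mode with
a Pz-dominant topography (for common-average-reference and best-channel
selection); full-rate 2048 Hz generation exercising the entire filtering
chain.

Not emulated: blinks and muscle artifacts (the variance-rejection rule is
tested on Gaussian tails instead, and its observed rejection rate is logged,
not asserted); volume conduction and realistic topographies; phase-locking
structure; alpha desynchronisation during stimulation; saturation of SSVEP
amplitude at high MD. Passing tests on synthetic data therefore validate the
*statistical machinery and its calibration*, not robustness to real-world
artifact regimes — for real recordings the ICA hook
(`removeOcularArtifacts`) accepts an external component-removal step.

# Numerical and implementation choices

* Square-wave sign at transition samples: $\mathrm{sgn}(0) = +1$ (half-open
  duty convention); affects at most $2F$ samples per second.
* 3 s at 2048 Hz is 6144 samples; epochs at 256 Hz are 768 samples, half-open
  windows $[o-3\,\mathrm{s}, o)$ / $[o, o+3\,\mathrm{s})$ around a 0-based
  onset offset.
* Notch: RBJ biquad at 50 Hz, Q = 30, forward–backward. Resampling 2048→256:
  zero-phase 257-tap FIR anti-alias low-pass, then take every 8th sample.
  High-pass: 257-tap (1 s) Hamming FIR at 2 Hz, forward–backward. The 1-s
  filter length is a deliberate compromise: a filter sharp enough for a
  1 Hz transition band (~850 taps) would leave zero-phase transients longer
  than a synthetic trial record; 257 taps keeps transients inside the 1-s
  padding the generator adds around each trial while preserving 10 Hz within
  5% and removing DC (both asserted in tests).
* Artifact rejection variance is computed on the stimulation epoch at the
  analysis channel (Pz) by default; epoch kind is configurable
  (`"baseline"`, `"both"`), single pass.
* Harmonic bins are exact integer-Hz bins (all stimulation frequencies are
  integers); zero pooled SD yields $d = 0$ with a warning; zero baseline SD
  is an error for z-scores.
* `log10` for the spectral log-transform; the base cancels in $z$ and $d$ up
  to a common factor.
* Rational-fit non-convergence raises an error (the last iterate is in the
  condition message via `minpack.lm`); a singular covariance produces `NA`
  bounds rather than fabricated ones.
* Baseline statistics are strictly per condition (10 baseline epochs by
  design), which makes $\sigma_B$ noisy; this is faithful to the procedure
  and is part of why electro detection curves are noisier than subjective
  ones.
* Experiment 1's reference curve is user-supplied (its classical tabulated
  source is not shipped); condition *counts* are curve-independent, and the
  package default is used when only bookkeeping is needed.

# Problem sizes in the shipped tests

The test suite runs cohorts far smaller than the study design (2–3 subjects
per experiment, 4–6 repetitions) and generates epochs directly at 256 Hz;
the full-rate 2048 Hz path is exercised on single trials. Threshold-recovery
checks use 40 subjective observers (5 MDs × 10 trials) and 12
electrophysiological observers × 5 frequencies; null calibration uses 100
zero-MD conditions of 10 trials and 2000 Wilcoxon replicates;
prediction-bound coverage uses 500 refits. These sizes are the package's
choice of smallest designs at which the medians and rates under test are
stable.

# Known limitations

* The absolute scale of the default reference curve is anchored to the
  reported peak (309), not derived from printed coefficients (see above);
  FVM values and relative-MD condition grids inherit it.
* The deviance-below-one validity gate is extremely strict for grouped
  binomial data; with small cohorts most frequencies collect fewer than 3
  valid records and drop out of pooling. This matches the rule as stated,
  but users with small datasets may prefer `devianceMax` scaled per degree
  of freedom.
* The z > 0 rule's 0.5 floor means electrophysiological "detection
  probabilities" never fall below chance; fitted thresholds are
  interpretable only through the calibration above.
* No sub-harmonic analysis, no CCA/common-spatial-pattern multichannel
  detectors, no ICA implementation (hook only), no hardware calibration of
  luminance.
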