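---
title: "Methods: heart-rate-variability responses to affective stimulation"
author: "hrvaffect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-rate-variability responses to affective stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hrvaffect` implements an end-to-end pipeline for studying short-term
heart-rate-variability (HRV) responses to emotionally salient stimulation,
of the kind used to probe residual affective processing in patients with
disorders of consciousness (DOC: the unresponsive wakefulness syndrome, UWS,
and the minimally conscious state, MCS) against healthy controls (HC).
The pipeline covers: a synthetic ECG/beat generator with embeddable
condition effects, ECG preprocessing and QRS detection, ectopic-beat
correction, twelve HRV measures per stimulus window, within-subject
normalization, and nonparametric group statistics laid out as a
feature-by-contrast results matrix.

# Experimental protocol model

A session (`SessionProtocol`) is a contiguous sequence of events: a 60-s
resting baseline, then twelve 55-s video stimuli in randomized order — six
featuring a personally familiar person (*acquaintance*), six an unknown
person (*stranger*) — each followed by a 55-s rest. Healthy participants
additionally have a rating gap after each stimulus, generated as an extra
rest-labelled event; analysis treats it as rest. Events are half-open
intervals `[onset, onset + duration)`.

# Synthetic beat generator

Beats are produced by an integrate-and-fire scheme on an instantaneous
heart-period function

$$ m(t) \;=\; m_0 + A_{LF}\sin(2\pi f_{LF} t) + A_{HF}\sin(2\pi f_{HF} t)
   + \delta\big(c(t)\big) + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma^2), $$

where $c(t)$ is the protocol condition at time $t$ and $\delta$ adds a
condition-specific heart-period shift (ms). Each next beat time is the
previous time plus the sampled period; the condition is evaluated at the
tentative *terminating* beat time, matching how intervals are later assigned
to windows, so a configured $\delta$ appears in window means exactly.

Defaults (`HeartPeriodModel`): $m_0 = 850$ ms (typical adult resting heart
period), $A_{LF} = 20$ ms at $f_{LF} = 0.1$ Hz (Mayer-wave band),
$A_{HF} = 25$ ms at $f_{HF} = 0.25$ Hz (respiratory sinus arrhythmia),
$\sigma = 10$ ms beat-to-beat noise, and
$\delta = (+25, 0)$ ms for (acquaintance, stranger). The cohort default
(`cohortSpec`) is 17 HC with the full effect and 5 MCS / 6 UWS with the
effect scaled to zero; these defaults *are* the study conditions the
acceptance suite runs, and are never adjusted to make a test pass.

The generator can also synthesize a waveform: a template of Gaussian
P/Q/R/S/T deflections (R amplitude 1 mV, width 10 ms) placed at each beat,
plus optional baseline wander (sinusoid, default 0.2 mV at 0.25 Hz), mains
interference (50 Hz) and white noise. The record starts 1 s before the
first beat so the first QRS complex is never truncated.

**What the generator emulates:** realistic beat timing with LF/HF spectral
structure, condition-locked mean shifts, ectopic contamination (`injectEctopics`
re-times a chosen fraction of non-adjacent beats to 60% of their preceding
interval), and the dominant ECG artifact classes. **What it does not:**
respiration-coupled amplitude modulation, non-stationary autonomic drift,
electrode motion bursts, arrhythmias beyond isolated ectopy, or any
physiological coupling between emotion and HRV beyond an additive
heart-period shift. Passing tests therefore demonstrate that the pipeline
recovers effects *of the assumed form* under controlled contamination; they
are not evidence about real patient recordings.

# ECG preprocessing

All steps are exposed individually and chained by `preprocessECG`:

1. **Resampling** to 256 Hz by Fourier-domain zero-padding/truncation
   (`fftResample`). An FFT method was chosen after the available
   polyphase-FIR routine showed passband amplitude error on pure tones;
   the FFT route is exact for band-limited signals.
2. **High-pass** 5th-order Butterworth at 0.5 Hz, applied forward-backward
   (zero phase) with odd-reflection padding of length `3 fs / fc`, so QRS
   latencies are not shifted by the filter.
3. **Notch** at 50 Hz, quality factor 30, as an order-2 Butterworth
   band-stop of width $f_0/Q$, also zero-phase.
4. **QRS detection** by the Pan–Tompkins cascade: 5–15 Hz band-pass,
   5-point centered derivative, squaring, 150-ms moving-window integration,
   adaptive signal/noise thresholds with a 200-ms refractory period and a
   1.66-mean-RR search-back, then refinement of each fiducial to the
   waveform maximum within ±50 ms.
5. **Ectopic correction** (below) and a 200–3000 ms plausibility gate on
   the resulting intervals.

# Ectopic correction and the rejection rule

An interval is flagged when it deviates from the local median of up to five
preceding and five following unflagged intervals by more than 20%
(`tol = 0.2`). Flagged beats are re-timed by a cubic spline fitted to the
unflagged beat times, with the prediction rescaled so the span of each
corrected run is preserved; corrected beats are annotated `"interpolated"`,
so downstream counts of corrected beats are exact. If 20% or more of beats
are implicated (`maxFraction = 0.20`), the series is refused with a typed
condition (`uncorrectableSeries`) rather than silently cleaned; pipeline
drivers log such subjects as exclusions and continue.

# HRV measures

Per window, from intervals assigned by their terminating beat:

* **Time domain** (ms and %): MeanNN, MedianNN, MadNN (median absolute
  deviation × 1.4826), SDNN (sample SD), RMSSD, SDSD, the 80th and 20th
  percentiles (Prc80NN, Prc20NN; R's type-7 quantile), and pNN20 / pNN50 —
  the percentage of successive-difference magnitudes *strictly greater*
  than 20 / 50 ms. The strict inequality is used for both thresholds; a
  boundary difference of exactly 50 ms does not count.
* **Frequency domain**: the tachogram is cubic-spline resampled at 4 Hz,
  mean-removed, Hann-tapered, and a single-segment Welch periodogram is
  integrated over 0.15–0.4 Hz to give HF (ms²). HFn is HF divided by the
  power over 0.04–0.4 Hz, i.e. normalized to total LF+HF power. Windows
  shorter than 120 s are flagged `lowReliability` (a 55-s window holds
  barely eight cycles of the lowest HF frequency); windows under 30 s or
  with fewer than 10 intervals return no spectral values. A zero-variance
  tachogram returns HF = 0, HFn = 0 with a `degenerate` flag rather than
  0/0.

A window with fewer than 4 intervals is marked invalid with all features
missing; missing data are propagated, never zero-filled.

# Normalization

For each subject, feature and stimulus window,

$$ z \;=\; \frac{x_{\text{stim}} - x_{\text{preceding rest}}}
                {\mathrm{MAD}_{\text{subject}}} $$

where the reference is the rest window immediately before the stimulus (the
baseline for the first stimulus) and the denominator is the raw MAD
(constant 1) of that feature over *all* of the subject's windows — baseline,
stimuli and rests alike. Using all windows makes the scale estimate
independent of the contrast being tested; a zero MAD is floored at $10^{-9}$
and flagged. This removes between-subject offsets and scale differences, as
the test suite verifies by invariance checks.

# Statistics

The sampling unit is the normalized stimulus window pooled within a group
(17 HC × 6 windows per condition = 102 values); `unit = "subject"` switches
to per-subject condition means. Nine contrasts are computed for each of the
twelve measures:

* within-group acquaintance vs. stranger (HC, UWS, MCS): Wilcoxon
  signed-rank, windows paired by protocol position (k-th acquaintance with
  k-th stranger);
* HC vs. MCS, HC vs. UWS, and HC vs. pooled DOC, separately per condition:
  Wilcoxon rank-sum.

Both tests drop zero differences, use mid-ranks and no continuity
correction. The signed-rank p-value is **exact under ties** for up to 50
informative pairs, via a shift-convolution over doubled mid-ranks (the
doubling keeps mid-ranks integral); beyond that the tie-corrected normal
approximation is used. The rank-sum p-value is exact (Mann–Whitney null)
when untied with both groups ≤ 50, otherwise tie-corrected normal. The
reported Z is the normal-approximation magnitude signed by the direction of
the median difference, so effect direction is always readable off the
table. p-values are Bonferroni-corrected within each contrast across the
twelve-measure family ($m = 12$), and the effect size is
$r = |Z| / \sqrt{n_1 + n_2}$. A Shapiro–Wilk screen is available as an
advisory check; the analysis is nonparametric regardless. Demographic
comparisons use a pooled-variance t-test, with group descriptives reported
under both the sample (n−1) and population (n) SD conventions, since
published tables differ in which they print.

# Design choices that were genuinely open

* **MAD basis.** The per-subject MAD could be computed from rest windows
  only; we use all windows so the denominator does not depend on the
  hypothesis under test and stays estimable for partially missing sessions.
* **pNN thresholds.** Strict `>` for both pNN20 and pNN50, treating the two
  thresholds symmetrically.
* **HFn denominator.** HF normalized by total 0.04–0.4 Hz power (LF+HF),
  the common "normalized units" convention, rather than by total spectrum
  including VLF, which a 55-s window cannot resolve.
* **Sampling unit.** Window-level pooling is the default because per-group
  subject counts (5–6 patients) are too small for a six-pair signed-rank
  test to reach corrected significance at all; the subject-level option is
  retained for sensitivity analyses.
* **Exactness policy.** Exact null distributions whenever they are
  computable in negligible time (n ≤ 50), including under ties for the
  signed-rank test, so small-sample p-values never depend on the normal
  approximation.
* **Failure semantics.** Data problems raise typed conditions
  (`hrvDataError`, `uncorrectableSeries`, `hrvConfigError`); cohort drivers
  convert them to logged exclusions and continue, mirroring how a study
  reports excluded participants.

# Problem sizes used by the test and acceptance suites

The suites choose sizes that exercise every code path while keeping a full
run to a few minutes: 1000 random series for the feature oracle; four heart
rates (50–120 bpm) × 120 s of noisy ECG for the detector; 300-beat series at
5–25% contamination for the ectopic rule; 1000 simulated null replicates for
test calibration; and 100 (tests) / 30 (acceptance script) replicate cohorts
at the full default size (17 HC, 5 MCS, 6 UWS) for end-to-end pattern
recovery. These are the package's own choices of demonstration scale.

# Known limitations

* The waveform generator's morphology is schematic; detector performance on
  pathological morphologies (bundle-branch block, low-amplitude records) is
  untested.
* Ectopy is modelled as isolated premature beats; runs of arrhythmia are
  outside the correction rule's design and should trip the rejection rule
  instead.
* The frequency-domain measures on 55-s windows are, by construction,
  low-reliability estimates and are flagged as such.
* Group comparisons pool windows within groups, so between-subject
  correlation is not modelled; conclusions at the subject level require
  `unit = "subject"` and adequate group sizes.
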