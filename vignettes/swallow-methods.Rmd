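---
title: "Swallowing-sound profiles from cervical auscultation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swallowing-sound profiles from cervical auscultation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swallowCA)
```

## The problem

Cervical auscultation (CA) records swallow and breath sounds with a small
microphone taped to the neck during a feeding observation. In preterm
neonates it is one of the few repeatable, non-invasive ways to characterise
swallowing, because instrumental assessments (videofluoroscopy, FEES) are
rarely justifiable in this population. `swallowCA` implements the complete
analysis chain for such recordings: per-swallow acoustic profiles from
annotated PCM WAV audio, a perceptual rating schema with a rule-based
coordination classifier, two-rater agreement statistics, and cohort-level
inference — plus a synthetic-data generator, since clinical feeding
recordings generally cannot be shared and every stage must be testable
without them.

The package consumes a session recording (single channel, 44,100 Hz,
integer PCM) and a swallow annotation table (`recording_id, swallow_id,
start_s, end_s`). Identifying swallow boundaries is a human task done with
simultaneous audio, video and spectrogram review; automatic swallow
detection is out of scope.

## Acoustic model

Each annotated swallow is reduced to four parameters.

**Duration** is simply `end_s - start_s` of the annotation.

**Peak frequency** is *not* a spectral argmax. It is the frequency below
which 95% of the spectral power of the loudest part of the swallow lies:

1. high-pass filter the segment (4th-order Butterworth, 400 Hz cutoff) to
   remove the large low-frequency energy of breathing and handling noise;
2. split into 20 ms frames with 50% overlap and select the frame of
   maximum energy $\sum x^2$;
3. estimate that frame's power spectral density by the Welch method —
   10 Hann-windowed sub-frames with 50% overlap, so the sub-frame length
   is $\lfloor L/5.5 \rfloor$ samples (160 samples for the 882-sample
   frame, a bin width of 275.625 Hz) — and normalise it to unit sum;
4. accumulate the normalised PSD from low to high frequency and report
   the centre frequency of the first bin where the cumulative power
   reaches 0.95.

This cumulative-power criterion replaces the arbitrary noise-floor
threshold of spectrogram-based readings with a quantile of the measured
spectrum itself. The Welch average (rather than a single periodogram) is
used for its variance reduction; the tests verify it against an
explicit-DFT brute force to 1e-9 relative error.

**Peak amplitude** is $20\log_{10}(\max|x|)$ with $x$ in integer
quantization units, i.e. decibels re 1 LSB, computed on the raw
(unfiltered) segment. The reference is a deliberate choice: no absolute
calibration (Pa) is available from a taped microphone chain, and the
16-bit full-scale ceiling of $20\log_{10}(32767) = 90.31$ dB is the only
common reference that tightly bounds reported neonatal peak amplitudes
just below 90 dB. The bit depth is configurable; the WAV reader refuses
float encodings precisely so this reference stays well defined.

**Peak power** is the largest per-frame signal power,
$10\log_{10}\max_f \overline{x_f^2}$, in dB re 1 LSB². Power, being a
short-time average of the squared amplitude, tracks perceived loudness
better than the instantaneous maximum and resists impulse-like
disturbance peaks. Saturated samples would bias it upward, so samples at
or above the clip threshold (default: full scale) are removed from both
the frame energy and the effective frame duration — a censored mean
square. Frames retaining under half their samples are discarded; if no
frame survives, the feature is reported missing with a reason code.

### Numerical choices

* **Sample windows** are half-open, `[round(start*fs), round(end*fs))`,
  with round-half-up, so adjacent annotations tile a recording exactly
  and segment length is pure index arithmetic.
* **Framing** drops a trailing partial frame; segments shorter than one
  frame are rejected as unanalysable rather than zero-padded, because
  padding biases power estimates downward.
* **Filtering** is causal (forward-only), the plain reading of a
  "fourth-order" filter; a zero-phase forward–backward variant is
  available via `filter_spec(zero_phase = TRUE)` and documented as having
  the squared (8th-order) magnitude response.
* **Peak power is computed on the raw segment by default.** Clip
  exclusion is only well defined before filtering: an IIR filter smears a
  saturated sample's energy into neighbouring retained samples, which
  both contaminates the censored estimate and breaks the closed-form
  sine check. `on_filtered = TRUE` applies the high-pass first, carrying
  clip positions through, for users who want the power measured in the
  same band as the peak frequency.
* **The 0.95 crossing** is the smallest bin whose cumulative power
  reaches the threshold (inclusive), reported as that bin's centre
  frequency — deterministic and honest about grid resolution. Whether
  the CDF should be built from the maximum-energy frame alone or pooled
  across frames is not fully determined by the published description;
  both are implemented (`mode = "max_energy_frame"` is the default,
  with `"pooled"` and `"per_frame_max"` as alternatives).
* **Degenerate inputs** (all-zero segments, fully clipped frames,
  constant samples) raise typed conditions; `extract_profile()` converts
  them to `NA` features with reason codes so cohort summaries can use
  available-case denominators.

## Perceptual schema and the coordination rule

The rating inventory is closed: nine breath-sound parameters rated pre-
and post-swallow (normal breathing, wet breathing, rattly chest,
grunting, crackles, stridor, wheeze, throat clearing, coughing) and seven
during-swallow sound parameters (crisp/clear, quick, loud, and the
canonical sequence IDS–BTS–FDS–GRS). Ratings are nominal
(`yes`/`no`/`cannot_be_determined`) over the whole 2-minute observation:
a parameter is *present* if demonstrated on at least one swallow, and a
present during-swallow sound is *consistent* only when heard in strictly
more than 80% of identified swallows — the 80% boundary itself is not
consistent (`presence_from_swallows()`).

`classify_coordination()` encodes the clinical rule:

* **uncoordinated** if (BTS present AND normal post-swallow breathing
  absent) OR (GRS present AND at least one adventitious post-swallow
  sound: wet breathing, rattly chest, cough, wheeze, crackles, throat
  clearing, stridor);
* otherwise **coordinated** if BTS present AND (normal post-swallow
  breathing present OR the nine pre- and post-swallow breath-sound
  ratings are identical);
* otherwise **undetermined**, with a reason.

Two genuinely open readings were settled as follows. The "and/or" in the
uncoordinated definition is parsed as two independent sufficient
conditions — the most permissive reading consistent with the prior CA
literature the rule descends from. And when both rules fire (a file can
show normal breathing after one swallow and adventitious sounds after
another), uncoordinated takes precedence: the clinically conservative
call. Exhaustive enumeration over the post-swallow rating hypercube
verifies the classifier is total on determined ratings.

Two-rater workflows mirror clinical practice: `consensus_profile()`
passes agreements through and *requires* an explicit resolution for every
disagreement, erroring with the list of unresolved parameters otherwise.
Cohort presence tables use available-case denominators
(`cannot_be_determined` excluded) and round percentages half-up to one
decimal, the convention of the published tables they mirror.

## Agreement statistics

Per parameter, ratings are tabulated over the `{yes, no}` categories with
`cannot_be_determined` pairs excluded pairwise. The package reports
percent agreement $p_o$, Cohen's $\kappa = (p_o - p_e)/(1 - p_e)$, and
PABAK $= (k p_o - 1)/(k - 1)$ — the prevalence- and bias-adjusted kappa,
which is immune to the skewed marginals common in this setting (several
parameters are present in nearly every neonate, which drags $\kappa$
down at high observed agreement). When both raters are constant on the
same category, $\kappa$ is undefined and returned as a flagged `NA`.

The conventional interpretation bands overlap at 0.80 and leave
(0.20, 0.21) unassigned as printed; `interpret_agreement()` uses the
closest total partition: excellent $[0.80, 1]$, substantial
$[0.61, 0.80)$, moderate $[0.41, 0.61)$, fair $[0.21, 0.41)$,
slight-to-poor below 0.21.

## Cohort statistics

Descriptives use the $n-1$ standard deviation and type-7
(linear-interpolation) quantiles for the IQR — the published tables
cannot adjudicate the quantile convention, so the common default is
used and documented. Normality is gated by Shapiro–Wilk (delegated to
`stats::shapiro.test`); Pearson correlations carry Fisher-z confidence
intervals, $\tanh(\operatorname{atanh} r \pm z_{(1+\gamma)/2}/\sqrt{n-3})$,
and Spearman's rho is the mid-rank Pearson correlation.

`sample_size_correlation()` implements
$n = \lceil ((z_{1-\alpha/2} + z_{\text{power}})/\operatorname{atanh}\rho)^2 + 3 \rceil$.
A planning statement of "difference ≥ 0.31" between acoustic variables is
interpreted as a correlation effect size, because this formula reproduces
the planned cohort of 80 neonates exactly at $\rho = 0.31$,
$\alpha = 0.05$, power 0.80. Note the published 95% CI for $r = 0.24$ at
$n = 80$ is (0.03, 0.45) while the Fisher-z closed form gives
(0.021, 0.437); the original CI method is unknown, and the package makes
no attempt to force agreement.

## What the synthetic data emulate — and what they do not

The generator exists so that every stage has inputs with analytic ground
truth. Its defaults are the reference cohort's conditions:

* `synth_swallow()`: tonal burst(s) plus white Gaussian noise, quantized
  to integer PCM. Defaults: 0.85 s duration, a single tone at 1678.3 Hz,
  peak amplitude 20,000 LSB, noise at 20 dB re 1 LSB. The 95%
  cumulative-power target, true maximum amplitude and tonal power are
  returned with the signal.
* `synth_session()`: a 120 s background-noise recording with
  non-overlapping bursts whose durations and frequencies are truncated
  normals at the cohort set-points (0.85 ± 0.31 s; 1678.3 ± 413.5 Hz),
  burst edges snapped to the sample grid so the emitted annotation table
  cuts them exactly.
* `synth_rating_pair()`: rater A is Bernoulli at the configured
  prevalence; rater B matches A with the configured agreement
  probability, independently per parameter.
* `synth_cohort()`: per-parameter prevalences default to the reference
  cohort's presence rates; the coordination class is always obtained by
  running the classifier on the sampled ratings, never drawn directly.
  The comorbidity count is Poisson with mean 2.5 — the reference cohort
  lists twelve common conditions whose prevalences sum to roughly 2.4
  expected conditions per neonate. The count is coupled to the peak
  amplitude (normal margin, 89.67 ± 1.1 dB) through a Gaussian copula
  whose latent correlation is calibrated by quadrature so the pair's
  Pearson correlation equals the target (default 0.24) exactly in
  expectation. Peak power is the amplitude minus a positive truncated
  normal gap, so the mean-square ≤ max-square ordering holds row-wise.

Determinism: every generator derives an independent substream from its
`seed`, so identical specs give bit-identical outputs and the audio,
rating and cohort fixtures can be regenerated independently.

These fixtures are deliberately *unrealistic* in ways that matter for
interpretation: swallow bursts are stationary tones, not the broadband
transient click-and-flush structure of real bolus transit; there is no
suck–swallow–breath rhythm, no breath sounds between swallows, no
microphone contact noise; rating tables have independent parameters,
whereas real adventitious sounds co-occur. Passing tests therefore
demonstrate that the *computations* are correct on signals with known
truth — not that the pipeline's clinical reference values generalise, and
not that the acoustic cohort means of any real population are recovered.

## Problem sizes used in the test suite

The statistical checks run at sizes chosen to keep Monte Carlo error
comfortably inside their tolerances: 1,000 synthetic cohorts of n = 80
for correlation recovery (tolerance 0.02 on the mean), 2,000 replicates
for 95% CI coverage (tolerance 1.5 points), 10,000 profiles for
prevalence reproduction (tolerance 1 point), 200 seeds for the
prevalence-skew PABAK > kappa property, and exhaustive enumeration for
the classifier hypercube and the 2×2 kappa/PABAK identities.

## Known limitations

* Swallow boundaries must be supplied; there is no detector.
* The decibel reference (1 LSB) is an inference from the reported
  amplitude scale, not a stated convention of the source instrumentation.
* Only integer PCM WAV (8/16-bit) is read; float audio is rejected by
  design rather than rescaled.
* Agreement statistics cover two raters; weighted or multi-rater
  coefficients (Fleiss) are out of scope.
* The published per-neonate joint rating patterns are not available, so
  the coordination prevalences (81.3% / 18.8%) are reproducible only as
  percent computations from the published counts, not re-derivable
  through the classifier from raw ratings.
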