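---
title: "Methods: sleep-stage suppression, oscillatory events, and affective responsivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep-stage suppression, oscillatory events, and affective responsivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnaffect)
```

## The analysis this package implements

`somnaffect` implements the offline analysis of a selective sleep-stage
suppression experiment: participants are randomized to a night in which
either REM sleep or slow-wave sleep (SWS) is suppressed by forced
awakenings, and physiological (skin conductance) and subjective responses
to a social stressor, plus declarative memory recall, are measured the
evening before, the morning after, and several days later. The pipeline
covers sleep architecture summaries, EEG preprocessing, fast-spindle and
slow-oscillation (SO) detection, SO-spindle phase coupling, accumulated
spectral "energy" per frequency band, the session skin-conductance response
(SCR) statistic, behavioral scoring, and linear-mixed-model inference with
Bonferroni follow-up families and a sensitivity power analysis.

Because raw recordings of such experiments are typically shareable only on
request, the package ships a first-class synthetic-data module that
generates suppression cohorts with known ground truth, so every downstream
stage is testable without any download.

## Sleep architecture

A hypnogram is a sequence of 30-s stage labels (W, N1, N2, SWS, REM) with
arousal/artifact annotations. Stage durations are epoch counts times 0.5
min; total sleep time is N1+N2+SWS+REM; WASO is wake after the first sleep
epoch.

Episode segmentation follows the rule that a REM episode starts with a REM
epoch and ends with the first run of at least four continuous minutes
(8 epochs) of wake or NREM; an SWS episode ends at the first REM epoch or
four continuous minutes of W/N1/N2. Interior gaps shorter than the
terminating run stay inside the episode, and episode boundaries are
half-open `[start, end)` with the end placed at the last target-stage
epoch. Fragmentation is the time inside a stage's episodes spent in other
stages or annotated arousals, divided by total stage time (so it can exceed
100%). Two conventions had to be fixed where the verbal rule is ambiguous:
the denominator is the night's total stage time (not per-episode time), and
any instant is counted at most once, so an arousal annotated on top of an
intra-episode wake epoch is not double-counted. The single-counting choice
is conservative; a sensitivity check simply adds the overlap back.

## EEG preprocessing

Broadband filtering is a zero-phase Hamming windowed-sinc FIR band-pass
with −6 dB points at 0.2 and 35 Hz; the transition bands (0.2 Hz wide)
reach 0.1 and 35.1 Hz, which reconciles the passband-edge and stop-edge
descriptions of such filters. Zero phase is obtained by centred convolution
with the odd-length symmetric kernel (reflection padding), not by
forward–backward filtering, so the magnitude response is that of the kernel
itself. Channels are re-referenced to the mastoid average. Clean-epoch
selection keeps epochs of the target stage whose artifact overlap is at
most 8 s (exclusive, a literal reading of ">8 s") and whose target-channel
impedance is at most 30 kOhm; one impedance value per channel per recording
is assumed.

## Event detection

**Individual sigma peak.** The participant's fast-spindle frequency is the
highest-frequency qualifying local maximum of the linearly detrended PSD
curve in 9–16 Hz; qualification is by topographic prominence (10% of the
detrended range by default). When no peak qualifies the caller may fall
back to the cohort mean of 13.47 Hz.

**Spindles.** The signal is band-pass filtered to the individual peak ±2 Hz
with an equiripple FIR, rectified, and smoothed with a 100-ms moving
average. With M the mean of this envelope over all analyzed epochs of the
stage/channel, an event needs a peak ≥ 5M, must stay ≥ 2M for at least
250 ms on both sides of the peak, and may last at most 3 s. Candidates
closer than 250 ms are merged first (one burst should not be counted
twice), and events overlapping artifact annotations are discarded. The
mean-amplitude estimator ("mean channel amplitude") is not defined in
detail by the verbal description; it is implemented as the mean of the
smoothed rectified band-filtered signal over the analyzed clean epochs, and
the 5M peak criterion is applied to the smoothed envelope (configurable).
All thresholds are signal-relative, so detections are invariant to
rescaling — a property the tests assert.

**Slow oscillations.** On the ≤3.5 Hz low-passed signal, candidate cycles
run between consecutive positive-to-negative zero crossings and must last
0.8–5 s (0.2–1.25 Hz). Relative thresholds — negative peak below 0.9× the
mean negative peak and peak-to-peak amplitude above 0.9× the mean — are
computed over the candidates after artifact exclusion, separately per
channel and stage.

Filtering inside the detectors is applied per contiguous run of kept
epochs. This is numerically equivalent for all interior samples (the epoch
mask would cut candidate segments at run edges anyway) and keeps a full
night tractable on one CPU.

## SO–spindle coupling

A spindle is SO-coupled when its amplitude peak lies inside an SO cycle
(half-open interval). The SO phase at the spindle peak is the angle of the
Hilbert analytic representation of the 0.2–1.25 Hz filtered signal. The
phase origin is not fixed by convention in the field; here 0 rad is the
positive peak of the filtered wave, ±π the trough, with phase increasing in
time. This choice shifts mean phases but, by rotation equivariance, leaves
resultant vector lengths (RVL) and optimally-coupled (OC) counts untouched.
The circular mean is the argument and the RVL the modulus of the mean unit
vector; OC-spindles are coupled spindles within 0.5 rad (inclusive,
shorter-arc) of the individual mean phase. Per-channel summaries for the
central electrodes are averaged afterwards — averaging summaries, not
pooling phases. Empty inputs give zero counts and a flagged mean rather
than an error, keeping cohort tables rectangular.

## Accumulated spectral energy

Per epoch, Welch PSD is computed with 1024-sample windows (4 s at 256 Hz;
0.25 Hz native bins) and 50% overlap, averaged into 1-Hz bins over
(0, 30] Hz, and averaged between F3 and F4. A "4 ms" window length that
sometimes appears in descriptions of this setting is arithmetically
impossible at 256 Hz and is treated as 4 s. Bin boundaries (4, 8, 12, 16,
22 Hz) belong to the lower band, matching an inclusive "≤4 Hz" SO-delta
band.

The energy measure z-scores every (epoch, bin) value against the pooled
mean and SD of the stage across all bins, epochs, and participants, shifts
the values so the global minimum is 1, and sums over each participant's
epochs — an intentionally duration-weighted quantity: more epochs mean more
accumulated energy. Bin values are log10-transformed before z-scoring
(spectral power is approximately log-normal, and the EEGLAB function this
emulates returns dB); without the transform the pooled moments are
dominated by the delta bins. Pooling treats epochs as observations; a
participant-mean-first alternative is exposed as a switch since the unit of
observation is ambiguous in verbal descriptions.

Amplitude confounds (skull/skin conductance affect all bins
multiplicatively) are removed in two OLS stages: the participant's mean
0–30 Hz PSD is regressed on the condition indicator and stage duration,
and each bin-wise energy sum is then regressed on that residual. Adjusted
values are centered residuals — orthogonal to the amplitude residual by
construction, with cohort mean ~0.

## Skin conductance

Baseline SCL is the trace mean over `[baseline_start + 120 s,
playback_start − 20 s)`; playback SCL the mean over the playback interval.
The session statistic is `scr0 = sqrt(100 × playback/baseline)`: the ratio
is put on a percent scale before the square root so the statistic lands on
the published magnitude (day means ≈ 12.7–15.5; equal playback and
baseline give 10), and the square root tames the ratio's skewness.
"Controlling for baseline SCL" is implemented as per-day OLS
residualization with the day grand mean added back; using baseline as a
model covariate instead is available by option. Both the raw and the
controlled statistic are kept; outlier exclusion is left to the inference
stage so raw values stay available.

## Behavior

The embarrassment composite is the mean of the two 0–4 ratings. Recall
scoring maps manually assigned categories to 1 / 0.5 / 0 points (the
linguistic synonym judgment is an input, not computed). The 60 stimulus
items are split into two 30-item subsets matched on the normative ease
dimension by sorting and alternating pair assignment, which cancels the
mean difference to first order; a Welch t-test documents the balance. On
ease norms drawn from the published range (2.4–5.3) the matched subsets
differ by under 0.05 points, comparable to the published 3.88 vs 3.84.

## Inference

Observations are outliers when they deviate ≥2.5 SD from the sample mean in
both their static value and their change score, or in a fitted-vs-residual
check; flags are logged, never silently dropped.

The main models are REML linear mixed models with a random participant
intercept, day as the three-level repeated factor, and a between-subject
predictor crossed with day. Three residual covariance treatments are
available: homoscedastic random-intercept (`RI`, fitted with `lmerTest`,
type-III F tests with Satterthwaite denominator degrees of freedom),
heterogeneous compound symmetry (`CSH`, `nlme`), and a general symmetric
structure (`UN`). A first-order factor-analytic request (`FA1`) is fitted
as the general symmetric matrix: with three repeated measures the FA1
parameterization (three loadings plus three uniquenesses) has the same
parameter count as the unstructured matrix and is not separately
identified, so the explicit parameterization is fitted and the requested
label recorded. AICc is reported for structure comparison. The `nlme` fits
report marginal F tests with containment degrees of freedom; the
Satterthwaite route is available through `RI` — an approximation to the
original software's fractional denominators, documented as such.

Follow-ups are paired t tests between days, between-condition regressions
on change scores, and Pearson correlations, each Bonferroni-corrected
within its declared family (six PSD bands; two spindle tests; three or six
repeated contrasts; three or two regressions), with nonparametric
equivalents (Friedman, Mann–Whitney U, Spearman) sharing the same
families. A fully tied Friedman layout (every participant constant across
days) is reported as statistic 0, p 1, since the tie correction of the
standard test is degenerate there.

**Sensitivity analysis.** The minimum detectable Cohen's f for the 2
(between) × 3 (within) mixed design at N = 29, α = 0.05, power = 0.8 is
found by inverting noncentral-F power at the design's degrees of freedom
(interaction/within: df 2 and 54; between: df 1 and 27). Two effect-size
conventions are implemented and both are always reported: the SPSS
partial-eta-squared convention, in which the noncentrality is `f² × error
df` (this is G*Power's "as in SPSS" option), giving 0.43 and 0.56 for the
two factors; and the G*Power default, in which the repeated-measures
correlation ρ (default 0.5) enters explicitly, giving 0.24 and 0.44. The
conventions answer the same question on different scales, which is why the
summary never reports one without the other.

```{r sensitivity}
sensitivity_summary(N = 29, alpha = 0.05, power = 0.8)
```

## The synthetic cohort: what it emulates, and what it does not

**Hypnogram.** A discrete-time Markov chain over the five stages at 30-s
resolution. Mean dwell times (epochs: W 7, N1 2, N2 10, SWS 25, REM 28)
and the exit kernel were calibrated so that the two suppressed conditions
land near the published group architecture (total sleep ≈ 6 h, suppressed
stage ≈ half the intact condition's duration, 10–14 forced awakenings).
On entering the suppressed stage, a forced awakening ends the bout after a
geometric dwell of mean 7 epochs (3.5 min) — the dwell is a free parameter
because awakening latencies are not published, and a much shorter dwell
cannot reproduce both the suppressed-stage durations (~43/48 min) and the
awakening counts (~10/13) at once. After an awakening the sleeper rebounds
toward the suppressed stage with probability 0.55 within a 14-epoch
window, passing through intermediate stages quickly; this reproduces the
fragmentation signature of repeated suppression (suppressed-stage
fragmentation far above the intact condition's). Awakening intensity steps
1–4 are drawn with condition-specific probabilities matching the published
mean strengths (1.9 / 1.6).

**EEG.** A 1/f colored-noise background (SD 15 µV, band-limited above
0.2 Hz to mirror the high-pass floor of preprocessed sleep EEG), plus: SO
cycles planted in SWS (6/min; sparsely in N2) with ~150 µV peak-to-peak;
spindle bursts in N2/SWS (5 and 4 per minute) at a participant-specific
center frequency drawn from N(13.47, 0.56²) Hz with 40 µV peak amplitude —
about 11× the in-band background rectified mean, chosen so plants clear the
5M detection threshold with margin (a plant exactly at 5× the background
mean sits on its own detection boundary, because the detector's M includes
the events); a fraction of spindles (22% in SWS, 15% in N2) peak-locked to
planted SO cycles at a von Mises phase (µ = 0, the up state; κ = 5); and a
multiplicative theta gain in REM epochs (per-participant log-normal, mean
1.4). The planted SO cycles are the SWS slow-wave activity: an optional
`sws_delta_gain` can add unlabelled background delta waves, but the default
keeps the ground-truth ledger exhaustive, since background delta cycles
would legitimately satisfy the detector's relative thresholds while
counting as false against the ledger. Events are identical across EEG
channels; mastoids carry 2 µV noise.

The generator does not attempt realistic EOG/EMG, microarousal morphology,
ECG artifacts, topographic gradients, or within-night nonstationarity
beyond the stage-conditioned content. Passing recovery tests therefore
shows the detectors implement their rules correctly and recover events of
published amplitude over a plausible background — not that they would
perform identically on real recordings.

**SCR and behavior.** The overnight (Day 1→2) percent SCR change is a
linear function of a latent "theta drive" (REM minutes × theta gain),
calibrated so the condition means land near 20.1% (SWS suppressed) vs 6.1%
(REM suppressed) and the drive–change association is strongly positive;
Day 2→5 changes are condition-mean draws (−15.9 / −20.5). Day-1 SCR is
N(13.75, 2²). SCL traces realize these targets as multiplicative playback
elevations over a log-normal tonic level, with smooth drift and measurement
noise. Behavioral trajectories use the published-scale day × sex means for
the embarrassment composite and recall percentage, with clipping to the
legal ranges; rating items are kept continuous by default so that zero
noise reproduces configured means exactly, with integer rounding available.

**Fidelity levels.** `simulate_cohort(level = "signals")` synthesizes raw
SCL traces and frontal EEG and runs the trace and spectral pipelines on
them; it exercises the signal path end to end and is used at small scale.
`level = "measures"` draws the session measures directly from the same
calibrated effect model, which is what makes 100-seed direction checks and
1,000-cohort type-I simulations tractable on one CPU: a single raw-EEG
cohort of 120 nights costs about a minute of synthesis and spectral
analysis alone, so the many-seed simulations would take hours at signal
level while estimating exactly the quantities the measures level draws
directly. Both levels share one seed-expansion scheme (a 31-bit hash of the
participant index), so cohorts are bit-reproducible and participants can be
regenerated independently.

**Problem sizes used by the test suite.** Planted-event recovery runs 20
full nights on one central channel; the direction check runs 100 cohorts of
60 participants per condition at measures level; the type-I simulation runs
1,000 cohorts of 15 + 14; oracle checks use 60-s signals. These sizes give
the Monte-Carlo estimates comfortable standard errors while keeping the
default suite in the minutes range.

## Numerical choices and degenerate inputs

* FFT lengths are padded to 5-smooth sizes (R's mixed-radix FFT is several
  times faster there than at large powers of two).
* The equiripple design falls back to the windowed-sinc kernel if the
  exchange algorithm fails to converge at the requested order.
* Zero-variance signals yield no events rather than division errors; empty
  coupled-spindle sets yield flagged missing means; a zero pooled SD in the
  energy z-score (constant input) yields energies equal to epoch counts,
  with a warning.
* The outlier screen refuses zero-variance inputs explicitly.
* `sensitivity_min_effect` returns 0 when the test's size already exceeds
  the target power (α → 1 limit).

## Known limitations

* The FA1 covariance structure is fitted as the general symmetric matrix
  (see above); containment rather than Satterthwaite degrees of freedom are
  reported for the `nlme`-fitted structures.
* The synthetic background is stationary within stages; detector
  performance on real, nonstationary EEG will differ, particularly for the
  relative-threshold SO detector, whose candidate set in N2 is dominated by
  background delta cycles exactly as it is in real data.
* The energy pipeline's z-score population is stage-wise; whether N2 epochs
  belonged to the original pooled population is not decidable from verbal
  descriptions, and N2 energies are emitted but not used by the inference
  stage.
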