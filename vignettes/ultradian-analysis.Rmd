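---
title: "Detecting and quantifying multiple ultradian rhythms in continuous physiological records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying multiple ultradian rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultrarhythm)
```

## The problem

Small mammals kept under constant conditions do not metabolise at a steady
rate. Continuous indirect calorimetry at one-minute resolution shows the
metabolic rate (MR) of a hamster-sized rodent rising and falling in bursts
many times a day, with core body temperature (T_b) and locomotor activity
moving along. These ultradian rhythms (URs; periods shorter than a day, here
0.3–6 h) are not one oscillation but several superimposed ones: a small
fluctuation of roughly +20% of resting metabolic rate (RMR) at a period near
1 h, a medium one of roughly +50% near 1.5–2.2 h, and large bursts exceeding
+100% of RMR every 2–5 h that coincide with activity, feeding and arousal.
The classes drift from day to day, attenuate during the circadian resting
phase, and carry a measurable share of the daily energy budget.

`ultrarhythm` implements the complete analysis chain for such records:

1. period detection in the ultradian band with a Morlet continuous wavelet
   transform (CWT) and shuffle-surrogate significance testing;
2. assignment of the detected periods to the small/medium/large classes and
   extraction of individual bursts with period-adapted search windows;
3. partition of daily energy expenditure (DEE) into RMR and ultradian
   metabolism via a lower-envelope estimate of RMR;
4. day-by-day period synchrony across classes and physiological variables;
5. an infrared-thermography activity index and nest-occupancy score;
6. a synthetic multichannel generator with known ground truth against which
   all of the above is validated.

No animal recordings ship with the package; every empirical statement below
is computed from the synthetic generator or from published group means.

## The wavelet periodogram

The analytic Morlet wavelet — a complex exponential tapered by a Gaussian,
with centre frequency $\omega_0$ — is convolved with the mean- and
trend-removed series across a log-spaced grid of scales $s$. Scale converts
to Fourier period by $P = s \cdot 4\pi/(\omega_0 + \sqrt{2+\omega_0^2})$.
Power is the squared modulus of the transform; the *periodogram* is its time
average per period.

Parameter choices, all configurable:

* $\omega_0 = 6$, the standard choice in chronobiological practice; it
  trades period resolution (relative bandwidth about $1/6$) against time
  resolution.
* `dj = 1/50` octave: 50 period-grid steps per octave, amply finer than the
  wavelet bandwidth, so grid quantisation never limits period estimates.
* Zero padding to the next power of two for the FFT convolution; the cone
  of influence (COI, the region where edge effects reach a given scale) is
  recorded per sample. COI-affected samples are *included* in the
  periodogram: the analysis windows are full 24-h days and all days are
  treated alike, so edge attenuation is a common factor across days.
  Sensitivity: excluding the COI region changes periodogram peak locations
  by well under one bandwidth, because peaks are time-averages dominated by
  the interior of the day.
* Power is divided by scale by default (`rectify = TRUE`, the standard
  spectral bias correction for CWT periodograms). Raw $|W|^2$ weights an
  oscillation of fixed amplitude proportionally to its period, which makes
  the short-period small class structurally invisible next to the large
  class; the rectified periodogram puts equal-amplitude oscillations on
  comparable footing. `rectify = FALSE` restores the raw convention.

## Surrogate significance

Observed periodogram values are compared against a null built by randomly
permuting the original samples — destroying all temporal structure while
keeping the marginal distribution, so the result is insensitive to how the
data are distributed. With $n$ surrogates, the per-period threshold is the
$m$-th largest surrogate periodogram value with $m = \lfloor \alpha (n+1)
\rfloor$: exceeding it is a Monte-Carlo test of exact level $m/(n+1)$.
Choosing $n$ such that $\alpha(n+1)$ is an integer (59 or 99 at
$\alpha = 0.05$) makes the realized level exactly $\alpha$; with the
conventional $n = 150$ at $\alpha = 0.05$ the realized level is
$7/151 \approx 0.046$, slightly conservative. Thresholds are seeded and
reproducible, and decrease monotonically as $\alpha$ grows.

Calibration is a testable property: on pure white noise the fraction of
period bins flagged at $\alpha = 0.05$ must match the nominal level.
Neighbouring period bins share most of their information (the grid is 8
times finer than the wavelet bandwidth), so the *replicate day*, not the
bin, is the independent sampling unit; the test suite checks the pooled
flagged fraction over 50 replicate days against the replicate-level
binomial interval around 0.05.

## Peak extraction and class assignment

Periodogram peaks are local maxima, filtered only by a minimal numeric
ripple criterion (prominence at least 0.5% of the maximum average power)
and a minimum separation of 12 grid steps (about a quarter octave, the
wavelet's own resolution limit — candidate maxima closer than this are one
peak, not two). Deliberately, there is *no* strong prominence floor: the
three amplitude classes span a six-fold amplitude range, i.e. a ~36-fold
power range, and any prominence floor expressed as a fraction of the
maximum would silently delete the smallest class. The operative filter is
the surrogate significance gate (default $\alpha = 0.01$ for periodogram
peaks, 0.05 for the time-resolved mask), mirroring how peak pickers with
default parameters plus a significance criterion are used in practice.

Up to three significant peaks, strongest first, are assigned to classes.
Three peaks are ranked purely by ascending period. With fewer peaks,
fallback bands are used (small [0.3, 1.25) h, medium [1.25, 2.4) h, large
[2.4, 6] h); two peaks falling in one band are spread over adjacent classes
preserving order, so a compressed pair like 1.33 h and 1.91 h is read as
medium and large rather than as two mediums.

## Burst extraction

Given a class period $P$, a sliding window of width $P$ marks samples that
are maxima of their window; candidates closer than $P/2$ to a stronger peak
are duplicates of it, and peaks in the first half-window of the day (whose
preceding minimum cannot be evaluated) are dropped. The preceding minimum is
searched within one period before each peak; amplitude is peak minus
minimum, rise time their separation. On noisy records an optional short
running average (`smooth = 5`) tempers the outward bias of window extrema.

Two exclusion rules handle superimposition, both motivated by the fact that
small and medium bursts also ride on top of large bursts:

* a small/medium burst whose minimum lies more than a quarter of the
  large-class amplitude above the RMR envelope did not start near baseline;
* a small/medium peak within half its class period of a detected
  large-class peak *is* the large peak, found again by a narrower window.

Both are flagged `superimposed` and excluded from baseline amplitude
statistics (they remain in the table). Burst peaks are phase-labelled
(resting = light phase, default 08:00–16:00 half-open) for the circadian
attenuation comparison, and T_b / activity co-amplitudes are read over the
same rise window, T_b with the configured thermal lag (default 10 min).

## Energy partition

Heat production converts oxygen consumption at the measured respiratory
exchange ratio (RER):
$\mathrm{HP[mW]} = (4.44 + 1.43\,\mathrm{RER}) \cdot \dot V O_2\,[\mathrm{mL\,O_2\,h^{-1}}]$,
linear in $\dot VO_2$ and affine in RER. DEE is the time integral of HP;
by construction DEE in kJ equals mean HP in mW times 86400/10^6.

RMR is tracked through the minima between bursts: the MR series is reduced
to 6-min averages, a rolling minimum with window equal to the day's
large-class period (fallback 3 h — wide enough to bridge every large burst,
narrow enough not to flatten slow baseline changes) selects anchor minima,
and the envelope interpolates linearly between anchors. Two numerical
details matter: the rolling window keeps its full width at the day edges by
shifting inward (a shrinking window systematically inflates edge anchors),
and any bin undercut by the interpolation joins the anchor set, so the
envelope never exceeds the smoothed series. An alternative `method =
"minima"` averages the anchor minima only; on synthetic data the two agree
closely and the envelope mode is the default because it weights time
uniformly.

The ultradian component is MR minus the envelope, floored at zero (noise
can dip below the envelope); the resting component is the remainder, so
mean MR and DEE decompose *exactly* — closure is an identity, not an
approximation. Known limitation: when all three oscillations overlap
continuously for longer than one large-class period, the true baseline is
unobservable by any minima-tracking method and the envelope rides a few
percent high; across replicate synthetic days the median recovery error of
the injected ultradian fraction stays below 2%, with occasional tail days
near 3%.

## Synchrony analysis

Per-day class periods form a day × (class × variable) time-course. Pearson
correlation (the relationship examined is linear association of period
time-courses; Spearman is a configuration away) is computed pairwise —
class against class within each variable, and variable against variable
within each class — on pairwise-complete days, requiring at least five
complete pairs; degenerate or too-short series are reported `NA`, never
imputed. The summary counts significant comparisons at raw two-sided
p < 0.05 with no multiplicity adjustment, matching how such counts are
conventionally reported; the percentage is exact arithmetic rendered at one
decimal.

## Thermovision activity

From 1-s surface-temperature traces (one area tracking the animal, two
fixed cage-floor areas), the activity index is the sample SD of the animal
trace within each minute — body movements change the visible surface and
hence the apparent temperature. Sample (n−1) SD is used; at 60 samples the
distinction from the population SD is a 0.8% scale factor. A minute counts
as outside-nest when either cage trace exceeds 30 °C for at least 30 of its
60 samples (the warm body heats the floor it sits on); the within-minute
majority rule is a robustness choice against isolated hot pixels, and the
count is monotone non-increasing in the threshold. Motionless rest would
give sub-0.5 °C fluctuation; this figure is documented as a heuristic
reference, not enforced as a hard rule.

## The synthetic generator

`synth_config()` / `generate_day()` simulate the statistical structure the
analysis assumes, with every injected quantity recorded as ground truth:

* **Baseline and classes.** RMR 1.0 mL O2 min⁻¹; class periods 1.0 / 2.0 /
  3.5 h; burst peak heights 0.2 / 0.5 / 1.2 × RMR. Periods and amplitudes
  are the documented study conditions; everything below is a modelling
  choice of this package.
* **Burst shape.** Asymmetric half-cosine pulses (fast rise, slower decay),
  rise 13 / 25 / 40 min and decay 22 / 45 / 90 min per class. The
  small-class rise matches observed rise times near 13 min; the large-class
  excursion spans roughly two hours. The resulting duty cycles (0.55–0.62)
  make each train quasi-sinusoidal, which is what the smooth, continuous
  oscillations in real records look like and what keeps harmonic leakage of
  the strong classes below the fundamental of the weak one.
* **Timing.** Events sit on an underlying oscillator's phase grid (random
  phase per day) with independent Gaussian timing jitter of SD 0.05 ×
  period. Spacings then vary visibly (SD ≈ 7% of the period) but timing
  errors do not accumulate across the day. A renewal model (jittering each
  spacing independently) was evaluated and rejected: accumulated phase
  diffusion broadens the per-day spectral lines and fills the band with a
  continuum that buries the small class — contradicting the empirical fact
  that per-day periodograms of real records resolve all three classes.
* **Circadian gating.** Burst heights ×0.6 during the light phase
  (08:00–16:00), i.e. 40% resting-phase attenuation.
* **Coupling.** Large bursts always drive activity and T_b; medium bursts
  drive activity with probability 0.79; small bursts couple to T_b with
  probability 0.32 and to activity with 0.56 — so roughly 68% of small
  bursts lack a T_b response and 44% lack an activity response, as a
  population property. T_b responds through a first-order low-pass with a
  10-min time constant (thermal inertia); RER dips from 0.96 towards 0.84
  along each large burst's envelope.
* **Day-to-day drift.** Log-periods follow a shared random walk (SD 0.06
  per day) plus per-class jitter (SD 0.03, tied to the drift parameter so
  zero drift means frozen periods). Classes therefore co-vary without being
  harmonics.
* **Noise.** Additive Gaussian per channel (MR 0.05 mL O2 min⁻¹, T_b
  0.05 °C, activity 0.5 counts, RER 0.01); activity is floored at zero and
  rounded to integer counts.

What the generator does *not* emulate: torpor episodes, ambient-temperature
dynamics, within-day period modulation, postural artefacts in the IR
traces, and sensor drift or recalibration gaps. Passing tests on synthetic
data therefore demonstrate correctness of the algorithms under the stated
statistical structure, not robustness to every pathology of real
recordings.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 5)
rec <- generate_day(cfg)
report <- run_day(rec$day, channels = "mr", n_shuffles = 150, seed = 5)
report
#> <ur_day_report> synthetic-1 day 1
#>   mr       periods [h]: small 1.02, medium 1.90, large 3.59
#>   DEE 44.09 kJ, ultradian fraction 33.8% of mean MR
rec$truth$periods_h
#> [1] 0.9931893 2.0388037 3.6542343
```

The detected periods sit within a few percent of the injected ones, and the
budget splits a 44 kJ day into roughly 29 kJ resting and 15 kJ ultradian
metabolism — the ultradian system carrying about a third of the daily
budget.

## Problem sizes and numerical conventions

Simulation-based checks in the test suite use 20 replicate days for period
recovery, 50 replicate days (59 surrogates each) for null calibration, and
8 noise-free days for energy-fraction recovery; these sizes give stable
medians while keeping a full run of the suite in the minutes range.
Ties in peak ordering break towards shorter periods; the light phase is
half-open `[08:00, 16:00)`; days run 00:00–24:00 on a 1-min grid with
exactly 1440 samples; envelope and burst windows are rounded to whole
minutes. Seeds enter through configuration objects or explicit arguments
only — no function consumes global RNG state without restoring it.
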