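---
title: "Methods: fibre characterization, validation screens, and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fibre characterization, validation screens, and the synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfiber)
```

`anfiber` analyses trial-based single-unit recordings from the auditory
nerve: spike trains (and optionally raw voltage traces) collected while
presenting tone bursts, clicks, silence, or complex sounds. This
vignette explains the models and conventions the package implements,
the tunable parameters that matter, what the synthetic fibre simulator
does and does not emulate, and the numerical choices made where a
convention had to be picked.

## Data model and conventions

An **experiment** is one animal: an ID, metadata (sex, age in months,
weight, ABR threshold in dB SPL, hardware identifiers, free-form
extras), and a list of **units** (single fibres). Each unit holds up to
one **recording** per protocol type: `BF` (frequency-response curve),
`RLF` (rate-level function), `CF` (frequency x level response field),
`PH` (phase locking), `CLICK`, `SR` (spontaneous rate), and the
complex-stimulus types `NOISE`, `SPS`, `CVC`.

Spike times are seconds from *trial start*; the stimulus onset is kept
separately in the recording settings, and every reported latency is
relative to stimulus onset. Silent trials carry `NA` for both stimulus
frequency and level. Age groups split at 12 and 36 months; both
boundary ages belong to the middle group (old is strictly above 36).

The portable container is versioned JSON mirroring this hierarchy.
Doubles are written with 17 significant digits — the smallest count
that round-trips IEEE-754 exactly — so `load_portable(save_portable(e))`
reproduces spike times bit-identically. Free-form subtrees (`extras`,
`analysis`) are canonically typed on reading: all numbers come back as
doubles, and the tokens `"NA"`, `"NaN"`, `"Inf"` are reserved for
missing/special numerics. Legacy and HDF5-based MATLAB experiment
containers load through a bundled Python bridge; unrecognized metadata
fields are preserved in `extras` rather than rejected.

## Spike detection

Raw traces are band-pass filtered at 300–3000 Hz with a Chebyshev
type-II filter of order 6 and 20 dB stopband attenuation, then a
trigger is applied and each contiguous supra-trigger excursion yields
one spike at the sample of its maximum.

Two conventions had to be fixed that the usual description of this
procedure leaves open:

* **Phase handling.** The filter is applied forward and backward
  (`signal::filtfilt`), i.e. zero-phase, so the stored spike time is
  the peak of the *unshifted* waveform. A causal application would
  delay every spike by the filter group delay (frequency dependent,
  several hundred microseconds here). Since detected spike times feed
  latency analyses, the unbiased choice is the right default; it is a
  deliberate decision, documented here, and a causal mode is not
  offered.
* **Polarity.** Detection triggers on positive excursions by default;
  a `polarity` flag inverts the trace for units with negative-going
  spikes.

Edges are handled by extending the trace with a reflected copy (about
one filter-settling length, at least three filter orders) before
filtering, which suppresses the start-up transient of the IIR filter.
Per-trial trigger overrides mirror the trial-by-trial adjustment an
experimenter performs offline; the effective trigger per trial is part
of the output.

Snippets for waveform review span −1.3 ms to +1.3 ms around the peak
(length `round(2.6 ms * fs) + 1` samples); spikes too close to a trace
edge are skipped and counted.

## Spike-rate analyses

**Tone-evoked rate**: spikes in the half-open window
`[onset, onset + duration)` divided by the stimulus duration, computed
per trial and then averaged (mean, SD) over the repetitions of each
unique frequency-level combination. Silent trials never enter these
condition averages.

**Spontaneous rate (SR)** is computed over the *total* trial duration
of silent trials, not the stimulus window. When a unit has several
possible sources, the preference is `SR` recording first (about 240 s
of silence), then `PH`, then `RLF`, then any tonal recording with
silent trials — always the source with the most accumulated silence.

A subtlety that matters for the threshold criteria below: the rate
criterion `T = mean SR + 1.2 * SD SR` uses the SD *across the silent
trials of the same recording*. That SD reflects the counting noise of
trials of that length, which is also the noise of the rates being
compared against `T`; substituting the much tighter SD of a long SR
recording makes the criterion fire on sub-threshold fluctuations. The
package therefore computes criteria from the recording's own silent
trials and uses the unit-level estimate only as a fallback.

## Thresholds, tuning, and phase locking

**RLF threshold**: the lowest level whose mean rate is *strictly*
higher than 15 spikes/s and strictly higher than `T`. Both
inequalities are strict; a rate exactly equal to the criterion does not
qualify, and `NaN` is returned when no level qualifies.

**Tuning curve / CF / Q10dB**: per stimulus frequency, the threshold is
the first level strictly above `T` (manual override available, e.g.
for zero-SR fibres). CF is the frequency of the minimum threshold;
ties resolve to the geometric mean of the tied frequencies. The 10-dB
bandwidth comes from linear interpolation of the threshold curve on a
log2-frequency axis, walking outward from the tip until each flank
crosses minimum + 10 dB; `Q10 = CF / bandwidth`, `NaN` whenever a
flank fails to cross inside the measured range (narrow grids, shallow
curves, or `NaN` gaps).

**Best frequency**: a smoothing spline is fitted to mean rate versus
log2 frequency and the peak of the fit on a 1000-point grid is the BF.
Smoothing is chosen by generalized cross-validation with a fixed
fallback (`spar = 0.5`) when GCV degenerates to interpolation; ties
resolve to the lowest frequency and boundary peaks are flagged. The
log-frequency axis was chosen because auditory tuning is approximately
symmetric on a log axis; the original description does not state the
axis or the smoothing parameter.

**Vector strength** for spikes in the stimulus-on window:
`vs = |sum_j exp(i 2 pi f t_j)| / N`. Significance uses
`p = exp(-N vs^2)`; with fewer than 50 pooled spikes the estimate is
considered invalid (`p = NaN`), and locking is significant when
`p < 0.001` (strict). Per level, spikes are pooled across all
repetitions before computing `vs`.

## Click latencies

All click latencies are relative to click onset.

* **Two-bin method**: a pooled PSTH at 0.05-ms bins over the whole
  trial; the baseline `B` is the highest *pre-onset* bin count (pooled
  counts, not rates); the latency is the centre of the first post-onset
  bin of the first pair of consecutive bins both strictly above `B`.
* **Poisson tail method**: post-onset spikes of all `R` repetitions are
  pooled and sorted; at the k-th spike (time `t_k` after onset) the
  probability `P_k = Pr[Poisson(lambda R t_k) >= k]` is the chance of
  seeing that many spikes from spontaneous activity alone
  (rate `lambda`). The latency is the first `t_k` with
  `P_k < 1e-6`. This operationalizes the one-line description of the
  Poisson-PDF method as a running tail probability; the exact original
  construction is not published in detail, so this reading is a
  documented interpretation. With `lambda = 0` any spike is
  significant and the latency is the first post-onset spike time.
* **First-spike latency (FSL)**: first post-onset spike per trial;
  trials without one are excluded and counted. Mean, median, SD,
  variance and IQR are reported; quantiles use the linear-interpolation
  rule (R type 7), which the IQR value depends on. With one
  contributing trial the central values are defined and the spread
  measures are `NaN`.

## PSTHs and complex stimuli

PSTHs pool the selected trials and convert counts to rates,
`rate = count / (n_trials * bin_width)`, so the conservation identity
`sum(rates) * bin_width * n_trials = total spikes` holds exactly; 5-ms
bins are the convention for complex-stimulus summaries, 0.05-ms bins
for click latencies. Level selection keeps trials within ±5 dB of the
target by default ("at or close to" a level), and the unit-level tone
PSTH pools BF, RLF and PH trials near the target level — the standard
view for judging a primary-like response shape.

For `NOISE`/`SPS`/`CVC` recordings, a trial is *included* when its
acquired duration matches the nominal trial duration; the included
count and indices are reported alongside the 5-ms PSTH.

## Single-unit validation screens

* **Refractoriness**: ISIs are computed within trials only — never
  across trial boundaries. Counts below 1 ms and below 0.6 ms (the
  absolute refractoriness of auditory-nerve fibres) are reported;
  "multiple" violations is read as ≥ 2 sub-0.6-ms intervals, which
  marks the unit as a likely multi-unit recording. One violation is
  reported but does not exclude.
* **Waveform / prepotential**: the median spike waveform with a
  pointwise 2.5–97.5 percentile band (an empirical band, chosen over a
  standard-error band because spike amplitude drifts within
  recordings). The prepotential score is the maximum absolute
  deflection 0.4–1.0 ms before the peak divided by a robust SD (MAD)
  of the earlier baseline; scores above 3 raise a flag. The original
  screen is visual; this quantification is a triage aid for human
  review, never an automatic exclusion.
* **RLF monotonicity**: below 80 dB SPL, a mean rate falling below its
  running maximum by more than `max(25% of the maximum, 2 pooled SEM)`
  raises a flag (non-primary neurons with inhibitory input show such
  nonmonotonicity). The constants are configurable; again the original
  criterion is visual and no numeric rule is published, so the flag is
  triage, not exclusion.
* The primary-like response check is supported by artefacts for human
  inspection (the pooled tone PSTH near 20–30 dB above threshold via
  `unit_tone_psth()`), not by an automatic classifier — no formal
  criterion exists.

## The synthetic fibre simulator

The simulator is a *phenomenological* model — the simplest forms
consistent with how auditory-nerve fibres are described:

* **Tuning**: V-shaped threshold curve on a log2-frequency axis. The
  slope is set in closed form so the bandwidth 10 dB above the tip is
  exactly `cf / q10`: with half-width `u` octaves per side,
  `2^u − 2^−u = 1/q10`, a quadratic in `2^u`.
* **Rate-level growth**: clipped-linear saturation,
  `rate = spont + max_driven * sat((level − thr(freq)) / dynamic_range)`;
  below threshold the rate is exactly spontaneous. Straight and
  sloping/flat-saturating rate-level shapes arise from where the level
  grid sits in the dynamic range. Cochlear nonlinearities
  (compression, two-tone suppression, adaptation) are out of scope.
* **Spiking**: inhomogeneous Poisson by thinning, then an absolute dead
  time (default 0.6 ms). Phase locking multiplies the rate by a von
  Mises density in the tone phase, `exp(kappa cos(2 pi f t)) / I0(kappa)`
  (unit mean over a period); `kappa` is obtained by numerically
  inverting the mean-resultant-length relation `I1/I0 = vs_target`,
  so spike phases have expected vector strength `vs_target` before
  dead-time distortion. The dead time thins preferentially where the
  rate is high, so measured `vs` deviates from the target by a few
  hundredths at high rates; recovery tolerances (±0.05) absorb this.
  The dead time also makes the realized firing rate
  `lambda / (1 + lambda r)` for intensity `lambda`; all rate-recovery
  checks compare against this corrected value.
* **Clicks**: a first spike at `latency_base + delta(cf)` with Gaussian
  jitter, followed by a ~5-ms exponentially decaying transient
  (1-ms time constant). The travelling-wave delay is
  `delta(cf) = 2 ms * (cf/1 kHz)^−0.4`, a package constant spanning
  roughly 0.7–3 ms over 0.4–16 kHz that reproduces the negative
  latency–CF correlation; it is a modelling choice, not a measured
  value.
* **Raw traces**: Gaussian background noise plus a canonical biphasic
  template (~1 ms support, peak normalized to 1) whose peak sample
  lands at `round(t * fs) + 1`; optional log-normal amplitude jitter
  emulates the amplitude drift of real recordings.
* **Population**: CFs log-uniform over 428–15825 Hz; spontaneous rates
  from a bimodal mixture with modes near 5 and 60 spikes/s;
  phase-locking strength declining with CF and exactly 0 at and above
  5 kHz; thresholds elevated by ~15 dB (middle-aged) and ~30 dB (old)
  on average; animal metadata (ABR threshold, weight) drawn around the
  age-group means of the modelled colony.

**Acquisition defaults** (values chosen once, as realistic protocol
settings): tone trials of 0.3 s with a 0.2-s tone after 0.05 s; BF
curves with 25 frequencies over 1.5 octaves at threshold + 10 dB, 5
repetitions; RLFs in 5-dB steps with 10 repetitions; response fields
with 15 frequencies over 2 octaves × 10 levels in 5-dB steps, 10
repetitions; PH with 3 levels × 50 repetitions; SR as 100 × 2.4-s
silence trials; clicks with 100 repetitions, 10-ms pre-onset baseline
in 40-ms trials. Silent trials are interleaved in tonal recordings as
often as the number of repetitions. The repetition counts are chosen
with the criterion statistics in mind: the strict `mean + 1.2 SD`
criterion discriminates driven from spontaneous cells with
`z ≈ 1.2 * sqrt(reps * stim_dur / trial_dur)`, so the response-field
protocol uses 10 repetitions (`z ≈ 3.1`); with very few repetitions the
criterion triggers on sub-threshold fluctuations — a property of the
criterion itself that users analysing sparse real grids should expect
(which is why the criterion is manually adjustable).

**What passing tests do and do not show.** The simulator produces
Poisson-like spike trains with exact V-tuning and clipped-linear rate
growth. Real fibres adapt within the tone burst, have non-Poisson
count statistics, asymmetric tuning tails, and level-dependent phase
cues; parameter recovery on the simulator therefore validates the
*estimators and their conventions* (windows, criteria, interpolation,
pooling), not robustness to every biological deviation.

## Problem sizes and tolerances used in the checks

The test suite and the acceptance script run a 50-fibre recovery study
(seeded; ~20 s) with SR recordings shortened to 30 × 2.4-s trials, plus
small constructed cases. Tolerances, asserted in the suite: BF median
error < 1 grid step (1.5/24 octave); RLF threshold median |error| ≤ 1
level step (5 dB — the strict criterion biases the estimate upward by
about one step); vector strength median |error| < 0.05; 2-bin click
latency median |error| < 0.3 ms (the method reports response onset,
~0.2 ms before the mean first-spike latency); spontaneous rate within
3 Poisson standard errors of the dead-time-corrected rate for ≥ 90% of
fibres. Oracle checks: spike detection equals an exhaustive
excursion-scan; Q10 matches a dense (0.02-Hz) re-interpolation oracle
to 0.1%; FSL statistics match direct arithmetic; the PSTH conservation
identity is exact on every randomized input.

## Known limitations

* The MATLAB loader maps the common field layouts (per-trial
  `spike_times`, `freqs`, `levels`; `curvesettings` timing fields under
  several spellings) and preserves everything else in `extras`; exotic
  layouts may need a pre-mapping step.
* The metadata sheet is schema-compatible with deposited sheets, not
  byte-identical: the deposited column set is not published, so the
  package defines and documents its own.
* The nonmonotonicity and prepotential screens quantify visual
  criteria; their constants are starting points for triage, and the
  package never auto-excludes a unit.
* The simulator omits cochlear nonlinearities, adaptation and
  non-Poisson variability, as noted above.
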