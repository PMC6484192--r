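---
title: "Classifying single-unit drug responses from extracellular recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying single-unit drug responses from extracellular recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikepharm)
```

## The analysis problem

A single hippocampal pyramidal neuron is recorded extracellularly across a
systemic drug injection: 15 minutes of baseline, the injection, then 105
minutes of continued recording (7200 s in all). The questions are
per-neuron — did it respond, in which direction, when, by how much — and
per-group: did the drug shift firing rates overall? `spikepharm`
implements this analysis end to end, together with a synthetic-data module
that generates sessions with known ground truth so every stage can be
validated by recovery rather than by eye.

The package is organised as a library (everything under `R/`, fully
tested) driven by the numbered narrative scripts under `analysis/`; those
scripts, not a shell wrapper, are the command-line surface.

## Simulating sessions

Spike trains are inhomogeneous Poisson processes simulated by thinning:
candidates are drawn from a homogeneous process at the profile's maximum
rate, kept with probability rate(t)/max, and an absolute refractory period
is then enforced by greedy deletion. Thinning is exact for the
piecewise-linear rate profiles used here, and the refractory deletion
never leaves an inter-spike interval below the dead time.

The rate profile is flat at `baseline_rate` until `onset_time` seconds
after the injection, then steps (or ramps linearly over `ramp_duration`)
to `baseline_rate * effect_multiplier`. Effects are multiplicative because
drug responses in this setting are reported as percent changes relative to
baseline; a multiplier of 2.6 is "+160%", 0.2 is "an 80% reduction".

Parameters, defaults, and why:

- `baseline_rate` — spikes/s. Cohort presets draw it uniformly on
  2–8 spikes/s: 8 is the pyramidal inclusion cap, and below ~2 spikes/s a
  60-s bin holds so few spikes that any baseline-referenced rule is
  dominated by counting noise; 2–8 is the range a practitioner would call
  a healthy pyramidal baseline.
- `refractory` — 2 ms by default, a physiological floor that prevents
  degenerate inter-spike-interval statistics. It biases realised rates
  down by roughly r·0.002 (≈ 1.6% at 8 spikes/s), which is why
  calibration-style checks in the tests disable it explicitly.
- `injection_time = 900` s, `session_duration = 7200` s — the session
  design; all downstream defaults (15 baseline bins, 105 post bins)
  follow from it.
- `onset_time` — drawn uniformly on each group's onset window (42–64 min
  across presets). Only ranges are known for when responses begin, so a
  uniform draw on the range is the least-informative choice consistent
  with them; the same applies to effect magnitudes.
- `seed` — one global seed fans out to per-unit substreams by unit index
  (parameter draws and the thinning stream are separate substreams), so a
  cohort is reproducible unit by unit and identical seeds give
  bitwise-identical timestamps.

The four cohort presets encode a saline control and three dose groups:
15, 16, 14 and 16 units with 3/2, 3/3, 8/1 and 10/2
excitatory/inhibitory units respectively (the rest null), excitatory
magnitudes from +25% up to +420% stratified as observed per group, and
inhibitory magnitudes between −55% and −80%. The low-dose group's
magnitudes were never reported; the presets reuse the modest control-scale
ranges (+25–70%, −60–70%) for it, which is the conservative choice — it
only matters for power, not for any calibration property.

Voltage synthesis adds a biphasic template at each spike time to white
Gaussian noise: a cosine main lobe of width 1 ms peaking at exactly
`peak_amplitude`, followed by a negative after-lobe at 0.35× amplitude.
The constructed SNR is `peak_amplitude / noise_sd` by definition. Real
extracellular noise is colored and spike shapes drift; this generator
deliberately tests the detector under the cleanest assumptions its SNR
criterion speaks about.

## Spike detection

Detection thresholds a boxcar-smoothed copy of the trace (0.25 ms window,
a quarter of the waveform width) at `threshold_k = 4` times the smoothed
noise SD, estimated by the median absolute deviation scaled to the
Gaussian SD — robust because spikes at ≤ 8 spikes/s occupy well under 1%
of samples. Smoothing trades a little peak amplitude (the waveform is
correlated across samples) for a √k reduction in noise, which is what
makes a 4-SD threshold usable at SNR 5. Thresholding is on the absolute
signal so negative-going spikes take the same code path.

Each suprathreshold excursion yields one event at the *raw* signal's peak
sample, so reported peak heights are not biased by the smoothing. The
detector's dead time (1.5 ms) runs from the excursion's onset — the
trigger — as in a hardware discriminator: a retrigger within the dead
time (typically the after-lobe, whose excursion can start ~1.4 ms after
the trigger) extends the excursion instead of producing a spurious event.
1.5 ms spans the full waveform while staying below the 2 ms refractory,
so two genuine spikes cannot be merged.

Window discrimination then keeps events whose peak height falls in
`height_window` — the software analogue of setting a hardware window
around the unit's spike height; the validation studies use
[0.85, 1.6] × amplitude. SNR is defined as mean event peak height over
the noise SD (the criterion itself is only "a ratio above 2", so a
definition had to be fixed); units at or below 2, or with no events at
all, are flagged for exclusion. At constructed SNR 5 this stage recovers
spikes with recall and precision above 0.99 (measured over 100 seeded
traces in the acceptance run); `analysis/02_detection_fidelity.R` maps
how both degrade toward SNR 3.

## Binning and baseline statistics

Bins are half-open, `[t, t + width)`, zero-based from recording start —
stated explicitly because every off-by-one dispute in binned analyses
comes from leaving this implicit. A trailing partial bin is dropped and
its length recorded. Two representations are built: 1000-ms acquisition
bins and the 60-s PSTH; summing 60 acquisition bins reproduces the
matching PSTH bin exactly, and total binned counts always equal the
spikes in the covered range (both are tested against brute-force
oracles).

Baseline statistics are the mean and *sample* SD (n − 1; n = 15 bins is
small) of the pre-injection 60-s PSTH bin rates. The SD is taken over
60-s bins rather than 1000-ms bins because the classification rule
operates on PSTH points; computing it over acquisition bins would inflate
the SD by the finer bins' counting noise and make the band incomparable
across bin widths.

## Response classification

A unit is *excitatory* when at least `run_length = 3` consecutive
post-injection bins lie strictly above mean + 2·SD, *inhibitory* when 3
consecutive bins lie strictly below mean − 2·SD, else *unaffected*.
Choices the rule's one-sentence statement leaves open, fixed here:

- Strict inequality at the band edges: a response must *exceed* the band.
- The inhibitory criterion mirrors the excitatory one symmetrically.
- If runs of both signs occur, the earlier run decides the label and both
  are recorded (ties in the same bin cannot occur; a single label per
  unit is wanted downstream).
- Degenerate baselines (SD = 0, e.g. a silent unit) are floored at the
  rate equivalent of one spike per bin (1/60 spikes/s) and flagged, so a
  silent-then-active neuron is classifiable rather than an error.
- Onset latency is (first qualifying bin start − injection)/60, in
  minutes; percent change averages the qualifying-run bins only (the
  response as called), with all-bins-from-onset available via
  `percent_scope = "post_onset"`.

The implementation is verified to agree *exactly* with an independent
brute-force scanner (test every window of 3 bins) on 1000 random PSTHs,
including constant and integer-valued pathologies.

One property of the rule deserves emphasis: with the band estimated from
15 baseline bins, its null call rate is about 5% per unit (measured over
300 seeded null units; the 14-df SD estimate is the main driver — an
underestimated SD makes the band easy to exceed). That is intrinsic to
the rule, not to this implementation. Consequences: in a 16-unit cohort,
all 16 labels match ground truth in only about half of replicates, and a
truly responsive unit is occasionally called early (or with the wrong
sign) by a pre-onset noise run. Recovery is therefore asserted where it
genuinely holds — truly responsive units at ≥ +100% are called with the
right sign in well over 95% of runs, and onsets of ≥ +160% steps are
recovered within ±2 min in over 90% — not as exact per-cohort count
matching.

## Group-level inference

Per group: response-class counts (excluded units tallied separately, and
counts + exclusions always sum to the group size), a two-tailed paired
Student t test on per-neuron mean rates, and per-bin mean ± SEM time
courses. The "post" mean is taken over the full 105-minute window, not
just response bins — the group question is whether the drug shifted
firing overall, not conditionally on having responded. Degrees of freedom
are n − 1 by definition of the paired test. α = 0.05, no
multiple-testing correction across the four groups (each group answers
its own question; reports say so). Under null cohorts (multiplier 1,
n = 16, 500 replicates in the acceptance run) the test rejects at
5% ± 2% — the calibration one should demand before believing any
significant group result.

## Problem sizes and numerical choices

Validation studies run at: 1000 random PSTHs for the classifier–oracle
check, 200 seeded sessions each for call-rate and onset recovery, 500
null cohorts of 16 units for type-I calibration, and 100 ten-second
traces at 20 kHz for detection fidelity — sizes at which every binomial
bound tested has comfortable margin while the whole suite runs in a few
minutes on one core. Timestamps are written with 17 significant digits so
write/read round-trips are exact; bin-edge comparisons use a 1e-9 s
guard against floating-point drift; seeds derived from the global seed
stay below 2³¹.

## What passing these tests does and does not show

The generator emulates the *statistical* structure of the study design:
session timeline, pyramidal-range stationary baselines, step/ramp
multiplicative effects with per-group magnitude and onset ranges, and
Gaussian-noise voltage traces at constructed SNR. It does not emulate
bursting or oscillatory firing, rate drift, waveform nonstationarity,
overlapping units, colored noise, or pharmacokinetic onset dynamics —
so passing recovery tests shows the pipeline is correct and calibrated
under its stated model, not that the 2-SD rule is optimal for real CA1
data. No spike sorting beyond a single amplitude window is attempted, and
no dose-response modeling is done at the group level.
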