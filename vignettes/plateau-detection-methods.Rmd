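---
title: "Defining and detecting SmO2 plateaus: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining and detecting SmO2 plateaus: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(COxPlateau)
```

## The problem

Wearable NIRS oximeters report muscle oxygen saturation (SmO₂) as an
arbitrarily scaled percentage between 0 and 100 a.u. In a 3-min all-out
cycling test, SmO₂ drops steeply at effort onset and, in many trials,
flattens toward an end-test level — a "critical oxygenation" (COx) plateau,
the local analogue of the end-test power plateau used to estimate critical
power. Because the signal is noisy (biological heterogeneity, movement
artifacts, skin perfusion) and arbitrarily scaled, "plateau" can only mean
*a bounded range of acceptable variability over a defined terminal window*.
This package turns that definition into an explicit, parameterised, testable
rule.

## Signal model and conditioning

Trials are modelled as time-stamped traces with metadata (subject, muscle
site, oxygen condition). The test occupies [0, 180] s; a full sample spans
[−30, 210] s (30 s pre-test, effort, 30 s recovery). Placing the test start
at second 0 makes "the last 45 s of the effort" the fixed interval
[135, 180] s for every trial.

Conditioning mirrors how field devices deliver data:

* **Trailing 5-s moving average.** Each output sample is the mean of input
  samples in the half-open window (t − 5, t]. It is trailing (causal)
  because the device applies its filter in real time; a centred variant
  exists for sensitivity analysis. Traces flagged as device-smoothed are not
  smoothed again unless forced, so the filter is applied exactly once.
* **1-Hz resampling by linear interpolation** onto the integer seconds
  inside the observed range. Genuine extrapolation beyond the first or last
  sample is refused: inventing values for a bounded physiological signal
  would fabricate data. Whether field pipelines used linear, spline or step
  rules is rarely reported; linear is the default and step ("constant") is a
  config option. Internal gaps wider than 4 s (two missed 2-s samples) abort
  with the gap identified rather than being bridged silently.
* **Inclusive integer windows.** The segment [a, b] holds b − a + 1
  samples: a 30-s window holds 31 values and the 45-s region 46. This is
  stated prominently because off-by-one conventions are the commonest source
  of irreproducible window counts.

## The plateau criteria

A criterion is (mode, T, window length, region, metric). The default
battery is A5, A10 (absolute ±5, ±10 a.u.) and R5, R10 (relative ±5 %,
±10 % of the window's first value). Candidate windows start at each integer
second s ∈ {135, …, 150}; the trial is positive iff any window is stable,
and the earliest stable window is reported together with its worst signed
deviation.

Design choices that were genuinely open, and how they were settled:

* **Anchored vs range stability.** The criteria are phrased in the field as
  a *threshold of change* with symmetric bounds (−T to +T), which reads most
  naturally as change relative to the window's first value: anchored
  stability, the default. The range reading (max − min ≤ T) is strictly
  stronger at the same T and is kept as a configuration for sensitivity
  checks; the two nest (range-stable at T ⟹ anchored-stable at T ⟹
  range-stable at 2T), which the test suite verifies.
* **Relative reference.** The window's first value, not the trial baseline:
  this matches the field arithmetic by which 5 % of a ~20 a.u. plateau is
  ~1 a.u. — far stricter than 5 a.u. absolute — and explains why relative
  criteria flag far fewer plateaus at low end-test levels.
* **Inclusive bounds.** A deviation of exactly T counts as stable
  (benefit-of-the-doubt). The published tables do not state the convention;
  it is exposed implicitly through the threshold value, and documented here.
* **Ties.** The earliest stable window wins. Window starts are integer
  seconds only, inherited from the 1-Hz grid.
* **Degenerate windows.** Regions pinned at 0 or 100 a.u. (device rails)
  are classified by the rule but flagged, since ceiling-clipped stretches
  are trivially "stable".
* **Relative mode at v₀ = 0** is an error (percent change undefined), not a
  silent negative.

## Rater agreement analytics

Visual assessment contributes binary plateau judgements from panels of four
raters (expert and non-expert). The package computes:

* **Fleiss' kappa** from the yes/no category counts:
  P(i) = Σⱼ n(i,j)(n(i,j)−1) / (n(n−1)), κ = (P̄ − P̄ₑ)/(1 − P̄ₑ). When all
  ratings fall in one category, P̄ₑ = 1 and κ is mathematically
  indeterminate; the package returns an explicit `undefined` marker rather
  than 1 or an error, because agreement is perfect but chance-corrected
  agreement is not estimable. No significance tests or intervals are
  computed.
* **Landis–Koch bands** with right-closed intervals (<0 poor; [0, 0.20]
  slight; (0.20, 0.40] fair; (0.40, 0.60] moderate; (0.60, 0.80]
  substantial; (0.80, 1] almost perfect). Right-closed placement maps every
  published panel value to its printed label; boundary values take the lower
  band.
* **Consensus**: an item is positive iff ≥ 3 of 4 raters said yes; a 2–2
  split is negative. **Percent agreement** between any two binary methods is
  100 × matches / items.

Cohort summaries report integer counts plus full-precision percentages;
count comparisons should use the integers, since printed percentages are
formatting artifacts (29/30 may be printed truncated as 96.66).

## The synthetic generator

The generator exists so every stage is testable with known ground truth.
Its noise-free backbone is

* baseline b for t < onset (default 65 a.u., drawn 60–75 a.u. in cohorts —
  typical pre-exercise levels);
* p + (b − p) · exp(−(t − onset)/τ) during the effort, with plateau level p
  drawn from 10–22 a.u. (the band spanned by published end-test group
  means for male and female athletes) and τ ≈ 15 s (cohorts draw 12–18 s),
  consistent with the fast desaturation seen in all-out tests;
* an optional linear drift d · (t − 135) confined to the analysis region —
  one parameter flips plateau vs non-plateau without altering early
  kinetics; d = −0.3 a.u./s gives −9 a.u. per 30-s window, cleanly between
  the A5 and A10 thresholds;
* exponential recovery toward baseline after 180 s (τ = 20 s);
* additive independent Gaussian noise (default 1 a.u.) and optional
  movement-artifact pulses, then clipping to [0, 100]. No autocorrelated
  noise model is fitted, since no noise spectrum is published for these
  devices; noise robustness claims therefore hold for white noise only.

The ground-truth label is computed by running the labelling criterion
(default A5, anchored) on the *noise-free* backbone, never the noisy
realisation — separating criterion behaviour from noise sensitivity. Cohorts
draw all randomness from a single seed; the number of true-plateau trials
per group is floor(n · fraction + 0.5).

What passing synthetic tests does **not** show about real data: real SmO₂
noise is autocorrelated and artifact-laden; real plateaus need not be
preceded by clean mono-exponential kinetics; and the generator shares its
labelling criterion with the detector, so perfect noise-free recovery is a
consistency check, not a field-validity claim. Validation against human
expert ratings requires the original study data, which are not
redistributable with the package.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script use cohorts of 120–200
trials (30–50 per group), the scale of the original 2 × 2 × 30 design;
property checks run 100 random traces/matrices against brute-force oracles.
Trace values round-trip through CSV at 17 significant digits, so write/read
is exact. All tolerances in the suite are either exact (integer counts,
labels) or 10⁻¹² (floating-point formula equivalence).

## Known limitations

* The criteria are validated for 3-min all-out tests only; they are not
  meaningful for ramp or step protocols, where breakpoint detection (out of
  scope here) is the appropriate tool.
* Only the SmO₂ channel is analysed; total haemoglobin is not parsed.
* Rater behaviour is not simulated beyond independent flips in the
  acceptance script; expert/non-expert differences are represented only as
  metadata.
* The exact column layout of vendor CSV exports varies by firmware; the
  column-mapping arguments absorb this, but no proprietary binary format is
  parsed.
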