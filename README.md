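# COxPlateau

Detection of critical-oxygenation (COx) plateaus in muscle-oximetry
recordings of 3-min all-out cycling tests.

Wearable near-infrared spectroscopy (NIRS) sensors report muscle oxygen
saturation (SmO₂) as an arbitrarily scaled percentage in 0–100 a.u. During a
3-min all-out test, SmO₂ falls rapidly from its pre-test baseline and — in
many trials, especially in the locomotor vastus lateralis — settles into a
stable end-test level, the local-oxygenation analogue of the critical-power
plateau. This package is for exercise physiologists and sports scientists
who need a reproducible, scriptable definition of that plateau instead of
eyeballing curves.

## The detection rule

A trial is **plateau-positive** if any 30-s window inside the last 45 s of
the effort is *stable*. With the 1-Hz resampled signal v(t) and a window
anchored at start second *s* (candidate starts s ∈ {135, …, 150}), the
default *anchored* stability rule is

  v(t) − v(s) ∈ [−T, +T]  for all t ∈ [s, s + 30]

with four criteria in the standard battery:

| id  | mode     | T                                   |
|-----|----------|-------------------------------------|
| A5  | absolute | 5 a.u. of %SmO₂                     |
| A10 | absolute | 10 a.u. of %SmO₂                    |
| R5  | relative | 5 % of the window's first value     |
| R10 | relative | 10 % of the window's first value    |

Bounds are inclusive; the earliest stable window wins. A *range* variant
(max − min ≤ T) is available for sensitivity analyses. Upstream, the signal
is conditioned the way the field's devices deliver it: 2-s sampling, a 5-s
trailing moving average, then linear interpolation to 1 Hz.

Multi-rater visual annotations are analysed with Fleiss' kappa
(κ = (P̄ − P̄ₑ)/(1 − P̄ₑ) over the yes/no category counts), Landis–Koch
interpretation bands, and a ≥3-of-4 majority-vote consensus; cohort
summaries and trial × method comparison matrices aggregate the binary
determinations. A seeded synthetic generator produces ground-truth-labelled
cohorts (exponential desaturation to a plateau, optional plateau-breaking
late drift, Gaussian noise, movement artifacts) for end-to-end validation.

## Worked example

```r
library(COxPlateau)

syn <- generateCohort(nPerGroup = 30, plateauFraction = 0.9,
                      noiseSd = 1, seed = 7)
det <- classifyAllCriteria(syn$cohort)
head(summarizeCohort(det), 4)
#>   criterion           muscle condition n_total n_plateau pct_plateau
#> 1        A5  triceps_brachii   hypoxia      30        28    93.33333
#> 2        A5 vastus_lateralis   hypoxia      30        27    90.00000
#> 3        A5  triceps_brachii  normoxia      30        27    90.00000
#> 4        A5 vastus_lateralis  normoxia      30        27    90.00000

mean(det[, "A5"] == truthLabels(syn$cohort))   # recovery of ground truth
#> [1] 0.9916667
```

Each group holds 30 trials of which 27 were generated with a true plateau
(zero late drift) and 3 with a −0.3 a.u./s drift that breaks the A5 rule;
the A5 determinations recover those labels in 99.2 % of the 120 trials at
1 a.u. noise. Per-trial results carry the winning window and its worst
deviation:

```r
detectPlateau(preprocessTrace(syn$cohort[[1]]), defaultCriteria()$A5)
#> PlateauResult [A5]: plateau detected (window [135, 165] s, worst deviation -2.13)
```

A thin command-line front end (`inst/scripts/coxplateau.R`) exposes
`simulate`, `detect`, `summarize` and `agree` subcommands over the same
functions.

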