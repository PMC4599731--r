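---
title: "Detection sequences, migration routes and apparent survival at a receiver curtain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection sequences, migration routes and apparent survival at a receiver curtain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoltroutes)
```

## The measurement model

A receiver curtain turns a continuous migration into a sparse point
process: a tagged smolt is observable only while within ~400–800 m of a
receiver, and each crossing of the line yields a burst of detections at
one or two adjacent receivers. Three ideas turn these bursts into an
analysis of migratory behaviour.

**Detection sequences.** Raw detections are mostly redundant (the same
fish pinging the same receiver every few minutes). We collapse them into
*detection sequences*: maximal runs in which every consecutive pair of
detections is less than `max_gap_hours` (default 1 h) apart in time and
at most `max_step_km` (default 1.6 km, two receiver spacings) apart along
the curtain. Each sequence is summarised by its first/last time and
receiver. Distinct sequences of one fish then represent distinct visits
to the curtain.

**Route classes.** The east–west axis is signed east-positive; receiver
indices increase westward from the mainland (receiver 1) to Vancouver
Island (receiver 27). Comparing where a fish's first sequence ended with
where its second began classifies its route: second sequence west →
*counterclockwise*; east → *clockwise*; same receiver, or no second
sequence but a downstream detection → *linear*. Fish seen once at the
entry curtain and never again are *unclassified*: the three named classes
cannot cover them, and they are excluded from route proportions (this is
also what reconciles the published per-group route counts with the larger
number of fish detected). Fish detected at the westward-exit curtain
(Juan de Fuca) are tallied separately and excluded from entry-curtain
analyses.

**Displacement.** Δx between two receivers is
`0.8 km × |index difference|`, plus 8.0 km when the pair spans the Texada
Island gap, signed west-negative. The gap handling follows the analysis
convention of adding the gap width to the spacing-based magnitude
(`gap_mode = "add"`); the alternative reading, replacing the single
gap-step by 8.0 km so that Δx equals physical chainage
(`gap_mode = "replace"`), is available because the two differ by one
receiver spacing (0.8 km) for every gap-spanning move. We default to
"add" as the literal form of the stated adjustment; no conclusion in the
test suite depends on the choice.

## Numerical and boundary choices

* *Strictness*: "less than one hour" is taken literally — a gap of
  exactly 60.0 min starts a new sequence; a step of exactly 1.6 km does
  not. The distance rule is evaluated in km from chainage, so receivers 7
  and 8 (8 km apart) always break a sequence despite being adjacent in
  index; `step_mode = "index"` restores the index-difference reading.
* *Ties*: detections with identical timestamps are ordered by ascending
  receiver index before grouping, making output deterministic.
* *Zero displacements*: a second sequence starting where the first ended
  scores Δx = 0 and the fish is linear. In the one-sample signed-rank
  test, exact zeros are dropped from the statistic (classical Wilcoxon
  zero handling) but retained in reported means.
* *Exact vs approximate tests*: exact null distributions are used when
  n ≤ 25 with no ties, otherwise the normal approximation with
  continuity correction. Every exact path (binomial, signed-rank,
  rank-sum, Fisher, Kendall) is checked in the test suite against an
  independent enumeration oracle at n ≤ 8.
* *Degenerate ANOVA inputs*: a between-group sum of squares of zero is
  reported as F = 0, p = 1 even when the residual variance is also zero.
* *Separation*: logistic fits whose fitted probabilities touch 0/1
  within 1e-8, or that fail to converge (IRLS, deviance tolerance 1e-8),
  are flagged and excluded from ranking and averaging with a warning.

## The survival models

Apparent survival `S_QCS` (any detection at the downstream curtain ~250
km along the migration) is modelled with binomial GLMs, in two candidate
sets: an *entry* set (entry receiver position, arrival day-of-year, and
for steelhead fork length and release year, plus natal population and
its interactions with position and date) using every fish detected at
the curtain, and a *lateral* set (Δx₁₂, the duration between the first
two sequences, and the analogous extras) using only multi-sequence fish.
Fork length and year are excluded for sockeye because they are collinear
with population; Seymour steelhead are excluded from the lateral set
(too few multi-sequence fish). Continuous predictors are standardized by
subtracting the mean and dividing by **twice** the SD, putting them on
the scale of binary predictors.

All term subsets that respect marginality (an interaction only with both
parents) are fitted and ranked by AICc with k counting every estimated
coefficient including the intercept. Coefficients are averaged over the
ΔAICc ≤ 2 set with renormalized Akaike weights. We report the full
(zero-substitution) average — absent terms contribute zero, shrinking
weakly supported effects — with the unconditional standard error
`Σ wᵢ √(seᵢ² + (βᵢ − β̄)²)` and Wald ±1.96 CIs; conditional (subset)
averages are emitted alongside, since both conventions are in common
use and the choice is not decidable from the published tables. The
pseudo-R² is McFadden's `1 − logLik/logLik₀` with adjustment
`1 − (logLik − k)/logLik₀`; note that no standard adjustment can exceed
the unadjusted value, so published tables where it does were presumably
computed with a different (unstated) metric that we do not attempt to
reproduce. Prediction curves are the inverse-logit of the averaged
linear predictor along one standardized variable, others held at 0
(their means), per population where interactions are present and only
over each population's observed range.

## What the generator emulates — and what it does not

`simulate_smolts()` is a 1-D along-migration + 1-D east–west
agent model. Per fish it draws fork length (group mean ± SD from the
published release table), a release date (uniform over a 45-day window
opening April 25, so entry-curtain arrivals centre on late May with an
SD near the reported 11–16 days), an over-ground speed of 1 BL/s clamped
to 13–17 km/day, and a behaviour class with probabilities
P(linear)/P(ccw)/P(cw) defaulting to 0.65/0.25/0.10 — the study-wide
route mix — applied to both species. Arrivals hit the eastern channel
(receivers 1–7) with probability 0.66, spread uniformly within each
stratum. Loopers re-cross after an exponential dwell (mean 70 h, the
reported mean duration between sequences, minimum 2 h so crossings
cannot merge into one sequence) displaced by a gamma-distributed
amplitude (mean 7 km, SD 4 km) scaled by √(dwell/70 h) — so milling
duration and displacement are positively associated, as observed — and
may close the loop with a third, oppositely displaced crossing
(probability 0.6, mean 2 km). Each crossing is detected as a whole with
the tag model's efficiency (V7 0.675, the midpoint of the reported
60–75%; V9 0.90), emitting pings every 120 s over a 5–20 min residence,
with an optional one-receiver westward drift within the first crossing
mirroring the small observed within-sequence drift.

Mortality composes two mechanisms. An exponential death clock at
`baseline_daily_hazard` (default 0.05 d⁻¹, chosen so that apparent
survival conditional on entry-curtain detection lands near the published
~0.34–0.39) kills fish in transit, truncating later crossings — so
loopers, who spend longer en route, die more. Optionally a logistic
stage on the entry-to-exit leg applies log-odds coefficients to
2-SD-standardized true covariates (entry position, day-of-year, milling
duration) and an eastern-channel indicator; with the hazard at zero this
makes the generator's survival exactly a logistic model with known
standardized coefficients, which is what the coefficient-recovery tests
exercise. The downstream curtain is treated as perfectly efficient by
default so that simulated apparent survival equals true survival; a
`qcs_efficiency` knob restores the confounding when wanted.

Deliberately not modelled: real hydrodynamics (rotation is imposed as a
behaviour class, with only a stylized drift hook), geodetic geometry and
array curvature, depth, predators, and within-crossing detection physics
(range testing, collisions). Consequently, passing tests demonstrate
that the *analysis* is correct and unbiased under the stated generating
process — not that the generating process is oceanographically faithful.
Two emergent behaviours of the real system are reproduced and tested:
with V7-level efficiency, missed first crossings alias counterclockwise
fish into the linear and clockwise classes, biasing the recovered
counterclockwise proportion low; and classification recovers the true
class of every fish whose second crossing actually occurred when
efficiency is 1 and loop amplitudes exceed the 1.6 km step rule.
Feasibility constraints (counterclockwise fish cannot arrive at the
westernmost receiver; clockwise fish cannot arrive at receiver 1; drift
is suppressed where it would strand a commanded loop) keep the ground
truth unambiguous.

## Problem sizes used for validation

The test suite validates the sequencer against brute force on 500 random
detection strings of up to 30 detections (plus full boundary-placement
enumeration up to 10), the exact tests against enumeration at n ≤ 8,
route recovery end-to-end on cohorts of 2 000 simulated smolts, and
survival-coefficient recovery (true standardized β_duration = −1.0,
β_position = +0.8) over 50 seeded replicates of n = 2 000, requiring the
mean full-model estimate within ±0.15 of truth and ≥ 90% CI coverage.
These sizes give stable Monte Carlo behaviour at seconds-to-minutes
runtimes; estimates at the study's own scale (~3 500 released fish) are
produced by `scripts/acceptance.R`.

## Known limitations

Apparent survival confounds death with non-detection; no
detection-efficiency correction (e.g. capture–recapture modelling) is
attempted, matching the analysis being reproduced. The route taxonomy
observes only curtain crossings: a fish looping entirely between
receivers, or west of the curtain, is invisible. Unclassified fish are
informative about detection efficiency and mortality but enter no route
statistic. The per-species published route-proportion means cannot all
be reconciled exactly from the per-group table (the steelhead
counterclockwise mean is a documented example), so the acceptance
arithmetic targets only quantities that recompute exactly from the
printed counts.
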