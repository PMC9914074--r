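---
title: "Evidence fusion for excretion-event detection: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence fusion for excretion-event detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(dsnurse)
```

## The detection problem

An excretion-nursing device must decide, from its own sensors, which of four
events has occurred: urine (A), stool (B), both (C) or nothing (D). Three
channels carry the signal — temperature (°C), relative humidity (%RH) and
ammonia concentration (ppm) — each expressed as an *excursion* above the
indoor environment baseline. A calibrated detection table maps each channel ×
event to an excursion interval (e.g. stool: temperature 0.5–2 °C, humidity
5–12 %RH, ammonia 1–2 ppm; urine: > 1.8 °C, > 20 %RH, > 2 ppm; both:
0–1 °C, 12–20 %RH, 1–2 ppm; "none" is a neighbourhood of zero). Individual
sensors are noisy and the intervals overlap, so the device fuses the three
channels — and three repeated read cycles — with Dempster–Shafer evidence
theory instead of thresholding a single reading.

## Frame semantics

The frame of discernment is Θ = {u, s, n}: urine present, stool present,
nothing. The four decision events are focal sets over Θ with **C = {u, s},
the union of A = {u} and B = {s}**. This is forced by the combination rule
used: the conflict coefficient counts products such as m1(A)·m2(C) as
non-conflicting, which requires A ∩ C = A. The semantically tempting
alternative — a dedicated "both-present" atom — would make A and C disjoint
and change the rule. A consequence worth keeping in mind throughout: under
Dempster's rule the union C only retains its diagonal product
m1(C)·m2(C)/K, while A and B also harvest their cross-products with C.
Evidence on C therefore *drains* toward the singletons under repeated
combination. This is a structural property of the rule, not an
implementation artifact, and it drives the central design choice below.

## From excursion to evidence

The device's calibration gives hard intervals, but a measured excursion is
the true excursion plus read noise. The package therefore scores an
excursion `d` against an interval (lo, hi) with a *Gaussian-smoothed
indicator*: the indicator of the interval convolved with a Gaussian kernel
of width `w`, rescaled to peak at 1. The "none" event, a point at zero, uses
the matching Gaussian peak `exp(-d²/2w²)`.

The width `w` (the *softness*) defaults to **twice the standard deviation of
the per-cycle averaged reading**, `2·σ_ch/√(reads per cycle)`, where σ_ch is
the configured per-read sensor noise (defaults 0.4 °C, 4 %RH, 0.6 ppm, of
the order of the installed sensors' datasheet accuracy). The two-sigma band
is the usual engineering coverage choice: an observation within two standard
errors of a boundary is treated as genuinely ambiguous between the adjacent
classes, observations further away as decisive. Softness tracks the noise
model, so a device configured with noiseless sensors reasons with crisp
intervals — which is what makes the noiseless-limit recovery property hold
exactly (below). Boundaries are half-open: a value exactly on a shared
boundary belongs to the class above it (2 ppm is urine), and an excursion of
exactly 0 belongs to "none".

Memberships become a basic probability assignment by the **consonant
allocation** (the default, `bpa_alloc = "consonant"`): because {s} ⊂ {u, s},
evidence compatible with both stool and the union C is ambiguous between
them and belongs on the union — only the singleton-exclusive excess supports
the singleton:

* m(A) ∝ max(0, μ_A − μ_C), m(B) ∝ max(0, μ_B − μ_C), m(C) ∝ μ_C, m(D) ∝ μ_D.

This is the canonical consonant mass induced by nested focal sets in
possibility theory. The naive alternative — normalizing the memberships
proportionally (`bpa_alloc = "proportional"`) — is provided for comparison,
but it interacts fatally with the drain property above: the ammonia interval
for stool and for both is *identical* (1–2 ppm), so proportional allocation
puts equal mass on B and C on every ammonia read, the cross-products hand
that tie to B at every fusion step, and the combined event C can never win a
fused decision. The packaged benchmark measures exactly that: under
proportional allocation the "both" class scores 0% even with noiseless
sensors, while the consonant allocation recovers all four classes perfectly
in the noiseless limit. The membership scheme and softness are configurable
per channel in `detection_basis()`.

## The pipeline

For each session (3 cycles × 2 reads per channel by default):

1. **Preprocessing.** Per channel, reads farther than 3 scaled median
   absolute deviations from the session median are discarded as obviously
   unreasonable (a robust, parameter-light outlier rule; the threshold is
   `mad_threshold`). A cycle is never emptied: if all its reads are flagged,
   the one closest to the session median is kept. If the MAD is zero nothing
   is dropped. Surviving reads are averaged per cycle and converted to
   excursions; the ammonia excursion is floored at zero.
2. **Per-cycle fusion.** The three channel BPAs M1 (temperature), M2
   (humidity), M3 (ammonia) are fused with Dempster's rule.
3. **Cross-cycle fusion.** The three cycle results are fused the same way.
4. **Decision.** The event with the highest fused mass wins; ties break in
   severity order both > stool > urine > none, preferring the decision that
   triggers the most complete cleaning action (the calibration is silent on
   ties; this is the safe default).

Every mass entering a combination is floored at 1e-4 and renormalized
(`floor_mass()`), so the pipeline can never hit total conflict (K = 0);
`ds_combine()` on raw, unfloored masses still reports total conflict as an
error, which is the honest answer for genuinely contradictory certainties.
Dempster's rule is associative and commutative, so cycle order is
irrelevant; the property suite checks this, and checks the closed-form
implementation against a generic subset-lattice implementation of the rule
on 10⁴ random mass pairs.

One measured caveat, deliberately reported rather than assumed away:
repeated fusion "polarizes" a result (certainties sharpen), but it does
**not** always preserve the decision. A union-heavy mass such as
(0.3, 0.15, 0.4, 0.15) decides "both" once but flips to "urine" under
self-combination — the drain property again. The test suite asserts this
counterexample.

## The direct baseline

The traditional comparator classifies the *session-mean* excursions
directly: each channel votes for every event whose printed interval contains
the excursion ("none" votes within a near-zero neighbourhood whose
half-width is the smallest positive interval bound of the channel: 0.5 °C,
5 %RH, 1 ppm); the event with the most votes wins, with the same severity
tie-break. This is the minimal interpretation of single-table thresholding;
it aggregates the same reads (as their mean) but uses no uncertainty
handling.

## The synthetic generator

`sim_config()`/`simulate_dataset()` stand in for bedside data collection.
Per session, one true excursion per channel is drawn uniformly from the
class's detection interval — the excretion happened once, so the excursion
is constant within the session and only read noise varies. Unbounded urine
sides need sampling caps; the defaults (temperature < 4 °C, humidity
< 45 %RH, ammonia < 10 ppm above baseline) are physically generous and live
in the config, not the code. "None" sessions have zero true excursion.
Every read then passes the sensor observation model: Gaussian noise (SDs
0.4 °C / 4 %RH / 0.6 ppm by default), clipping to the measurable ranges
(−40–80 °C, 0–99.9 %RH, 0–300 ppm) and the ammonia detection floor (below
1 ppm the sensor reports 0). The default indoor baseline is 22 °C, 40 %RH,
0 ppm — an ordinary ward room; it is a configuration input, not an estimate.

What the generator does **not** emulate: sensor drift and recalibration,
quantization, correlated or heavy-tailed noise, ammonia transport dynamics,
diet- and subject-dependent excursion distributions, and class imbalance.
Benchmarks on this generator therefore demonstrate the *mechanics* of the
method — recovery, determinism, robustness to the modelled noise — not
clinical performance.

## Measured behaviour and limitations

All numbers here are computed by the packaged benchmark
(`scripts/acceptance.R`, 500 sessions per class, seed 1) and the test suite:

* In the noiseless limit, both classifiers are exact (100%) on all four
  classes.
* Under the default noise, the fused pipeline scores ≈ 92% overall; its
  errors concentrate in the stool/both confusion, where the calibrated
  intervals genuinely overlap (identical ammonia rows, overlapping
  temperature rows) and the union class pays the drain tax.
* The direct baseline scores ≈ 94% on the same sessions. Under this clean
  generative model — disjoint humidity intervals, small session-mean noise —
  interval voting on the session mean is close to the Bayes-optimal
  decision, so *no* fused detector can beat it by a large margin here; the
  McNemar paired chi-square on the discordant pairs is correspondingly
  small. A large real-device advantage for fusion, as reported for bench
  hardware, would have to come from the data pathologies listed above that
  the generator deliberately does not model. The comparison report exists
  precisely to make this measurable rather than assumed.
* Fused accuracy is non-increasing in the configured noise SD (checked on a
  three-point noise grid at one standard error's tolerance).

## Workflow timings and alarms

The actuator simulator encodes the control flow with exact timestamps (no
clock jitter): stool/combined flush = both flush valves + pump for 10 s with
the vacuum joining at 5 s and running to 18 s; urine flush = a fixed 10 s
re-detection wait, 5 s valve + pump, then 10 s vacuum; cleaning 15 s
(combined events open both cleaning circuits, urine only its own); drying =
heater 8 min, fan 10 min. The urine *cleaning* duration is not specified by
the control-flow description and is assumed symmetric with stool (15 s,
configurable); combined events follow the stool branch since it already
opens both circuits; the 10 s urine delay is modelled as a fixed wait rather
than a closed-loop re-detection. Totals: 633 s for stool/combined, 640 s for
urine. Alarms: side angle outside ±30°, clean-water level below threshold,
dirt level above threshold; each drives the buzzer.

## Problem sizes

The shipped checks use 2 000 benchmark sessions (500 per class), 10⁴ random
mass pairs against the lattice oracle, 600 sessions per point of the noise
grid, and 100-session noiseless recovery runs — sizes chosen so the entire
suite runs in well under a minute of compute while keeping binomial standard
errors around or below one percentage point on the headline accuracies.
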