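# dsnurse

Multi-sensor evidence fusion for intelligent excretion-nursing devices.

Bedridden and incontinent patients depend on nursing equipment that can tell,
from its own sensors, whether the patient has passed urine, stool, both, or
nothing — and then flush, wash and dry accordingly. A single sensor (the usual
ammonia-only approach) is unreliable: sensor error and environmental
interference routinely confuse the event classes. `dsnurse` implements
decision-level fusion of three sensors — temperature, humidity and ammonia
concentration — using Dempster–Shafer evidence theory, together with
everything needed to exercise the method without hardware: an interval
detection basis with a direct threshold baseline, a datasheet-faithful
synthetic event simulator, the device's flush/clean/dry actuator workflow and
alarm logic, and paired statistical evaluation. It is aimed at researchers and
engineers working on assistive-care sensing who need a tested, reproducible
reference implementation.

## The method

Events live on the frame of discernment Θ = {u, s, n} (urine present, stool
present, nothing). The four decision events are the focal sets

* A = {u} (urine), B = {s} (stool), C = {u, s} (both), D = {n} (none).

Each sensor contributes a basic probability assignment (BPA)
m = (m(A), m(B), m(C), m(D)), built from how compatible its excursion above
the indoor baseline is with each event's calibrated interval (see the
methods vignette for the membership and allocation scheme). Two BPAs are
fused by Dempster's rule of combination,

    (m1 ⊕ m2)(X) = (1/K) · Σ_{Y ∩ Z = X} m1(Y) · m2(Z)

with the conflict (normalization) coefficient

    K = Σ_{Y ∩ Z ≠ ∅} m1(Y) · m2(Z) ,

so that, C being the union of A and B,

    (m1 ⊕ m2)(A) = [m1(A)m2(A) + m1(A)m2(C) + m1(C)m2(A)] / K ,

and symmetrically for B, while C and D keep only their diagonal products.
A detection session consists of 3 cycles × 2 reads per sensor: within each
cycle the three sensor BPAs M1, M2, M3 are fused, the three cycle results are
fused across cycles, and the event with the highest fused mass is the
decision (ties broken toward the most complete cleaning action). The
traditional baseline, for comparison, classifies the session-mean excursions
directly against the same intervals by majority vote; the two classifiers
are compared with McNemar's paired chi-square test on the discordant pairs.

## Worked example

```r
library(dsnurse)

basis    <- detection_basis()                      # calibrated intervals + environment
sessions <- simulate_dataset(n_per_class = 5, seed = 42)
res      <- detect_sessions(sessions, basis)
head(res, 4)
#>   session_id true_label fused direct      m_A      m_B      m_C      m_D
#> 1      S0001      urine urine  urine 1.00e+00 7.00e-12 1.00e-12 1.00e-12
#> 2      S0002      urine urine  urine 1.00e+00 7.00e-12 1.00e-12 1.00e-12
#> 3      S0003      urine urine  urine 1.00e+00 7.00e-12 1.00e-12 1.00e-12
#> 4      S0004      stool stool   none 2.44e-05 9.94e-01 5.21e-03 7.95e-04
```

Each row is one session: `fused` is the evidence-fusion decision, `direct`
the threshold baseline, and `m_A`..`m_D` the final fused masses — session
S0004 shows the point of fusion: the baseline voted "none" on the session
mean, while the accumulated evidence puts mass 0.994 on stool.

```r
comparison_report(res$true_label, res$fused, res$direct)
#> <comparison report> n = 20
#>   fused accuracy:  95.00%
#>   direct accuracy: 95.00%
#>   discordant pairs: b = 1 (only direct right), c = 1 (only fused right)
#>   McNemar chi-square = 0.500 (not significant at 0.05)

run_workflow("urine")       # actuator schedule for the detected event
#> <actuator schedule>
#>       10-    15 s  flush_valve_urine
#>       10-    15 s  pump
#>       15-    25 s  vacuum
#>       25-    40 s  clean_valve_urine
#>       25-    40 s  pump
#>       25-    40 s  vacuum
#>       40-   640 s  fan
#>       40-   520 s  heater
```

A command-line wrapper with `simulate`, `detect`, `evaluate`, `workflow` and
`table2-report` subcommands is installed at
`system.file("scripts", "dsnurse", package = "dsnurse")`.

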