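# apcdeg

Kinetic modelling of ordered substrate degradation by APC/C^Cdc20.

During mitosis the anaphase-promoting complex/cyclosome, activated by
Cdc20 (APC/C^Cdc20), ubiquitinates substrates such as the cyclin Clb5 and
securin and thereby schedules their destruction. Different substrates of
the *same* enzyme pool begin to decline at reproducibly different times,
yet each disappears quickly once its decline starts. `apcdeg` is an R
package for exploring how substrate–enzyme kinetics produce this
behaviour, and for detecting degradation onset in single-cell
fluorescence traces. It is aimed at systems biologists studying
cell-cycle proteolysis and, more generally, at anyone modelling
multi-step enzymatic commitment processes.

## The model

A mass-action ODE system over species A (free enzyme), S₀…S₄ (free
substrate with 0–4 ubiquitins) and AS₀…AS₄ (enzyme-bound substrate):

* binding A + Sᵢ → ASᵢ at *k_a* (/(nM·s)); dissociation ASᵢ → A + Sᵢ at
  *k_d* (/s); ubiquitin transfer ASᵢ → ASᵢ₊₁ at *k_c* (/s), one ubiquitin
  per event;
* substrate carrying four ubiquitins is degraded at *e* = 1000/s (bound
  forms release their enzyme), making the fourth ubiquitin the committed
  step;
* APC/C^Cdc20 either accumulates linearly at *p_A* = 0.06 nM/s from zero
  or is constant; S starts at 200 nM with no production;
* optional deubiquitination variants, a two-substrate extension in which
  S and C compete for one enzyme pool, and a single-binding-event
  processivity model with the closed form p + p² + p³ + p⁴,
  p = k_c/(k_c + k_d).

Timing is summarised by **T95** (time to fall to 95% of the initial
amount; the onset delay), **T50**, and **Td = T50 − T95** (the
degradation-rate proxy), computed from the total-substrate curve with
linear interpolation and explicit censoring. Scans over the 25×25
log-spaced (k_c, k_d) grid locate the overlap zone where both in-vivo
criteria hold: T95 > 200 s and Td < 600 s.

The trace-analysis half smooths and normalizes single-cell GFP traces,
takes the first derivative, finds its minimum and backtracks to the
latest near-zero point — the degradation onset — with a documented
group-delay compensation, and compares onset populations by t test.
Seeded generators produce synthetic traces (plateau, jittered onset,
exponential or model-shaped decline, Gaussian noise) so the whole
pipeline is testable without external data.

## Worked example

```r
library(apcdeg)

p  <- RateParams(kc = 0.1, kd = 10)   # an overlap-zone parameter set
tc <- simulateDegradation(p)          # 3000 s, 1-s output grid
timingMetrics(tc)
#> TimingMetrics for substrate S
#>   T95 (onset delay):   741.99 s
#>   T50 (half-life pt):  1217.61 s
#>   Td  (T50 - T95):     475.62 s
#>   max APC/C occupancy: 0.1660
```

Degradation onset is delayed by ~12 min after enzyme activation (T95),
yet the 95%→50% drop takes only ~8 min (Td) — the delayed-but-fast
behaviour seen in vivo — while S occupies at most 17% of the enzyme.

```r
avgUbiquitins(simulateProcessivity(1, 1))
#> [1] 0.9375
```

With catalysis and dissociation equally fast, a binding event attaches on
average 0.94 ubiquitins (p + p² + p³ + p⁴ at p = ½): most encounters end
before the fourth ubiquitin, which is why onset can lag activation.

A shell entry point wrapping the same functions is installed at
`inst/scripts/apcdeg` with subcommands `simulate`, `scan`, `compete`,
`processivity`, `synth` and `onset`.

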