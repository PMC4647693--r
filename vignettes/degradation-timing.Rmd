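---
title: "Modelling the timing of APC/C-Cdc20 substrate degradation"
author: "apcdeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the timing of APC/C-Cdc20 substrate degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcdeg)
```

## The question

During mitosis the anaphase-promoting complex/cyclosome bound to its
activator Cdc20 (APC/C^Cdc20^) targets regulators such as the cyclin Clb5
and securin for proteasomal destruction, and it does so in a fixed order:
some substrates begin to decline minutes after others, even though a single
enzyme pool drives all of them and is already active.  Once a substrate
does start to decline, it disappears within a few minutes.  `apcdeg`
implements a quantitative framework for asking how the kinetics of the
substrate--enzyme interaction can produce both behaviours at once: a robust
*delay* in degradation onset, and a *fast* degradation rate after onset.

## The one-substrate model

The core is a deterministic mass-action model of multi-step ubiquitination.
The species are free enzyme $A$, free substrate $S_i$ carrying
$i = 0 \dots 4$ ubiquitins, and enzyme-bound substrate $AS_i$.  The
reactions are:

* binding $A + S_i \rightarrow AS_i$ with rate constant $k_a$ (per nM per
  second),
* dissociation $AS_i \rightarrow A + S_i$ with rate constant $k_d$ (/s),
* ubiquitin transfer $AS_i \rightarrow AS_{i+1}$ for $i < 4$ with rate
  constant $k_c$ (/s), one ubiquitin per catalytic event,
* degradation of the four-ubiquitin forms $S_4$ and $AS_4$ with rate
  constant $e$ (/s); degradation of $AS_4$ releases free enzyme, because
  the enzyme is a catalyst and is not consumed,
* optionally, deubiquitination at rate $k_{dub}$ (/s), removing one
  ubiquitin per event from a configurable set of species.

Two enzyme-input modes are provided.  In the default *linear* mode the
enzyme accumulates at $p_A$ nM/s from $A(0) = 0$, mimicking gradual
activation of APC/C^Cdc20^ after checkpoint silencing.  In *constant* mode
the full amount $A_{\mathrm{const}}$ is present from $t = 0$, mimicking
abrupt activation.  There is no substrate production: in vivo the level of
these substrates plateaus before degradation begins, so the pre-degradation
supply is folded into the initial condition.

Reference parameter values, used as defaults throughout: $S_0 = 200$ nM
(estimated cellular Clb5 concentration), $p_A = 0.06$ nM/s (from
single-cell estimates of Cdc20-GFP accumulation), $e = 1000$/s (so that a
four-ubiquitin substrate is destroyed essentially instantaneously — this
makes "four ubiquitins" the committed step rather than a modelled
proteasome), and $A_{\mathrm{const}} = 100$ nM (half the substrate amount)
in constant mode.  $k_a$, $k_c$ and $k_d$ are the biologically variable
quantities and are scanned.

Two structural choices deserve flagging because the reaction scheme leaves
them open.  First, $S_4$ is allowed to rebind the enzyme
($k_a \cdot A \cdot S_4$): the four-ubiquitin bound form is reachable by
either catalysis or binding.  Second, degradation of $AS_4$ returns its
enzyme to the free pool.  Both choices follow from treating the enzyme as
catalytic; with $e = 1000$/s their quantitative impact is minimal because
$S_4$ and $AS_4$ never accumulate (the test suite checks they stay below
1% of $S_0$).

Deubiquitination variants mirror the four cases commonly considered:
`all` (every ubiquitinated species), `free_only` ($S_{1..4}$),
`bound_only` ($AS_{1..4}$), and `mono_only` ($S_1$ and $AS_1$ only, the
case where only mono-ubiquitinated substrate is a good deubiquitinase
substrate).  Every variant reduces bitwise to `none` when $k_{dub} = 0$.

## Timing metrics

From the total-substrate curve $\sum_i (S_i + AS_i)$ the package computes:

* **T95** — first time the total falls to 95% of its initial value; the
  proxy for the delay in degradation onset,
* **T50** — first time it falls to 50%,
* **Td = T50 − T95** — the time to go from 95% to 50% remaining; the proxy
  for degradation rate (smaller = faster),
* **max occupancy** — the maximum over time of (substrate-bound
  enzyme)/(total enzyme).

Crossings are located by linear interpolation between the 1-s output
samples.  The baseline is always the $t = 0$ value, not a running maximum
(total substrate is non-increasing in this model, so the two coincide; the
choice is stated for clarity).  A crossing that does not occur within the
horizon is *censored*: it is reported as `NA` plus an explicit flag, never
as a sentinel number, because the slow corners of the parameter space
genuinely never reach 50% within 3000 s and downstream ratios must not be
fabricated there.

The in-vivo-motivated criteria are $T95 > 200$ s (material onset delay)
and $Td < 600$ s (fast degradation).  `delayMask()`, `rateMask()` and
`overlapMask()` evaluate them over a scan.  Cells whose T95 is censored
satisfy the delay criterion (their onset is delayed beyond the horizon)
but can never satisfy the rate criterion.

## Parameter scans and sensitivity

`buildLogGrid()` reproduces the reference grid: 25 values each of $k_c$
and $k_d$ log-spaced on $[10^{-3}, 10^{3}]$/s and 6 values of $k_a$ on
$[10^{-4}, 10]$/(nM s).  The $k_c$/$k_d$ neighbour ratio is exactly
$10^{1/4} \approx 1.778$; throughout the package the "factor of 1.8"
perturbation is implemented as this exact grid ratio, treating 1.8 as the
rounded form of the spacing.  `sensitivityT95()` recomputes the perturbed
run from scratch rather than reading a neighbouring grid cell, so the
sensitivity is well defined off-grid; on-grid the two approaches coincide
up to that rounding.

Scans never abort on a single-cell solver failure; the cell is flagged and
the scan continues.  Scans are deterministic, and the tidy CSV emitted for
a given configuration is byte-identical across runs.

## Two-substrate competition

`TwoSubstrateParams()` duplicates the reaction set for a second substrate
C sharing the enzyme pool and the association constant $k_a$.  Both
substrates start at 200 nM.  The named scenarios encode the two ways C can
be the better substrate: ten-fold tighter binding
(`affinity`: $k_{d,C} = k_{d,S}/10$) or ten-fold faster catalysis
(`catalytic`: $k_{c,C} = 10 k_{c,S}$).  Scan maps index the grid by the
parameters of S; C's follow the scenario rule.

The competition metrics need a denominator convention, which the package
fixes explicitly (and records in output metadata): *relative onset
difference* is $(T95_S - T95_C)/T95_C$, *Td ratio* is $Td_C/Td_S$, and the
*competition effect* is $(T95_S^{two} - T95_S^{alone})/T95_S^{alone}$,
i.e. the relative delay imposed on S by adding C, measured against the
one-substrate baseline with identical parameters.  Any metric with a
censored ingredient is censored.

## Processivity

The single-binding-event model starts from $AS_0$ as the sole species;
each complex either gains a ubiquitin ($k_c$, for $i<4$) or dissociates
($k_d$), with no rebinding and no degradation.  The expected number of
ubiquitins at dissociation has the closed form
$p + p^2 + p^3 + p^4$ with $p = k_c/(k_c + k_d)$, which serves as an
independent oracle for the ODE route.  Internally the simulation
integrates the time-rescaled system (rates divided by $k_c + k_d$), so the
result depends only on the ratio $k_c/k_d$ and is *exactly* invariant
under $(k_c, k_d) \to (c k_c, c k_d)$ — the formal statement of
processivity being a relative-strength property, unlike T95 and Td which
depend on absolute rates.  Terminal accounting keeps the $i = 4$ molecules
in the denominator (this model has no degradation arrow), and the
integration stops when the bound pool falls below $10^{-6}$ of its initial
amount, which bounds the accounting error at a few parts in $10^6$.  The
degenerate $k_d = 0$ case never dissociates; it is reported as average 4
with an explanatory note rather than left to a non-terminating root
search.

## Onset detection on fluorescence traces

Single-cell GFP traces (30-s sampling, about an hour) are processed as:
centered moving average (default window 5 samples = 2.5 min, partial
windows at the edges), normalization by the smoothed maximum, first
derivative by central differences, location of the derivative minimum (the
fastest-declining point; it must be negative), and a backward scan for the
latest earlier sample whose derivative is at least `zeroFraction`
(default 0.1) times that minimum — i.e. no longer materially declining.

Two operationalizations are declared rather than inferred, since the
original procedure fixes neither: the "close to zero" threshold of 0.1,
and the smoothing kernel (a moving average, chosen for transparency).  Two
further numerical guards matter in practice:

* **Group-delay compensation.**  A centered moving average of half-width
  $h$ smears a sharp onset over $[t_0 - h, t_0 + h]$ samples and the
  central difference reaches one sample further, so the latest near-zero
  derivative sample sits exactly $h + 1$ samples *before* the true corner.
  The reported onset adds $h + 1$ samples back (never moving past the
  derivative minimum).  This makes the call exact for a noise-free
  plateau-then-decline trace at any window length, and unbiased to within
  one sample at realistic noise.
* **Material-decline guard.**  An onset is only called if the smoothed
  normalized trace actually loses at least `minDrop` (default 5%) of its
  maximum; otherwise numerical ripple on a flat trace would be promoted to
  a "decline".

A monotone non-decreasing trace yields no call; a trace already declining
at its first sample is called at the first sample and flagged.  Detection
is invariant to positive rescaling of the intensities.  Population
comparisons use a two-sample t test (Welch by default, pooled on request).

## Synthetic data

`TraceSpec()`/`generateTrace()` emulate the features of single-cell GFP
degradation data that the detector actually relies on: a flat plateau, a
per-cell onset (population onset plus Gaussian jitter, default sd 30 s),
then an exponential decline (default rate 0.005/s, a half-life of about
2.3 min, matching the few-minute degradation seen in vivo) or the rescaled
total-substrate curve of a model run, with additive i.i.d. Gaussian noise
(default sd 2% of the plateau) on a 30-s grid over one hour.  All
randomness derives from a single seed, per cell, so any trace is
reproducible in isolation and generation order is irrelevant.

What the generator does *not* emulate — photobleaching, the mCherry/SPB
reference channel, cell-cycle alignment, segmentation noise with
heavy-tailed outliers — bounds what passing tests show: they demonstrate
that the detector recovers onsets under plateau-plus-decline dynamics with
Gaussian noise, not that it is robust to every artefact of real imaging.
`generateModelPopulation()` closes the loop between the two halves of the
package: simulate, add measurement noise, detect onsets, and compare the
calls with the model's own T95.

## Numerical choices and problem sizes

The degradation system is stiff ($e = 1000$/s against scanned rates down
to $10^{-3}$/s), so the default integrator is the adaptive
stiffness-switching `lsoda` with `rtol` $10^{-8}$ and `atol` $10^{-10}$
nM; output is sampled every 1 s over a 3000-s horizon, and metric
computations interpolate linearly between samples.  In rare
fast-degradation runs `lsoda`'s dense-output interpolation fails once the
substrate pool underflows to machine zero; such runs are retried
automatically (and deterministically) with the plain BDF solver `vode`
before an integration failure is reported.  Concentrations more
negative than $-10^{-6}$ nM abort the run as a solver failure; tiny
negative excursions above that are clipped to zero for reporting.  A
fixed-step explicit Euler mode is provided for replication studies; being
explicit it requires $dt < 2/\max(\text{rate})$, i.e. $dt < 2$ ms with the
default $e$, and it raises an explicit integration-failure error naming
the parameter set when driven outside that regime.

The test suite cross-checks the adaptive solver against an independently
written fixed-step Euler oracle at $dt = 10^{-3}$ s on five designated
parameter sets over a 600-s window — long enough to cover enzyme
accumulation, the onset and the bulk of the decline at those parameter
sets, while keeping the pure-R oracle loop (600,000 steps per run)
affordable.  Scans in the tests and the acceptance script use the full
25×25 grid.

## Known limitations

The model deliberately omits E1/E2 dynamics, activator exchange, ubiquitin
chain topology, and explicit proteasome kinetics; all are folded into the
three substrate-specific constants and $e$.  Competition is limited to two
substrates.  The onset detector assumes a single decline per trace and
uniform sampling.  None of the in vivo quantities (the 4-min securin-2A
vs Clb5 onset gap, the 3-min Clb5-2A delay, the fold-change of catalysis
with an intact ABBA motif) are recomputed here: those require the original
single-cell and biochemical data, and the package's scope is the modelling
and trace-analysis machinery around them.
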