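---
title: "Model and methods: cost-effectiveness of surgical options for displaced femoral neck fractures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipcea)
```

## The decision problem

An active older patient with a displaced femoral neck fracture receives one
of three prostheses: bipolar hemiarthroplasty (BHA), single-bearing total
hip arthroplasty (SB-THA) or dual-mobility THA (DM-THA). THA implants cost
more up front but dislocate and revise at different rates and support
different quality of life, so the choice is an economic as well as a
clinical one. The package evaluates the three strategies over a five-year
horizon from the Japanese public payer's perspective, in 2022 yen and
QALYs, both discounted at 2% per year, against a willingness-to-pay (WTP)
threshold of ¥5,000,000 per QALY.

## States, tracker and events

The Markov model has four health states: well post-surgery (on the primary
implant), well post-R-THA (after a first revision, always performed with a
DM implant), well post-RR-THA (after a re-revision; the model assumes no
further revisions), and death, which is absorbing. A per-patient tracker
counts dislocations on the current implant: the first is managed by closed
or open reduction (one-cycle cost and disutility), the second forces a
revision; the tracker resets when the implant is replaced. Infection states
are deliberately out of scope. Each annual cycle one of the mutually
exclusive events occurs: death (life-table probability, evaluated first),
revision for non-dislocation causes, revision for dislocation (only on the
revised implant — see below), dislocation, or nothing.

Transition probabilities for the reference arm are tabulated by 5-year age
band (65–89; older ages reuse the last band). The DM-THA arm multiplies the
SB-THA rates by DM-vs-SB relative risks. For BHA no direct BHA-vs-SB ratio
exists, so `derive_strategy_probabilities()` chains through DM-THA. The
chained BHA *dislocation* probability (0.0215 × 0.17 / 0.41 ≈ 0.0089 in
the 75–79 band) is used as is. The chained BHA *revision* rates, however,
are not used by default: chaining gives a revision-for-dislocation rate
(0.0086 × 0.40 × 7.16 ≈ 0.0246/year) nearly three times BHA's total
dislocation rate, which is internally inconsistent — an implant cannot be
revised for dislocation more often than it dislocates. The engine therefore
defaults to `bha_revision_rates = "shared"` (BHA revises at the reference
SB-THA rates); the chained variant remains available as a switch for
sensitivity work.

## Cycle-accounting conventions

Several accounting details are genuinely open in this model family; each
is an explicit `sim_config()` switch with a fixed default, chosen once as a
package convention by comparing candidate variants against the published
base-case table and horizon scenarios with the cohort evaluator, and frozen
thereafter. The defaults are:

* **Surgery year** (`first_cycle_events = TRUE`): cycle 1 accrues the
  surgery bundle — initial-year inpatient costs plus implant plus surgical
  fee — instead of the annual maintenance cost, and events can already
  occur.
* **Revision year** (`revision_year_cost = "full_initial"`): a revision
  accrues the revision fee and DM implant *and* a fresh initial-year THA
  cost on top of the annual well cost, because a revision restarts an
  arthroplasty year.
* **Revision utility** (`revision_event_utility = "origin_toll"`): in the
  event cycle the patient keeps the origin state's utility minus the
  revision disutility (for SB/DM-THA this equals the printed composite
  0.870 − 0.185 = 0.685); the printed post-revision state utility applies
  from the next cycle.
* **Death** (`death_accrual = "half"`): deaths happen mid-cycle on
  average, so the death cycle credits half the cycle's cost and utility.
  This is the only half-cycle adjustment in the model.
* **Revision-for-dislocation probability** (`revdis_mode =
  "r_state_only"`): on the primary implant, revisions for dislocation
  emerge from the tracker (second dislocation); the tabulated
  revision-dislocation probability acts as a direct event only on the
  revised implant, avoiding double counting the tracker mechanism.
* **Discounting** (`discount_first_cycle = FALSE`): factor
  1/(1+r)^(t−1), first cycle undiscounted.

## Parameters and distributions

`packaged_parameters()` returns the transcribed published inputs: banded
probabilities, six relative risks, three one-cycle disutilities, six state
utilities and ten cost items (yen), each with a point estimate and a
low/high sensitivity range. Printed ranges are used verbatim; where only a
point estimate exists the package applies the source's convention
SE = 0.2 × point, range = point ± 1.96 SE (`derive_range()`). Post-revision
utilities are calculated composites (0.870 − 0.185 = 0.685;
0.870 − 0.287 = 0.583) but are varied and sampled as parameters in their
own right, since the one-way analysis treats them separately. The well
post-SB-THA and post-DM-THA utilities share the point estimate 0.870 yet
remain distinct, independently sampled parameters.

For probabilistic sensitivity analysis, families follow parameter roles:
gamma for costs and lognormal for relative risks (both by method of
moments from the point estimate and SE, the lognormal centred so its
*median* equals the point estimate because the printed intervals are
symmetric on the log scale), normal for disutilities, and beta for
utilities and probabilities. Infeasible beta moments (SE² ≥ m(1−m)) fall
back to a [0, 1]-truncated normal; zero-width ranges are fixed. Joint draws
are independent across parameters — no correlation structure is published —
and a sampled set whose competing event probabilities exceed 1 in any band
is rejected and redrawn, with the count reported.

## Engines

The **microsimulation** (`run_microsimulation()`) is a first-order Monte
Carlo walk of 100,000 patients per arm, vectorized across trials, with one
deterministic seed substream per strategy so arms are compared on
independent randomness and any run reproduces exactly. The **cohort
expectation** (`cohort_expectation()`) propagates occupancy over the finite
state space (health state × tracker ∈ {0, ≥1} × alive) and returns exact
expected values; the tracker saturates at one because a second dislocation
always revises. The test suite holds the two engines to agreement within
three Monte Carlo standard errors across strategies, ages and sexes, and to
a brute-force enumeration of the full two-cycle outcome tree on toy
parameters. Sensitivity analyses, threshold searches, the PSA and the
scenario grids all use the cohort evaluator by default: it is noise-free,
fast enough for 10,000 PSA evaluations, and equal to the microsimulation in
expectation; a nested microsimulation evaluator is available behind the
`method` argument.

## Decision outputs and numerics

`cea_frontier()` sorts strategies by cost, removes strict and extended
dominance, and reports increments and ICERs along the frontier;
`wtp_decision()` maximizes net monetary benefit with ties broken by lower
cost, then fixed strategy order, and the suite property-checks its
equivalence with the frontier-ICER rule. QALY increments below 10⁻⁶ make an
ICER "undefined" (the tornado's infinity case). Threshold search
(`find_threshold()`) bisects on the *incremental net monetary benefit*
λ·ΔE − ΔC rather than on the ICER itself — the same root, but continuous
where ΔE approaches zero — to a relative parameter tolerance of 10⁻⁶ after
verifying a sign change on the bracket. The acceptability curve uses a WTP
grid of 0–20M yen in ¥250,000 steps; the PSA scatter ellipse is the sample
covariance scaled by the χ²(2 df) 0.95 quantile (5.991). Money is rounded
to whole yen and QALYs to three decimals only in the output writers;
internal arithmetic is double precision throughout.

## Synthetic data

The official 2022 abridged life table of Japan is an input the package does
not bundle. `synthetic_japan_life_table()` builds a labelled synthetic
stand-in: annual death probabilities for ages 65–100 obtained by log-linear
hazard interpolation through approximate Japanese old-age anchors (female
q(75) ≈ 0.011, male ≈ 0.025, mortality doubling roughly every 6–8 years,
males above females throughout). It emulates the level and slope of recent
Japanese mortality but not the official cell values, cause structure, or
any fracture-attributable excess mortality — the model treats "active older
patients" as having general-population mortality. Tests passing on the
synthetic table therefore demonstrate correctness of the machinery and
robustness of the published qualitative patterns, not exact numerical
agreement with the original setting; `read_life_table()` accepts the
official `age`/`qx` columns directly (abridged tables are expanded by
repeating the interval value). `gompertz_life_table()` provides a two-
parameter closed-form alternative for property tests, and
`random_parameter_set()` draws bounded, always-valid parameter sets for
generator-contract tests.

## Known limitations

* The five-year horizon stops short of implant lifetimes; no extrapolation
  is attempted beyond it, or beyond age band 85–89.
* The exact cycle accounting of the original implementation is not
  published; the conventions above are this package's own, and the
  remaining discrepancy concentrates in the DM-vs-SB dislocation
  relative-risk crossing value, which this model places below the
  published figure.
* Costs are Japanese fee-schedule values used as printed; no currency-year
  restandardization is performed (conversions to £/US$ use the flat 2022
  rates 162 and 131 yen).
* PSA draws are independent across parameters; correlations (e.g. between
  revision rates) would narrow or widen the acceptability curves in ways
  the model cannot represent.
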