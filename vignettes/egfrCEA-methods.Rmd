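---
title: "Methods: the egfrCEA decision model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the egfrCEA decision model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrCEA)
```

This vignette is the package's own account of its model: the assumptions,
the tunable parameters, the numerical conventions, and — because several of
them were genuinely open — the design choices and why we made them. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The decision problem and the model

Advanced EGFR mutation-positive non-small-cell lung cancer can be treated
first-line with erlotinib (an oral EGFR tyrosine-kinase inhibitor) or with
platinum-doublet chemotherapy such as carboplatin–gemcitabine (CG).
Erlotinib roughly triples median progression-free survival in this
population but carries a high acquisition cost; the economic question is
whether it is cost-effective from the Chinese health-care-system
perspective, in 2010 USD.

The model is a three-state cohort Markov chain — progression-free (PFS),
progressed (DP), dead — run in 3-week cycles over a 10-year horizon
(`ceiling(10 × 365.25 / 21) = 174` cycles). The whole cohort starts in PFS.
Each cycle a PFS patient stays, progresses, or dies; a DP patient stays or
dies; death is absorbing. Costs and effects are discounted at 3%/year with
`d_k = 1.03^{-k \cdot 21/365.25}`. Months are 30.4375 days and years 365.25
days everywhere, so unit conversions are calendar-independent.

### Cycle-timing conventions

The source model's timing conventions are unstated, so the package fixes
one consistent set, chosen because it makes occupancy × per-cycle cost
reproduce the reported lifetime DP costs:

- **End-of-cycle counting, no half-cycle correction.** Person-time, QALYs
  and per-cycle costs accrue to the state occupied at the *end* of each
  cycle (`k ≥ 1`).
- **Progression takes effect next cycle.** Patients who progress in cycle
  `k` join the DP at-risk pool at the start of cycle `k + 1`: they incur
  neither DP cost nor DP mortality in their entry cycle.
- **Median interpolation.** The model median PFS is the linear
  interpolation, on occupancy, of the cycle at which the PFS trace crosses
  0.5, converted to months.

## Survival calibration

**Per-arm exponential defaults.** The source fitted Weibull curves to the
trial Kaplan–Meier data but did not publish the fitted shapes. We therefore
default to `weibull_shape = 1` (exponential), calibrated to each arm's own
trial median (13.1 / 4.6 months) through
`scale = median / (ln 2)^{1/shape}`. The trace median then reproduces the
trial median at cycle resolution regardless of the shape, which is the
validation the analysis rests on. `fit_weibull_to_km()` (least squares on
`log(−log S)` against `log t`) recovers shapes from Kaplan–Meier data when
pseudo-IPD is available.

**The hazard ratio is deliberately unused by default.** The trial hazard
ratio (0.16) is inconsistent with the hazard ratio implied by the two
exponential medians (4.6/13.1 ≈ 0.35); the source does not say which
quantity anchored its fits. Calibrating each arm to its own median
reproduces both trial medians; `use_hazard_ratio = TRUE` switches to
deriving the erlotinib curve from the CG curve via
`apply_hazard_ratio()` for scenario analysis.

**Post-progression mortality is back-calibrated.** No overall-survival
curve was available to the source ("the lack of an overall survival curve"
is its own stated limitation), and the only printed anchor for
post-progression survival is the discounted DP person-time of the base
case: 1.23 years (erlotinib) and 3.65 years (CG). We model DP → death as a
constant per-cycle probability per arm and find it by bisection on
\[0, 1\] so the discounted DP person-time of the trace matches the target
(discounted, because the reported table is explicitly discounted at
3%/year). Discounted DP person-time is strictly decreasing in the
probability, so bisection is exact; tolerance 1e−8 on the probability
(≤ 60 iterations, deterministic), which delivers the target within 1e−6
years. An unreachable target (larger than the person-time at zero
mortality) is an error that reports the achievable maximum. Direct
PFS → death transitions default to 0 (every PFS exit is a progression)
because the source never quantifies pre-progression death; a
`p_pfs_death` hook exists.

## Costs and utilities

All costs are 2010 USD. Per cycle: CG treatment $1599.41 (cycles 1–4,
treated as all-inclusive of the $54.74 administration component, which is
reported separately but never added on top — the source never decomposes
the aggregate), then best supportive care $1415.40; erlotinib $1971.10
(cycles 1–7; the weekly unit price 3 × $657.05 = $1971.15 cross-checks it),
then $0 from cycle 8 under the manufacturer donation programme; blood tests
$10.59 (CG) / $3.53 (erlotinib) per PFS cycle, added on top by default
(only the *differential* blood-test cost matters to the ICER; both
behaviours are switches, and CG blood tests stop at the BSC switch, BSC
being assumed all-inclusive); DP $1209.96 per *cycle* in both arms.

Two printed ambiguities are resolved as config switches with reasoned
defaults:

- **Anaemia rate 0.13 vs 9%.** The trial table prints 9%, the sensitivity
  table 0.13. Default 0.13, because
  0.42 × 461.5 + 0.40 × 3395.0 + 0.13 × 531.7 = 1620.951 reproduces the
  reported expected adverse-event management cost exactly; 0.09 is one
  override away.
- **DP cost basis.** The running text says "per month", the parameter
  table "per cycle". Default `dp_cost_basis = "cycle"`, the reading
  consistent with the reported lifetime DP costs; `"month"` prorates by
  cycle length.

The adverse-event management cost is a single expected one-off charge at
model entry (rate × unit cost, undiscounted, CG arm only — erlotinib's
trial rates are all zero), not a per-cycle hazard: it is reported as one
lifetime number equal to that expectation. Utilities are 0.65 (PFS on
erlotinib), 0.56 (PFS on CG, adjusted down for chemotherapy toxicity), 0.47
(DP, both arms), 0 (death); QALYs are discounted person-time × utility.

## Two evaluators: trace and anchored

The package exposes two deterministic pipelines and is explicit about what
each is for.

The **trace pipeline** (`base_case()`) runs calibration → trace →
economics from first principles. Its medians validate against the trial;
but because the source's Weibull shapes are unpublished, an exponential
trace cannot reproduce the source's base-case occupancies (an exponential
calibrated to a 13.1-month median has a longer discounted PFS expectation
than the reported 1.27 years, which implies a shape > 1).

The **anchored evaluator** (`anchored_evaluator()`), on which the tornado
and the PSA run, therefore fixes the base case at the *reported*
occupancies and lifetime cost totals and propagates parameter changes
around that point: effects are anchor occupancies × (possibly sampled)
utilities; each cost pool is scaled multiplicatively in its unit costs,
with component shares taken from the calibrated trace; the adverse-event
charge is recomputed exactly (and, for CG, folded into the PFS cost pool —
the reported totals are exactly PFS + DP). At base values the evaluator
returns the anchors; at zero costs it returns zero. A discount-rate
override (the one structural row of the sensitivity table) rescales each
anchored component by the ratio of trace-pipeline components at the new
versus the base rate, with post-progression mortality held at its
base-rate calibration — recalibrating it to a target that is itself a
3%-discounted quantity would be incoherent. Structural survival parameters
(medians, DP mortality) are not varied in the PSA because the sensitivity
table does not list them.

## Sensitivity analyses

**Tornado.** Each parameter in turn is set to its low and high value with
everything else at base; both ICERs (CG minus erlotinib) are recorded and
entries are ranked by absolute spread. An entry whose incremental QALYs
change sign across the range is flagged unstable and reported with signed
infinite sentinels rather than a meaningless ratio. Results are invariant
to the order the parameters are listed in.

**Distributions.** The published table gives a family and a low–high range
per parameter but no dispersion convention. We read the range as a 95%
interval, `sd = (high − low)/3.92`, and moment-match with mean = base:
gamma `shape = (m/s)^2`, `scale = s^2/m`; lognormal solved from the mean
and sd of the distribution itself (`σ² = ln(1 + s²/m²)`,
`μ = ln m − σ²/2`); beta `α = mν`, `β = (1 − m)ν` with
`ν = m(1 − m)/s² − 1` (an error names the row if the range is too wide for
a beta, i.e. ν ≤ 0). The `constant` family (discount rate) is a point mass,
varied one-way but never sampled. Parameters are sampled independently —
the source describes no correlation structure. Draws outside a parameter's
domain (utilities and rates in \[0, 1\], costs ≥ 0 — impossible for the
families used, but guarded) are resampled and counted.

**PSA outputs.** Each of the `n_iter` iterations (default 1000) re-runs the
anchored pipeline at the sampled values and records incremental cost and
QALYs (CG minus erlotinib) with its cost-effectiveness-plane quadrant;
exact zeros are assigned to the positive side. The CEAC reports, at each
willingness-to-pay λ, the fraction of iterations with
`λ·ΔQALY − ΔCost > 0` as CG's probability of being cost-effective,
erlotinib's being the complement. Everything is reproducible from the seed,
which is recorded in every output file. Because the dispersion convention
is ours, the published CEAC landmarks (the 50% crossing near the
deterministic ICER and the two 95% points) are treated as soft checks: the
tests assert the 50% crossing within a factor of 2 of the deterministic
ICER, not the printed dollar values.

## The synthetic-data generator

`generate_ipd()` emulates what the survival machinery needs from the trial:
two-arm progression-free event times drawn by inverse transform
(`t = scale · (−ln U)^{1/shape}`) from each arm's Weibull with
administrative censoring at a fixed follow-up. Defaults: exponential arms
at the trial medians, 500 patients per arm, 24 months follow-up. The arm
size and follow-up are generator choices, *not* trial facts — the source
prints no usable arm-level counts — and the generator makes no attempt to
reproduce the actual trial figures, accrual patterns, dropout, or
overall survival. A green parameter-recovery test therefore establishes
that the estimator chain (Kaplan–Meier via `survival::survfit`, then the
`log(−log S)` fit) is consistent, not that the original curves were
exponential.

## Numerical conventions and degenerate inputs

- Bisection tolerance 1e−8 on the DP mortality probability; no RNG
  anywhere in the deterministic pipelines.
- A survival curve that has vanished at a cycle start makes the state
  absorbing (transition probability 1).
- A PFS trace that never crosses 0.5 reports its median as `NA`.
- `icer()` with equal QALYs and different costs returns a signed infinite
  sentinel; a dominant strategy suppresses the ratio entirely.
- An event-free arm yields a flat Kaplan–Meier curve with a warning;
  fitting it is an error (at least two points with 0 < S < 1 are required).
- Internal arithmetic is full precision; only printed reports round
  (costs and QALYs to 2 decimals).

## Known limitations

- The CG arm's calibrated post-progression mortality leaves part of the
  cohort alive in DP at 10 years; the horizon truncates that tail by
  construction (the person-time targets are themselves 10-year discounted
  quantities). Extending the horizon with the same probabilities therefore
  *increases* CG life-years noticeably, and the horizon-adequacy property
  holds only for the (converged) erlotinib arm.
- The trace pipeline's base-case costs and QALYs differ from the anchored
  ones because the source's Weibull shapes are unpublished; the anchored
  evaluator exists precisely to make the uncertainty analyses operate
  around the reported base case.
- Utilities come from non-Chinese literature and enter linearly; the DP
  utility dominates the tornado, so this is the model's softest input.
- No treatment switching, toxicity-discontinuation states, or second-line
  composition within DP; one mean DP cost absorbs all of it.
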