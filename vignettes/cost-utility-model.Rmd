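---
title: "Methods: a semi-Markov cost-utility model of antipsychotic sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a semi-Markov cost-utility model of antipsychotic sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(szcea)
```

This vignette documents the model structure, its assumptions, the numerical
choices made in the implementation, and the limitations a user should keep in
mind when interpreting output.

## Decision problem

Three first-line antipsychotic strategies for schizophrenia — lurasidone,
olanzapine and risperidone — are compared from a healthcare-system
perspective in 2020 CN Yuan. Each strategy is a four-line sequence: the
first-line drug, then aripiprazole, then clozapine, then clozapine augmented
with risperidone. After the last line fails, patients re-trial it
indefinitely (`repeat_last`). Outcomes are discounted lifetime costs and
QALYs over a 15-year horizon; decisions are summarised as dominance labels,
incremental cost-effectiveness ratios and net monetary benefit at
willingness-to-pay thresholds of 1–3× per-capita GDP (72,447 / 144,894 /
217,341 CN¥ per QALY).

## State space and transitions

The cohort occupies five health states, expanded by treatment line and — for
the stable states — by a time-on-line clock `u` (a semi-Markov/tunnel
construction):

1. **ACUTE**: a 6-week treatment trial. Trial failure has probability
   `min(1, RR × 0.3934)`, a risk ratio against a placebo-arm discontinuation
   reference. Failures move to the next line's ACUTE state; successes
   stabilise with the clock reset to `u = 0`.
2. **STABLE_ADH**: relapse and discontinuation compete each cycle. Their
   per-cycle probabilities come from parametric baseline survival curves for
   a quetiapine reference arm — Weibull (discontinuation) and Gompertz
   (relapse) — scaled per drug by proportional hazards
   (`S_drug = S_0^HR`) and conditioned on the clock:
   `p(u) = 1 − S(u+Δ)/S(u)` with Δ = 42/365.25 years. By default relapse is
   resolved before discontinuation within a cycle
   (`settings.event_order = "relapse_first"`; the alternative order is a
   configuration switch). Discontinuers become non-adherent; the clock
   advances to `u + 1` for both stayers and new non-adherents, because one
   cycle of time-since-stabilisation has elapsed either way.
3. **STABLE_NONADH**: off drug. The relapse hazard is the *baseline* curve
   scaled by the odds transform `(1 − a)/a = 1.618` of the adherent share of
   relapses `a = 0.382`, evaluated on the same continuing clock.
4. **RELAPSE**: exactly one cycle, then the next line's ACUTE state.
5. **DEAD**: absorbing. Death is resolved first each cycle at the life-table
   annual probability of the cohort's current age converted to a hazard,
   multiplied by sex-specific standardized mortality ratios (10.17 male,
   12.42 female), converted to a per-cycle probability and mixed at 68.3%
   male. The cohort trace records all dead mass at line 1, since dead
   patients have no active line.

The clock grid is capped at the number of cycles; mass reaching the cap
stays there (the conditional event probabilities have essentially plateaued
by then).

Diabetes is an irreversible prevalence overlay rather than a state: each
cycle, on-treatment occupancy (ACUTE plus STABLE_ADH) accrues incidence
`min(1, RR_diabetes × 0.0069)` per cycle, and the prevalent pool survives
with the cohort. Prevalence multiplies a per-cycle management cost
(1,544.83) and a utility decrement (0.151). This deliberately ignores any
differential mortality or treatment-switching consequence of diabetes.

## Valuation

Costs per occupied cell and cycle comprise drug acquisition (dose × unit
cost × 42 days; only in ACUTE and STABLE_ADH; the augmented line sums its
clozapine and risperidone components), outpatient care (615.88 acute/relapse,
312.48 stable), expected inpatient care (admission probability × length of
stay × daily cost by state class: 0.52 × 26.4 d × 520 acute, 0.006 × 3.8 d ×
240 stable, 0.41 × 31 d × 520 relapse), and weight-gain/EPS management in
the acute trial only, weighted by `min(1, RR × baseline)` event
probabilities. QALYs use utilities 0.919 (stable) and 0.604 (acute/relapse)
minus acute adverse-event disutilities and the diabetes decrement, scaled by
Δ years and floored at zero.

Both streams are discounted at 5%/yr with cycle-start accrual
(`(1+r)^(−cΔ)`); a half-cycle correction (half weight on the first and last
cycle) is available as `settings.half_cycle_correction` but off by default.
Comparisons orient both deltas so positive favours the reference:
`ΔC = cost_comp − cost_ref`, `ΔQ = qaly_ref − qaly_comp`,
`NMB = λ·ΔQ + ΔC`; "dominant" means both positive. USD figures divide by
6.90 and round half-up.

## Parameters and uncertainty

All inputs live in a single validated configuration object
(`builtin_basecase()` / `synth_config()`), serialisable to YAML and
addressable by dotted paths. Sixty uncertain parameters carry 95% bounds and
a sampling family:

- ratio parameters (RR, HR, SMR, lengths of stay) — log-normal with
  `meanlog = log(point)` and `sdlog = (log hi − log lo)/(2 × 1.959964)`;
- probabilities and utilities — beta by method of moments from the point
  (mean) and `SE = (hi − lo)/(2 × 1.959964)`, with a ±25% uniform fallback
  (and a warning) if moment-matching is infeasible;
- costs — gamma by method of moments.

The one-way analysis (`run_owsa()`) sets each parameter to each bound in
turn — including a tornado-only discount-rate sweep over 0–8% — and records
the reference-vs-comparator NMB; results are sorted by NMB range. The
probabilistic analysis (`run_psa()`) draws all non-tornado-only parameters
independently, one RNG substream per parameter derived from the master seed
(so adding a parameter does not perturb the other draws), rebuilds the
configuration per iteration and re-runs every strategy.
`ceac()` turns the draws into pairwise and overall (highest-NMB, ties split
equally) acceptability probabilities.

## Calibration and the synthetic generator

Two classes of input are not available as published point values and are
generated by documented rules rather than transcribed:

- **Baseline quetiapine survival curves.** Only the parametric families are
  known. `calibrate_scale()` solves, in closed form, for the scale that
  makes the cumulative event probability hit an anchor at a fixed horizon
  and shape: 12-month discontinuation 40% (Weibull, shape 1 — constant
  hazard) and 12-month relapse 30% (Gompertz, slope 0.1/yr — mildly
  increasing hazard). These anchors are assumptions, stated once and never
  tuned; `synth_config()` accepts overrides so their influence can be
  examined directly.
- **The general-population life table.** `synth_life_table()` builds a
  Gompertz-shaped schedule: male annual death probability 0.002 at age 40,
  hazard doubling every 8 years, female hazard lower by a factor 1.7, ages
  20–100. Both generators are deterministic closed forms and take no seed.

What depends on the anchors and what does not: the incremental-arithmetic
layer (`compare_strategies()`, `to_usd()`, NMB) is exercised against
externally reported per-strategy totals (`reference_results()`) and is
anchor-free. The full pipeline's *levels* — and, for the closely priced
risperidone comparison, even the sign of the cost difference — do depend on
the anchors; the test suite asserts dominance over olanzapine and the QALY
direction against both comparators across ±10% anchor perturbations, and
records the risperidone cost direction as the anchor-sensitive quantity it
is.

## Numerical choices

- The Gompertz cumulative hazard `(θ/b)(e^{bt} − 1)` uses `expm1` and a
  series branch for `|bt| < 1e−8`, so `b → 0` degrades smoothly to the
  exponential.
- The cycle loop is vectorised over lines × clock as matrix operations; a
  clock-collapsed occupancy array (cycle × line × state) is always stored,
  while the full clock-resolved array is kept only when
  `run_cohort(..., keep_clock = TRUE)` (the default; Monte-Carlo loops turn
  it off). One full run-and-value pass takes on the order of tens of
  milliseconds, which is what makes the 60-parameter tornado and
  thousands-of-iterations PSA practical.
- Probabilities are clamped to [0, 1] at the few places where a risk-ratio
  product or an exhausted survival curve could leave the range, and
  `cycle_prob()` returns 1 where `S(u) = 0`.
- Occupancy conservation (unit mass at every cycle) and agreement with an
  independent individual-level microsimulation (`microsim_oracle()`, same
  event logic, random draws) are asserted in the test suite rather than
  assumed.

```{r}
cfg <- synth_config()
tr <- run_cohort(cfg, "lurasidone")
max(abs(apply(tr$occ_cls, 1, sum) - 1))
```

## Decisions on underdetermined points

Choices the source material left open, and how they were resolved:

- **Clock semantics for new non-adherents**: the time-since-stabilisation
  clock continues (advances to `u + 1`), it is not frozen; the non-adherent
  relapse curve is evaluated on the same clock.
- **Within-cycle event order**: relapse before discontinuation by default,
  with the opposite order available as a setting rather than hard-coded.
- **Dead-mass bookkeeping**: recorded at line 1; lines are attributes of
  living patients.
- **Clozapine unit cost 0.001 CN¥/mg**: transcribed as stated despite being
  implausibly low; it makes the augmented line's acquisition cost almost
  entirely risperidone's.
- **Inpatient length-of-stay by state**: acute 26.4 d, stable 3.8 d, relapse
  31 d.
- **Diabetes overlay granularity**: prevalence is tracked for the cohort as
  a whole (incidence weighted by on-treatment occupancy), not per line — an
  approximation that avoids a second tunnel dimension.

## Limitations

- The 12-month anchors for the baseline curves are assumptions; conclusions
  that hinge on small cost differences between closely priced strategies
  (lurasidone versus risperidone) are sensitive to them, and the package
  makes no claim to resolve that comparison's cost direction.
- The synthetic life table is a stylised Gompertz schedule, not an official
  national table.
- Diabetes is the only modelled long-term metabolic consequence, with no
  feedback on mortality or switching; weight gain and EPS affect only the
  acute trial cycle.
- Adherence is binary and absorbing within a line; partial adherence is not
  modelled.
- Parameter draws in the probabilistic analysis are independent; no
  correlation structure between, say, a drug's discontinuation and relapse
  hazard ratios is imposed.
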