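---
title: "Model structure, assumptions and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkcea)
```

This vignette is the package's own account of the science it implements:
what the model assumes, which conventions were fixed where the design was
genuinely open, and what the shipped parameter fixture does and does not
represent. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The cohort model

The model is a discrete-time Markov cohort simulation with a monthly cycle
and a lifetime horizon (default: until the cohort reaches age 100 or its
alive mass falls below `1e-4`). The population is advanced CKD patients at
risk of hyperkalaemia, all on a maximum RAASi dose at entry, 41.98% with
comorbid heart failure. The HF split is fixed at baseline — patients
without HF never develop it — so the cohort is carried as two independent
subcohorts sharing one Dead state.

Within a subcohort the state is factored as
CKD stage × potassium category × RAASi status × treatment exposure
(× NYHA class for the CKD+HF subcohort): 121 collapsed states for
CKD-only, 481 for CKD+HF. Occupancy is a mass vector over that product
space; every per-cycle operator acts on one axis at a time, which keeps
each factor's transition rows exactly stochastic (tested to 1e-12).

Key structural assumptions, all deliberate simplifications of the modelled
disease process:

* CKD progression is forward-only (no stage regression); ESRD comprises
  separate dialysis and transplant states; transplant failure is not
  modelled — the transplant state carries its own mortality only.
* The CKD and NYHA chains progress independently; for events (MACE,
  hospitalisation, death) the CKD-only and HF-only probabilities are
  estimated separately and the **maximum** of the two applies to CKD+HF
  patients.
* Hyperkalaemia is a recurrent monthly event with no persistence: the
  potassium category is re-drawn every cycle from the phase- and
  exposure-specific incidence row, and the residual probability returns
  the patient to normokalaemia. No resolution dynamics are modelled
  because none are specified for the underlying estimates.
* Effect modifiers are hazard ratios applied on the rate scale,
  `p' = 1 - (1-p)^{HR}`. This is the standard consistent mapping when
  effects are estimated on rates but the model works in per-cycle
  probabilities; it guarantees `p' ∈ [0,1)` for any positive HR.
* Background mortality is a floor, not an addend:
  `p_death = max(life-table monthly probability, modelled probability)`.
  The annual life-table `q` is blended across sexes by the proportion
  female, looked up at `floor(age)`, and converted by
  `1 - (1-q)^{1/12}`. Age advances by 1/12 per cycle.

## Within-cycle ordering

The source estimates do not pin an ordering of events inside a cycle, so
the package fixes one canonical convention and applies it everywhere
(cohort engine and microsimulation alike):

1. potassium category re-draw (this *is* the month's HK event);
2. RAASi transition given the new category (months ≥ 2; month 1 holds
   RAASi fixed pending treatment response);
3. treatment exposure update — the end-of-month-1 response split
   (60.93% responders), then from month 2 the 10.33% monthly
   discontinuation, forced stop at ESRD, and potassium-triggered
   re-treatment (≥ 5.5 mmol/l, applied to mass that started the step off
   treatment, so an exit lasts at least one cycle);
4. clinical events and transitions, using the *post-update* potassium and
   RAASi statuses for the modifiers: expected MACE/hospitalisations, then
   death, then CKD and NYHA chain moves for survivors. Mass entering ESRD
   has treatment switched off at entry.

Month 1 needed its own convention because the baseline potassium
distribution (81.35% at 5.5–6, 18.65% above 6) is prevalence from the
source trial while the month-1 incidence row is an event probability. The
package keeps the baseline categories as the month-1 state (they drive
cycle-1 modifiers; RAASi is held anyway) and counts/costs month-1 incident
events from the month-1 incidence row, which is identical across arms and
therefore cancels in every incremental result.

Accruals use the start-of-cycle convention: patients dying in a cycle
contribute that cycle's occupancy (life years, utilities, state costs)
before removal. Costs and QALYs for cycle *m* are discounted by
`(1 + r)^{-(m-1)/12}` with r = 0.035/year. An optional half-cycle
correction (`settings$half_cycle`) averages start- and end-of-cycle
occupancy for state-based accruals; it is off by default because the
monthly cycle makes it small relative to the structural uncertainties.

The expected per-cycle QALY increment is clamped at zero (with a warning)
if event disutilities exceed the utility mass — reachable only with
inconsistent user configurations, never with the fixture.

## Treatment dynamics

All treatment-arm patients receive patiromer for month 1. Responders
(60.93%) continue; non-responders move off treatment and incur
SoC-equivalent risks with no legacy effect. Off-treatment patients in the
treatment arm re-start in any month their potassium is ≥ 5.5 mmol/l
(unless in ESRD); re-treated patients re-enter at responder rates — the
response split is not re-applied, because repetition is specified but a
second stratification is not. There is no cap on re-treatment episodes,
and the patiromer drug cost recurs from the re-entry cycle. The
`tx.prop_raasi_m1.*` fields carry the (unpublished) share still on RAASi
at the end of month 1; the default of 1 reproduces the month-1 RAASi hold.

The package's exposure accountant (on-treatment mass at each cycle start,
summed) satisfies a closed-form check: with re-treatment disabled and
mortality/ESRD removed, mean months on treatment equal
`0.6093·(1 + 1/0.1033) + 0.3907·1`, and the test suite verifies this to
1e-6.

## The reference fixture: what it is and is not

`make_reference_fixture()` assembles the complete input set. Published
point estimates are carried verbatim with their printed standard errors
(the NYHA block, whose printed shares total 100.01%, is renormalised so
the starting distribution sums to one). Inputs published only in
supplementary appendices — baseline CKD/NYHA transition probabilities,
baseline MACE/hospitalisation/mortality, all effect-modifier magnitudes,
most costs, utilities and disutilities, and the life table — ship as
**placeholders**, flagged in the registry's `provenance` column and
tabulated in the README. They were chosen once for UK plausibility and to
respect the model's qualitative structure (RAASi protective for
progression/events/death and permissive for HK; harm increasing with
potassium; costs and disutilities increasing, utilities decreasing, with
disease severity), and they are deliberately not calibrated to any
published output.

Consequently the fixture emulates the *structure* of the study conditions,
not their exact levels. Passing tests demonstrate internal correctness —
conservation, stochasticity, closed-form accounting, engine/microsimulation
agreement, and the model's qualitative behaviour (patiromer averts HK
events and RAASi churn, adds drug cost, extends survival; HK-sweep losses
monotone and severity-ordered; optimal RAASi management never QALY-losing)
— but not agreement with any published absolute figure. Reproducing
published totals requires substituting the real appendix values through a
config file, which `load_parameters()` supports field-by-field.

Where SEs are not printed (the age-dependent ESRD inputs, the patiromer
subsequent-month RAASi columns, treatment response/discontinuation, the
3.51% return-to-optimal), the fixture assumes 10% of the mean, flagged
`se_assumed`; subsequent-month HK rows use the footnoted 10%-of-mean rule.
The synthetic life table is a Gompertz form by sex calibrated to the broad
magnitude of recent UK national tables and is clearly labelled synthetic.

Two bookkeeping conventions fill gaps in the published table layout: NYHA
state-management costs are folded into the CKD (disease-management) ledger
category, since the eight-category cost table has no HF line; and the
CKD+HF per-state utility is the **minimum** of the CKD-state and
NYHA-state utilities, a conservative combination chosen over the
multiplicative rule (the difference is second-order for the utility ranges
involved).

## Probabilistic and deterministic sensitivity analysis

PSA samples every uncertain scalar independently, moment-matched to its
(mean, SE): beta for probabilities, utilities and disutilities (method of
moments, `α = m·ν`, `β = (1-m)·ν`, `ν = m(1-m)/s² - 1`; infeasible
requests, `s² ≥ m(1-m)`, raise an error naming the parameter); gamma for
costs and hazard ratios (`shape = m²/s²`, `rate = m/s²`); normal for
demographics, with the sampled proportion female truncated to [0,1].
Zero-SE parameters are degenerate, so structural zeros stay exactly zero.
After sampling, each starting-distribution block is renormalised onto the
simplex and any HK severity triple or from-max RAASi pair exceeding one in
total is rescaled — a guard against rare joint tails, not a re-weighting
of the means. Draws are consumed in fixed registry order, making runs
bit-reproducible for a given seed. The default draw count is 1,000 (the
source analysis does not state its own); the CEAC reports the share of
draws with positive net monetary benefit per willingness-to-pay value.

The one-way analysis defaults to the inputs the base-case conclusions are
most sensitive to — discount rate (0–6%), horizon, baseline age, the
RAASi→CKD-progression modifier, RAASi and treatment discontinuation —
with default ranges of mean ± 1.96·SE clamped to each parameter's domain.

## Scenario engines

**HK-incidence sweep.** Evaluated on SoC inputs with all trial-phase
incidence rows zeroed; each curve sets one severity category's
subsequent-month probability to `1 - exp(-rate/12)` for annual rates on
[0, 0.5], and results are increments against the all-zero reference.
Because the engine is deterministic, rate-0 increments are exactly zero by
construction. The baseline potassium prevalence is common to every run and
cancels.

**Optimal-RAASi value grid.** 48 cells: age {40, 50, 60, 70} × starting
CKD stage {3, 4, 5; stage 5 pre-RRT} × HF status × management. "Optimal"
zeroes every discontinuation/down-titration probability so the cohort
stays at the maximum dose for life; "none" starts the cohort discontinued
with the return-to-optimal probability zeroed. The age-dependent ESRD
table (step function at the 40/50/60/70 knots, held from the nearest knot
at or below the current age; linear interpolation available via
`settings$age_rule`) drives transplant access and ESRD mortality.

## Validation design

The microsimulation oracle (`run_microsimulation()`) consumes the *same*
per-cycle probability builders as the cohort engine but propagates
individuals by sampling state transitions. MACE and hospitalisation — pure
events with no state consequence — and their costs/disutilities are
accrued in expectation given each realised path; this leaves every
estimator unbiased for the cohort expectation while removing needless
Monte-Carlo noise from the comparison. The acceptance suite runs 100,000
individuals at a fixed seed and requires agreement with the cohort engine
within three standard errors on discounted life years, QALYs, total cost
and all eleven tracked event counts.

Problem sizes used by the shipped tests were chosen to keep the default
suite brisk while leaving the checks statistically meaningful: 2,000
PSA-style draws for the demographic sampling check, 200 full-horizon PSA
draws for the acceptability-curve properties, the 100,000-individual
microsimulation for the engine comparison, and a six-point rate grid for
the sweep. `scripts/acceptance.R` uses 1,000 PSA draws.

## Known limitations

* Incident HF, CKD stage regression, transplant failure and
  therapy-attributable adverse events are out of scope by design.
* The placeholder inputs make absolute outputs indicative only; all
  value-level conclusions require appendix-sourced inputs.
* HK events carry no between-cycle persistence, so consequences of
  sustained hyperkalaemia beyond the monthly hazard structure are not
  captured.
* Cohort age and sex enter as cohort-level values (no heterogeneity
  beyond the factored states); the microsimulation inherits this.
* Event disutilities are one-off per event (not duration-weighted); the
  alternative would need event-duration inputs the model does not carry.
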