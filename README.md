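# hkcea

A Markov cohort cost-effectiveness model of hyperkalaemia (HK) management
with the potassium binder patiromer versus standard of care (SoC) in
advanced chronic kidney disease (CKD) patients with and without heart
failure (HF), from a UK payer perspective.

## Who this is for

Health-economic modellers and HTA analysts who need a tested,
config-driven implementation of a lifetime HK management model: to
reproduce and stress a published model structure, to re-run it with their
own (e.g. appendix-sourced or country-specific) inputs, or to study the
relationship between HK incidence, renin–angiotensin–aldosterone system
inhibitor (RAASi) enablement and lifetime outcomes.

## The model

A cohort enters at a mean age of 65.3 years, split once at baseline into a
CKD-only and a CKD+HF subcohort (no incident HF). Within a subcohort the
monthly-cycle state space is factored:

* **CKD chain** — CKD3 → CKD4 → CKD5 → end-stage renal disease (ESRD:
  dialysis and transplant as separate states), forward-only;
* **HF chain** — NYHA I–IV, adjacent moves both ways (CKD+HF subcohort
  only), progressing independently of the CKD chain;
* **potassium category** — ≤5, 5–5.5, 5.5–6, >6 mmol/l, re-drawn each cycle
  from phase- and exposure-specific incidence rows (trial-derived in months
  1–3, registry-derived rates thereafter);
* **RAASi status** — maximum dose, sub-maximal (no return to maximum),
  discontinued (monthly return-to-optimal probability 3.51%);
* **treatment exposure** — on patiromer (responders, 60.93% at the end of
  month 1) or off; responders discontinue at 10.33%/month from month 2,
  stop at ESRD, and re-start whenever potassium is ≥ 5.5 mmol/l.

One shared Dead state absorbs both chains. Events (MACE, any-cause
hospitalisation, death) are estimated separately from the CKD state and the
NYHA state and the **higher of the two probabilities** is applied for
CKD+HF patients. Hazard-ratio modifiers act on the rate scale,
`p' = 1 − (1 − p)^HR`: RAASi use protects progression/MACE/hospitalisation/
death and raises HK incidence; higher potassium raises MACE/hospitalisation/
death. Background all-cause mortality from a life table is a floor:
`p_death = max(1 − (1 − q_annual)^(1/12), p_modelled)`. Costs (2019–20 GBP,
eight ledger categories) and utilities accrue per cycle and are discounted
at 3.5%/year; the ICER is ΔCost/ΔQALY between arms.

Analyses: deterministic base case; probabilistic sensitivity analysis
(beta draws for probabilities/utilities, gamma for costs/hazard ratios,
normal for demographics; moment-matched to mean/SE) with a
cost-effectiveness acceptability curve; one-way sensitivity analysis; an
HK-incidence sweep (annual rate 0–0.5 per severity category, versus a
no-HK reference); and a lifetime optimal-RAASi value grid over baseline
age {40,50,60,70} × CKD stage {3,4,5} × HF status. A seeded
individual-level microsimulation validates the cohort engine.

## Inputs and provenance

There is no study dataset: every input is a model parameter, carried in a
single flat registry (`make_reference_fixture()`) and overridable from a
YAML/JSON config (`load_parameters()`; JSON Schema in `inst/schema/`).
Published point estimates (baseline cohort, HK incidence and RAASi tables,
treatment parameters, age-dependent ESRD inputs, HK event costs
£0/£223.11/£2,933.49, discount rate) are flagged `main-text`. Inputs that
the source publication relegates to supplementary appendices ship as
**documented placeholders** flagged `placeholder`, chosen once for UK
plausibility and to respect the model's ordering constraints:

| block | placeholder values (monthly unless noted) |
|---|---|
| CKD progression | 3→4: 0.006; 4→5: 0.008; 5→dialysis: 0.020 |
| NYHA worsening / improvement | 0.015/0.010/0.008 and 0.005/0.005/0.003 |
| MACE baseline | CKD3–5: 0.002/0.003/0.005; dialysis 0.008; transplant 0.003; NYHA I–IV: 0.004/0.006/0.010/0.020 |
| Hospitalisation baseline | CKD3–5: 0.008/0.012/0.020; dialysis 0.030; transplant 0.015; NYHA I–IV: 0.010/0.015/0.025/0.050 |
| Mortality baseline | CKD3–5: 0.0010/0.0015/0.0030; NYHA I–IV: 0.002/0.004/0.010/0.030 |
| RAASi effect (HR, sub-max / discontinued vs max) | CKD progression 1.30/1.60; MACE 1.25/1.50; hospitalisation 1.15/1.30; death 1.20/1.40; HK incidence 0.85/0.70 |
| Potassium effect (HR vs ≤5, by category) | MACE 1.10/1.30/1.60; hospitalisation 1.10/1.25/1.50; death 1.10/1.30/1.80 |
| State costs (GBP/month) | CKD3–5: 120/180/280; dialysis 2,800; transplant 350 (+17,000 at entry); NYHA I–IV: 100/150/250/400 |
| Event costs (GBP) | MACE 3,500; hospitalisation 2,500; RAASi titration change 150 |
| Drug costs (GBP/month) | patiromer 172.50; RAASi 1.50 (max) / 0.75 (sub-max) |
| Utilities | CKD3–5: 0.85/0.80/0.72; dialysis 0.60; transplant 0.74; NYHA I–IV: 0.82/0.74/0.64/0.50 |
| Event disutilities | HK 0.002/0.005/0.015 by severity; MACE 0.05; hospitalisation 0.01 |
| Life table | synthetic Gompertz UK-like table, ages 40–100 by sex (`make_life_table()`) |

Substitute real appendix values through a config file to reproduce the
published figures; with placeholders, absolute results differ but the
model's structural behaviour (signs, orderings, dominance patterns) is
meaningful and is what the test suite asserts.

## Worked example

```r
library(hkcea)
p <- make_reference_fixture()
traj_pat <- run_cohort(p, "patiromer")
traj_soc <- run_cohort(p, "soc")
cea <- compute_cea(traj_pat, traj_soc)
print(cea)
```

```
Cost-effectiveness comparison: patiromer vs soc 

                                patiromer          soc  incremental
  Total costs (disc, GBP)          82,397       81,938          458
    treatment                       1,578            0        1,578
    HK                                309          503         -195
    CKD                            22,268       21,909          359
    RRT                            49,676       50,804       -1,128
    MACE                            2,453        2,488          -35
    hospitalisation                 5,376        5,417          -41
    RAASi_drug                         87           75           12
    RAASi_titration                   650          742          -91
  Life years (disc)                 9.489        9.377        0.113
  QALYs (disc)                      7.059        6.962        0.097

  ICER (disc)   GBP 4,732 /QALY
  ICER (undisc) GBP 5,065 /QALY
  NMB at GBP 20,000/QALY: 1,479
```

Patiromer adds treatment cost up front, averts HK events and RAASi
titration churn (negative HK/RAASi-titration/RRT increments), and extends
discounted survival by 0.113 life years (0.097 QALYs), at £458 extra
discounted cost per patient under the placeholder fixture — a positive
ICER of £4,732/QALY. Supporting quantities:

```r
mean_treatment_duration(traj_pat)                  # 9.58 months on patiromer
events_per_1000(traj_pat, traj_soc, "hk_k_55_6")   # 220 HK events averted /1000
```

Further analyses follow the same pattern: `run_psa()` (CEAC via
`ceac_at()`/`plot()`), `run_owsa()` (tornado), `run_hk_sweep()`,
`run_raasi_value()`. A command-line wrapper with the same capabilities is
installed at `inst/cli/hkcea` (subcommands `validate`, `fixture`, `run`,
`psa`, `owsa`, `sweep-hk`, `raasi-value`).

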