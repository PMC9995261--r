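Package: hkcea
Title: Markov Cohort Cost-Effectiveness Model of Hyperkalaemia Management
    and RAASi Enablement in Chronic Kidney Disease
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A monthly-cycle Markov cohort model of hyperkalaemia (HK)
    management with the potassium binder patiromer versus standard of care
    in advanced chronic kidney disease (CKD) patients with and without
    heart failure (HF), from a UK payer perspective. The cohort progresses
    over a lifetime horizon through factored health states (CKD stage and
    end-stage renal disease, NYHA class, serum potassium category, RAASi
    dose status, treatment exposure), with life-table background mortality,
    discounted costs and quality-adjusted life years, and an incremental
    cost-effectiveness comparison. Includes probabilistic sensitivity
    analysis with a cost-effectiveness acceptability curve, one-way
    deterministic sensitivity analysis, a hyperkalaemia-incidence sweep,
    a lifetime optimal-RAASi value analysis over age/stage/HF strata, and
    a seeded individual-level microsimulation used to validate the cohort
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
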