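# Clinical progression: hazard-ratio application, ESRD age rules, CKD chain,
# combination rule, mortality floor.

test_that("hazard ratios act on the rate scale", {
  expect_equal(apply_modifier(0.10, 0.5), 1 - 0.9^0.5)  # 0.05131670...
  expect_equal(apply_modifier(0.25, 1), 0.25)
  expect_equal(apply_modifier(0, 3.7), 0)
  # monotone in the modifier
  hrs <- c(0.2, 0.5, 1, 1.5, 3)
  expect_true(all(diff(apply_modifier(0.1, hrs)) > 0))
})

test_that("CKD+HF event probabilities take the higher of the two chains", {
  expect_equal(combined_event_prob(0.03, 0.05), 0.05)
  expect_equal(combined_event_prob(0.05, 0.03), 0.05)
  expect_equal(combined_event_prob(0.04, 0.04), 0.04)
  expect_equal(combined_event_prob(0, 0.2), 0.2)
})

test_that("age-dependent ESRD parameters return the printed values at the knots", {
  knots <- list(
    `40` = c(0.0215, 0.0070, 0.0018, 0.0007),
    `50` = c(0.0168, 0.0055, 0.0037, 0.0018),
    `60` = c(0.0018, 0.0006, 0.0061, 0.0032),
    `70` = c(0.0018, 0.0006, 0.0123, 0.0055))
  for (a in names(knots)) {
    v <- esrd_params_for_age(as.numeric(a), fx)
    expect_equal(unname(v), knots[[a]], tolerance = 1e-15)
  }
  # default step rule holds the value from the knot at or below the age
  expect_equal(esrd_params_for_age(65, fx), esrd_params_for_age(60, fx))
  expect_equal(esrd_params_for_age(39, fx), esrd_params_for_age(40, fx))
  expect_equal(esrd_params_for_age(90, fx), esrd_params_for_age(70, fx))
  # linear rule interpolates midway
  pl <- fx; pl$settings$age_rule <- "linear"
  v45 <- esrd_params_for_age(45, pl)
  expect_equal(v45[["transplant_ckd5"]], (0.0215 + 0.0168) / 2)
})

test_that("CKD transition rows are distributions and honour modifiers", {
  for (state in c("CKD3", "CKD4", "CKD5", "Dialysis", "Transplant")) {
    for (r in c("MaxDose", "SubMaxDose", "Discontinued")) {
      pr <- ckd_transition_probs(state, 65, r, fx)
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      expect_true(all(pr >= 0))
    }
  }
  expect_equal(ckd_transition_probs("CKD5", 40, "MaxDose", fx)[["Transplant"]],
               0.0215)
  # identity modifier reproduces the baseline probability exactly
  p1 <- fx
  p1 <- set_param(p1, "mod.raasi.disc.ckd_prog", mean = 1)
  pr <- ckd_transition_probs("CKD3", 65, "Discontinued", p1)
  expect_equal(pr[["CKD4"]], get_param(fx, "prog.ckd3_to_ckd4"))
  # a worse RAASi status accelerates progression
  expect_gt(ckd_transition_probs("CKD3", 65, "Discontinued", fx)[["CKD4"]],
            ckd_transition_probs("CKD3", 65, "MaxDose", fx)[["CKD4"]])
  # no regression: mass only flows forward
  expect_equal(ckd_transition_probs("CKD4", 65, "MaxDose", fx)[["CKD3"]], 0)
})

test_that("mortality applies the life-table floor and the max rule", {
  # annual q -> monthly closed form
  expect_equal(annual_prob_to_monthly(0.0237), 1 - 0.9763^(1 / 12))
  expect_equal(annual_prob_to_monthly(0), 0)

  # modelled risk above the floor: modelled wins
  p <- fx
  p$life_table$qx <- 0.0237  # monthly floor 0.0019968
  p <- set_param(p, "ev.death.ckd3", mean = 0.004)
  expect_equal(mortality_prob("CKD3", NA, 65, "K_le5", "MaxDose", p), 0.004)
  # floor above the modelled risk: floor wins
  p2 <- set_param(p, "ev.death.ckd3", mean = 0.001)
  expect_equal(mortality_prob("CKD3", NA, 65, "K_le5", "MaxDose", p2),
               1 - 0.9763^(1 / 12))
  # monotone in both the life-table q and the modelled probability
  qs <- seq(0, 0.3, by = 0.05)
  floors <- vapply(qs, function(q) {
    pq <- p; pq$life_table$qx <- q
    mortality_prob("CKD3", NA, 65, "K_le5", "MaxDose", pq)
  }, numeric(1))
  expect_true(all(diff(floors) >= 0))
  mods <- vapply(seq(0.001, 0.05, length.out = 8), function(d) {
    pd <- set_param(p, "ev.death.ckd3", mean = d)
    mortality_prob("CKD3", NA, 65, "K_le5", "MaxDose", pd)
  }, numeric(1))
  expect_true(all(diff(mods) >= 0))

  # HF chain raises mortality through the max rule; potassium and RAASi
  # modifiers raise it further
  m_ckd <- mortality_prob("CKD3", NA, 65, "K_le5", "MaxDose", p)
  m_hf <- mortality_prob("CKD3", "NYHA_III", 65, "K_le5", "MaxDose", p)
  expect_gte(m_hf, m_ckd)
  expect_gt(mortality_prob("CKD3", NA, 65, "K_gt6", "Discontinued", p), m_ckd)
})

test_that("with neutral modifiers and no ESRD the CKD occupancy follows the pure chain", {
  p <- no_death(no_esrd(fx))
  for (nm in grep("^mod\\.raasi\\..*ckd_prog$", p$params$name, value = TRUE)) {
    p <- set_param(p, nm, mean = 1)
  }
  n_cyc <- 24
  tr <- run_cohort(p, "soc", horizon_age = get_param(p, "demo.age_mean") +
                     n_cyc / 12 + 1e-6)
  # oracle: direct matrix power of the baseline chain
  p34 <- get_param(p, "prog.ckd3_to_ckd4")
  p45 <- get_param(p, "prog.ckd4_to_ckd5")
  Tm <- matrix(c(1 - p34, p34, 0, 0, 0,
                 0, 1 - p45, p45, 0, 0,
                 0, 0, 1, 0, 0,
                 0, 0, 0, 1, 0,
                 0, 0, 0, 0, 1), 5, 5, byrow = TRUE)
  v <- c(0.5514, 0.4486, 0, 0, 0)
  for (i in seq_len(n_cyc)) v <- as.vector(v %*% Tm)
  expect_equal(unname(tr$ckd_trace[n_cyc, 1:5]), v, tolerance = 1e-12)
})
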