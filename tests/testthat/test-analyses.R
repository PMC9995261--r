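# Analyses: base case, PSA/CEAC, one-way DSA, HK sweep, RAASi value grid.

test_that("neutralised treatment effects collapse the base case to zero increments", {
  p <- neutralise_arms(fx)
  cea <- run_base_case(p, horizon_age = 80)
  expect_equal(cea$incremental[["cost_disc"]], 0, tolerance = 1e-9)
  expect_equal(cea$incremental[["qaly_disc"]], 0, tolerance = 1e-12)
  expect_true(all(abs(cea$events_diff_per_1000) < 1e-9))
})

test_that("PSA is seed-reproducible and degenerates to the base case with zero SEs", {
  p0 <- fx; p0$params$se[] <- 0
  psa0 <- run_psa(p0, n_draws = 3, seed = 4, horizon_age = 75)
  base <- run_base_case(p0, horizon_age = 75)
  expect_true(all(abs(psa0$d_cost - base$incremental[["cost_disc"]]) < 1e-9))
  expect_true(all(abs(psa0$d_qaly - base$incremental[["qaly_disc"]]) < 1e-12))
  # the CEAC is then a step function located at the base ICER
  expect_equal(unname(psa0$ceac[psa0$wtp_grid < base$icer]),
               rep(0, sum(psa0$wtp_grid < base$icer)))
  expect_equal(unname(psa0$ceac[psa0$wtp_grid > base$icer]),
               rep(1, sum(psa0$wtp_grid > base$icer)))

  psa1 <- run_psa(fx, n_draws = 10, seed = 21, horizon_age = 75)
  psa2 <- run_psa(fx, n_draws = 10, seed = 21, horizon_age = 75)
  expect_identical(psa1$d_cost, psa2$d_cost)
  expect_identical(psa1$ceac, psa2$ceac)
  expect_true(all(psa1$ceac >= 0 & psa1$ceac <= 1))
  # CEAC at unbounded willingness-to-pay tends to the share of QALY-gaining draws
  expect_equal(ceac_at(psa1, 1e12), mean(psa1$d_qaly > 0))
})

test_that("one-way sensitivity analysis spans and degenerate parameters behave", {
  p <- set_param(fx, "tx.response", se = 0)
  ow <- run_owsa(p, param_ranges = list(
    "econ.discount_annual" = c(0, 0.06),
    "tx.response" = NULL), horizon_age = 80)
  tab <- ow$table
  # zero-SE parameter: zero span
  expect_equal(tab$span[tab$parameter == "tx.response"], 0)
  # discounting: the two ICERs bracket the base value
  dr <- tab[tab$parameter == "econ.discount_annual", ]
  expect_gt(dr$span, 0)
  expect_gte(ow$base_icer, min(dr$icer_low, dr$icer_high))
  expect_lte(ow$base_icer, max(dr$icer_low, dr$icer_high))
})

test_that("HK sweep increments are zero at rate 0, monotone and severity-ordered", {
  sw <- run_hk_sweep(fx, rates = c(0, 0.25, 0.5), horizon_age = 80)
  tab <- sw$table
  z <- tab[tab$annual_rate == 0, ]
  expect_true(all(z$d_cost == 0 & z$d_qaly == 0 & z$d_ly == 0))
  for (cat_ in unique(tab$category)) {
    s <- tab[tab$category == cat_, ]
    s <- s[order(s$annual_rate), ]
    expect_true(all(diff(s$d_qaly) <= 1e-12))  # QALY losses grow with the rate
  }
  at5 <- tab[tab$annual_rate == 0.5, ]
  loss <- -at5$d_qaly[match(c("K_5_55", "K_55_6", "K_gt6"), at5$category)]
  expect_true(all(diff(loss) >= 0))  # more severe events lose more QALYs
  # severe events add net cost through their management cost
  expect_gt(at5$d_cost[at5$category == "K_gt6"], 0)
})

test_that("optimal RAASi management never loses QALYs and neutral modifiers collapse it", {
  rv <- run_raasi_value(fx, ages = c(40, 70), stages = c(3, 5),
                        hf = c(TRUE, FALSE))
  g <- raasi_value_gains(rv)
  expect_equal(nrow(g), 8L)
  expect_true(all(g$qaly_gain >= 0))

  # with all RAASi effect modifiers neutral the two strategies coincide on
  # health outcomes
  p1 <- fx
  for (nm in grep("^mod\\.raasi\\.", p1$params$name, value = TRUE)) {
    p1 <- set_param(p1, nm, mean = 1)
  }
  a <- run_cohort(p1, "soc", raasi_override = "optimal", horizon_age = 75)
  b <- run_cohort(p1, "soc", raasi_override = "none", horizon_age = 75)
  expect_equal(sum(a$qaly_disc), sum(b$qaly_disc), tolerance = 1e-12)
  expect_equal(sum(a$ly_disc), sum(b$ly_disc), tolerance = 1e-12)
})

test_that("age-dependent ESRD inputs drive the value analysis at the right knots", {
  # a 70-year-old cohort pinned to dialysis experiences the printed monthly
  # dialysis mortality when it exceeds the life-table floor
  p <- degenerate_start(fx)
  p <- set_param(p, "demo.age_mean", mean = 70, se = 0)
  p <- set_param(p, "start.ckd3", mean = 0, se = 0)
  p <- set_param(p, "start.ckd5", mean = 1, se = 0)
  p <- set_param(p, "prog.ckd5_to_dialysis", mean = 1)  # into dialysis at once
  p <- set_param(p, "esrd.transplant_ckd5.a70", mean = 0)
  p <- set_param(p, "esrd.transplant_dial.a70", mean = 0)
  for (nm in grep("^mod\\..*death$", p$params$name, value = TRUE)) {
    p <- set_param(p, nm, mean = 1)
  }
  tr <- run_cohort(p, "soc", horizon_age = 72)
  # cycle 2 starts with everyone on dialysis; survival over cycle 2 is
  # 1 - max(life-table floor, 0.0123) = 1 - 0.0123 at age 70
  expect_equal(tr$alive[3] / tr$alive[2], 1 - 0.0123, tolerance = 1e-9)
})
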