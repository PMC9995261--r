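# Cohort engine: conservation, limits, accumulators, microsimulation
# agreement at small n.

test_that("mass is conserved and Dead is absorbing at every cycle", {
  for (arm in c("patiromer", "soc")) {
    tr <- run_cohort(fx, arm, horizon_age = 85)
    totals <- rowSums(tr$ckd_trace)
    expect_true(all(abs(totals - 1) < 1e-12))
    expect_true(all(diff(tr$ckd_trace[, "Dead"]) >= 0))
    expect_true(all(diff(tr$alive) <= 1e-12))
    expect_true(all(tr$ckd_trace >= -1e-15))
  }
})

test_that("forcing certain death at cycle 1 yields one twelfth of a life year", {
  p <- fx
  p$life_table$qx <- 1
  tr <- run_cohort(p, "soc")
  expect_equal(tr$n_cycles, 1L)
  expect_equal(sum(tr$ly), 1 / 12)
  expect_lte(sum(tr$qaly), sum(tr$ly))
})

test_that("with unit utility, no mortality and no discounting QALYs equal life years", {
  p <- no_death(fx)
  for (nm in grep("^util\\.state\\.", p$params$name, value = TRUE)) {
    p <- set_param(p, nm, mean = 1)
  }
  for (nm in grep("^disutil\\.", p$params$name, value = TRUE)) {
    p <- set_param(p, nm, mean = 0)
  }
  p <- set_param(p, "econ.discount_annual", mean = 0)
  tr <- run_cohort(p, "soc", horizon_age = 70)
  expect_equal(sum(tr$ly), tr$n_cycles / 12)
  expect_equal(sum(tr$qaly), sum(tr$ly))
  expect_equal(sum(tr$qaly_disc), sum(tr$qaly))
  expect_equal(tr$n_cycles, 57L)  # months with start age below 70
})

test_that("zero discounting reproduces the undiscounted accumulators exactly", {
  p0 <- set_param(fx, "econ.discount_annual", mean = 0)
  tr <- run_cohort(p0, "patiromer", horizon_age = 80)
  expect_identical(tr$ledger, tr$ledger_disc)
  expect_identical(tr$ly, tr$ly_disc)
  expect_identical(tr$qaly, tr$qaly_disc)
})

test_that("the engine is deterministic", {
  t1 <- run_cohort(fx, "patiromer", horizon_age = 80)
  t2 <- run_cohort(fx, "patiromer", horizon_age = 80)
  expect_identical(t1$ledger, t2$ledger)
  expect_identical(t1$events, t2$events)
})

test_that("event differences per 1,000 match a hand-computed degenerate model", {
  a <- run_cohort(fx, "patiromer", horizon_age = 75)
  expect_equal(events_per_1000(a, a, "hk_k_55_6"), 0)

  # no mortality, neutral RAASi->HK modifiers, HK only in the SoC
  # subsequent-month K>6 row: the SoC arm accrues exactly 0.01 expected
  # events per cycle from cycle 4 on
  p <- no_esrd(no_death(zero_hk_rows(degenerate_start(fx))))
  p <- set_param(p, "hk.sub.soc.k_gt6", mean = 0.01)
  p <- set_param(p, "mod.raasi.submax.hk", mean = 1)
  p <- set_param(p, "mod.raasi.disc.hk", mean = 1)
  # keep the treatment arm fully exposed so its zeroed patiromer rows apply
  # to everyone (off-treatment mass would otherwise incur SoC rates)
  p <- set_param(p, "tx.response", mean = 1)
  p <- set_param(p, "tx.disc_monthly", mean = 0)
  b <- run_cohort(p, "soc", horizon_age = 67)
  a2 <- run_cohort(p, "patiromer", horizon_age = 67)
  expect_equal(sum(b$events[, "hk_k_gt6"]), 0.01 * (b$n_cycles - 3),
               tolerance = 1e-12)
  expect_equal(events_per_1000(a2, b, "hk_k_gt6"),
               1000 * 0.01 * (b$n_cycles - 3), tolerance = 1e-9)
})

test_that("patiromer reduces cumulative HK events at 5.5 mmol/l and above", {
  a <- run_cohort(fx, "patiromer")
  b <- run_cohort(fx, "soc")
  expect_lte(sum(a$events[, "hk_k_55_6"]), sum(b$events[, "hk_k_55_6"]))
  expect_lte(sum(a$events[, "hk_k_gt6"]), sum(b$events[, "hk_k_gt6"]))
})

test_that("trajectory summaries and exports are consistent", {
  tr <- run_cohort(fx, "patiromer", horizon_age = 75)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), tr$n_cycles)
  expect_equal(sum(df$ly), sum(tr$ly))
  s <- summary(tr)
  expect_equal(s$cost_disc, sum(tr$ledger_disc))
  dir <- file.path(tempdir(), "traj")
  paths <- write_trajectory(tr, dir)
  expect_true(all(file.exists(file.path(dir, c("trajectory_patiromer.csv",
                                               "trajectory_patiromer_summary.json")))))
  js <- jsonlite::read_json(file.path(dir, "trajectory_patiromer_summary.json"))
  expect_equal(js$ly_disc, sum(tr$ly_disc), tolerance = 1e-9)
})

test_that("a fully degenerate path gives identical cohort and microsimulation results", {
  p <- no_death(zero_hk_rows(degenerate_start(fx)))
  p <- set_param(p, "tx.response", mean = 1)
  p <- set_param(p, "tx.disc_monthly", mean = 0)
  p <- set_param(p, "prog.ckd3_to_ckd4", mean = 0)
  for (nm in grep("^raasi\\.(m23|sub)\\.", p$params$name, value = TRUE)) {
    p <- set_param(p, nm, mean = 0)
  }
  p <- set_param(p, "raasi.return_to_max", mean = 0)
  tr <- run_cohort(p, "patiromer", horizon_age = 70)
  ms <- run_microsimulation(p, "patiromer", n = 1, seed = 5, horizon_age = 70)
  expect_equal(unname(ms$mean[["ly_disc"]]), sum(tr$ly_disc), tolerance = 1e-12)
  expect_equal(unname(ms$mean[["qaly_disc"]]), sum(tr$qaly_disc), tolerance = 1e-12)
  expect_equal(unname(ms$mean[["cost_disc"]]), sum(tr$ledger_disc), tolerance = 1e-9)
})

test_that("microsimulation is seed-reproducible and agrees with the cohort at small n", {
  m1 <- run_microsimulation(fx, "patiromer", n = 500, seed = 99, horizon_age = 80)
  m2 <- run_microsimulation(fx, "patiromer", n = 500, seed = 99, horizon_age = 80)
  expect_identical(m1$ly_disc, m2$ly_disc)
  expect_identical(m1$events, m2$events)

  n <- 4000
  ms <- run_microsimulation(fx, "patiromer", n = n, seed = 31, horizon_age = 85)
  tr <- run_cohort(fx, "patiromer", horizon_age = 85)
  # smoke-level agreement; the rigorous 3-SE check at large n runs in the
  # acceptance suite
  expect_lt(abs(ms$mean[["ly_disc"]] - sum(tr$ly_disc)) / ms$se[["ly_disc"]], 4)
  expect_lt(abs(ms$mean[["qaly_disc"]] - sum(tr$qaly_disc)) / ms$se[["qaly_disc"]], 4)
  expect_lt(abs(ms$mean[["cost_disc"]] - sum(tr$ledger_disc)) / ms$se[["cost_disc"]], 4)
})
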