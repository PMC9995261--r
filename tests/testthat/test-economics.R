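# Discounting, cycle economics, and the CEA comparison.

test_that("discount factors follow the annual-rate closed form", {
  expect_equal(discount_factor(0), 1)
  expect_equal(discount_factor(12, 0.035), 1 / 1.035)
  expect_equal(discount_factor(24, 0.035), 1 / 1.035^2)
  expect_equal(discount_factor(7, 0), 1)
  expect_true(all(diff(discount_factor(0:120, 0.035)) < 0))
})

test_that("single-cycle economics matches hand arithmetic on a one-state cohort", {
  p <- degenerate_start(fx)
  co <- build_initial_cohort(p, "soc")
  ce <- cycle_economics(co, c(hk_k_gt6 = 1), p, month = 1)

  # one expected severe HK event charges its printed management cost
  expect_equal(ce$ledger[["HK"]], 2933.49)
  # state costs: whole cohort in CKD3 on maximum-dose RAASi, off treatment
  expect_equal(ce$ledger[["CKD"]], get_param(p, "cost.state.ckd3"))
  expect_equal(ce$ledger[["RAASi_drug"]], get_param(p, "cost.drug.raasi_max"))
  expect_equal(ce$ledger[["treatment"]], 0)
  expect_equal(ce$ledger[["RRT"]], 0)
  expect_equal(ce$ly, 1 / 12)
  expect_equal(ce$qaly,
               get_param(p, "util.state.ckd3") / 12 -
                 get_param(p, "disutil.event.hk.k_gt6"))
  # month 1 is undiscounted
  expect_equal(ce$ledger_disc, ce$ledger)
  # later cycles discount at the cycle-start factor
  ce13 <- cycle_economics(co, c(hk_k_gt6 = 1), p, month = 13)
  expect_equal(unname(ce13$ledger_disc[["HK"]]), 2933.49 / 1.035)

  # zero occupancy: all-zero ledger
  co0 <- co
  co0$occ$ckd_only[] <- 0
  co0$occ$ckd_hf[] <- 0
  ce0 <- cycle_economics(co0, c(mace = 0), p, month = 1)
  expect_true(all(ce0$ledger == 0))
  expect_equal(ce0$ly, 0)
})

test_that("ledger categories account for the total cost and discounting never inflates", {
  tr <- run_cohort(fx, "patiromer", horizon_age = 85)
  expect_equal(sum(colSums(tr$ledger)), sum(tr$ledger), tolerance = 1e-9)
  expect_true(all(colSums(tr$ledger_disc) <= colSums(tr$ledger) + 1e-9))
  expect_lte(sum(tr$ly_disc), sum(tr$ly))
  expect_lte(sum(tr$qaly_disc), sum(tr$qaly))
  expect_true(all(tr$ledger >= 0))
})

test_that("CEA arithmetic, dominance labels and antisymmetry", {
  a <- run_cohort(fx, "patiromer", horizon_age = 80)
  b <- run_cohort(fx, "soc", horizon_age = 80)
  cea <- compute_cea(a, b, wtp = 20000)
  # ICER = incremental cost / incremental QALY by construction
  expect_equal(cea$icer,
               cea$incremental[["cost_disc"]] / cea$incremental[["qaly_disc"]])
  expect_equal(cea$nmb,
               20000 * cea$incremental[["qaly_disc"]] - cea$incremental[["cost_disc"]])
  # arm swap negates incrementals and the NMB
  cea_r <- compute_cea(b, a, wtp = 20000)
  expect_equal(cea_r$incremental[["cost_disc"]], -cea$incremental[["cost_disc"]])
  expect_equal(cea_r$incremental[["qaly_disc"]], -cea$incremental[["qaly_disc"]])
  expect_equal(cea_r$nmb, -cea$nmb)
  expect_equal(cea_r$icer, cea$icer)  # ratio is swap-invariant

  df <- as.data.frame(cea)
  expect_equal(df$incremental[df$quantity == "ICER (disc, GBP/QALY)"], cea$icer)

  # dominance labelling on synthetic totals
  mk <- function(cost, qaly) {
    t0 <- a
    sc <- cost / sum(t0$ledger_disc)
    t0$ledger <- t0$ledger * sc; t0$ledger_disc <- t0$ledger_disc * sc
    sq <- qaly / sum(t0$qaly_disc)
    t0$qaly <- t0$qaly * sq; t0$qaly_disc <- t0$qaly_disc * sq
    t0
  }
  expect_equal(compute_cea(mk(1000, 2), mk(2000, 1))$dominance, "dominant")
  expect_equal(compute_cea(mk(2000, 1), mk(1000, 2))$dominance, "dominated")
  expect_equal(compute_cea(mk(2000, 2), mk(1000, 1))$dominance, "tradeoff")
})
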