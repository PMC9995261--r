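# Costs, utilities, discounting, and the incremental cost-effectiveness
# comparison between arms.

#' Discount factor at a cycle start
#'
#' Costs and QALYs accrued in cycle `month + 1` are discounted by the factor
#' at the cycle start: `(1 + annual_rate)^(-month/12)`.
#'
#' @param month Completed months at the cycle start (>= 0).
#' @param annual_rate Annual discount rate (default 3.5%).
#' @return Discount factor(s) in (0, 1\].
#' @export
discount_factor <- function(month, annual_rate = 0.035) {
  stopifnot(all(month >= 0))
  (1 + annual_rate)^(-month / 12)
}

#' Single-cycle economics for a cohort snapshot
#'
#' Computes the eight-category cost ledger, the QALY accrual and the
#' life-year accrual for one monthly cycle, given a cohort occupancy and the
#' cycle's expected event counts. State costs and utilities apply to the
#' occupancy; event costs and disutilities to the expected events; both are
#' returned raw and discounted at the cycle-start factor. A negative
#' computed QALY increment (event disutilities exceeding the utility mass,
#' which signals an inconsistent configuration) is clamped at zero with a
#' warning.
#'
#' @param cohort An `hk_cohort`.
#' @param events Named numeric vector of expected event counts for the cycle
#'   (any subset of the tracked kinds; missing kinds count as zero).
#' @param p An `hk_params` object.
#' @param month Cycle index (>= 1); the discount factor is indexed at
#'   `month - 1`.
#' @return List with `ledger` and `ledger_disc` (named by ledger category),
#'   `qaly`, `ly`, `qaly_disc`, `ly_disc`.
#' @export
cycle_economics <- function(cohort, events, p, month) {
  stopifnot(inherits(cohort, "hk_cohort"), month >= 1)
  ei <- .engine_inputs(p)
  st <- list(ckd_only = .static_cells(ei, 1L), ckd_hf = .static_cells(ei, 4L))
  ev <- stats::setNames(numeric(length(EVENT_KINDS)), EVENT_KINDS)
  ev[names(events)] <- events

  occv <- lapply(cohort$occ, as.vector)
  dot <- function(field) {
    sum(occv$ckd_only * st$ckd_only[[field]]) +
      sum(occv$ckd_hf * st$ckd_hf[[field]])
  }
  alive <- sum(occv$ckd_only) + sum(occv$ckd_hf)
  hk_ev <- ev[c("hk_k_5_55", "hk_k_55_6", "hk_k_gt6")]

  ledger <- c(
    treatment = dot("on_cell") * ei$c_patiromer,
    HK = sum(hk_ev * ei$c_hk),
    CKD = dot("c_ckd_cell"),
    RRT = dot("c_rrt_cell") + ev[["transplant_entry"]] * ei$c_transplant_entry,
    MACE = ev[["mace"]] * ei$c_mace,
    hospitalisation = ev[["hospitalisation"]] * ei$c_hosp,
    RAASi_drug = dot("c_raasi_cell"),
    RAASi_titration = (ev[["raasi_discontinuation"]] +
                         ev[["raasi_downtitration"]] +
                         ev[["raasi_return"]]) * ei$c_raasi_change)

  ly <- alive / 12
  qaly <- dot("u_cell") / 12 - sum(hk_ev * ei$du_hk) -
    ev[["mace"]] * ei$du_mace - ev[["hospitalisation"]] * ei$du_hosp
  if (qaly < 0) {
    warning("negative QALY increment clamped at 0 (disutilities exceed ",
            "utility mass; check the configuration)")
    qaly <- 0
  }
  df <- discount_factor(month - 1, ei$discount)
  list(ledger = ledger, ledger_disc = ledger * df,
       qaly = qaly, ly = ly, qaly_disc = qaly * df, ly_disc = ly * df)
}

#' Incremental cost-effectiveness comparison
#'
#' Pairs two arm trajectories (run on the same parameter set and horizon
#' rule) into per-arm totals, incrementals, the ICER with dominance
#' handling, and the net monetary benefit at a willingness-to-pay threshold.
#'
#' @param a Intervention-arm `hk_trajectory` (conventionally patiromer).
#' @param b Comparator-arm `hk_trajectory` (conventionally SoC).
#' @param wtp Willingness-to-pay threshold, GBP per QALY.
#' @return Object of class `hk_cea`.
#' @export
compute_cea <- function(a, b, wtp = 20000) {
  stopifnot(inherits(a, "hk_trajectory"), inherits(b, "hk_trajectory"))
  tot <- function(x) {
    c(cost = sum(x$ledger), cost_disc = sum(x$ledger_disc),
      ly = sum(x$ly), ly_disc = sum(x$ly_disc),
      qaly = sum(x$qaly), qaly_disc = sum(x$qaly_disc))
  }
  ta <- tot(a); tb <- tot(b)
  d_cost <- ta[["cost_disc"]] - tb[["cost_disc"]]
  d_qaly <- ta[["qaly_disc"]] - tb[["qaly_disc"]]
  d_cost_u <- ta[["cost"]] - tb[["cost"]]
  d_qaly_u <- ta[["qaly"]] - tb[["qaly"]]

  label <- if (d_qaly > 0 && d_cost <= 0) "dominant"
    else if (d_qaly < 0 && d_cost >= 0) "dominated"
    else "tradeoff"
  icer <- if (d_qaly != 0) d_cost / d_qaly else NA_real_
  icer_undisc <- if (d_qaly_u != 0) d_cost_u / d_qaly_u else NA_real_

  structure(list(
    arms = c(a = a$arm, b = b$arm),
    totals = rbind(a = ta, b = tb),
    ledger_disc = rbind(a = colSums(a$ledger_disc), b = colSums(b$ledger_disc)),
    ledger = rbind(a = colSums(a$ledger), b = colSums(b$ledger)),
    incremental = c(cost = d_cost_u, cost_disc = d_cost,
                    ly = ta[["ly"]] - tb[["ly"]],
                    ly_disc = ta[["ly_disc"]] - tb[["ly_disc"]],
                    qaly = d_qaly_u, qaly_disc = d_qaly),
    icer = icer, icer_undisc = icer_undisc, dominance = label,
    wtp = wtp, nmb = wtp * d_qaly - d_cost,
    events_diff_per_1000 = vapply(EVENT_KINDS, function(k)
      events_per_1000(a, b, k), numeric(1))),
    class = "hk_cea")
}

#' @export
print.hk_cea <- function(x, ...) {
  cat("Cost-effectiveness comparison:", x$arms["a"], "vs", x$arms["b"], "\n\n")
  fmt <- function(v) formatC(v, format = "f", digits = 3, big.mark = ",")
  fm0 <- function(v) formatC(v, format = "f", digits = 0, big.mark = ",")
  cat(sprintf("  %-26s %12s %12s %12s\n", "", x$arms["a"], x$arms["b"], "incremental"))
  cat(sprintf("  %-26s %12s %12s %12s\n", "Total costs (disc, GBP)",
              fm0(x$totals["a", "cost_disc"]), fm0(x$totals["b", "cost_disc"]),
              fm0(x$incremental[["cost_disc"]])))
  for (nm in colnames(x$ledger_disc)) {
    cat(sprintf("    %-24s %12s %12s %12s\n", nm,
                fm0(x$ledger_disc["a", nm]), fm0(x$ledger_disc["b", nm]),
                fm0(x$ledger_disc["a", nm] - x$ledger_disc["b", nm])))
  }
  cat(sprintf("  %-26s %12s %12s %12s\n", "Life years (disc)",
              fmt(x$totals["a", "ly_disc"]), fmt(x$totals["b", "ly_disc"]),
              fmt(x$incremental[["ly_disc"]])))
  cat(sprintf("  %-26s %12s %12s %12s\n", "QALYs (disc)",
              fmt(x$totals["a", "qaly_disc"]), fmt(x$totals["b", "qaly_disc"]),
              fmt(x$incremental[["qaly_disc"]])))
  if (x$dominance == "tradeoff") {
    cat(sprintf("\n  ICER (disc)   GBP %s /QALY\n", fm0(x$icer)))
    cat(sprintf("  ICER (undisc) GBP %s /QALY\n", fm0(x$icer_undisc)))
  } else {
    cat("\n  Dominance:", x$dominance, "\n")
  }
  cat(sprintf("  NMB at GBP %s/QALY: %s\n", fm0(x$wtp), fm0(x$nmb)))
  invisible(x)
}

#' Table-shaped CEA results
#'
#' @param x An `hk_cea`.
#' @param ... Unused.
#' @return A data.frame shaped like a standard cost-effectiveness results
#'   table: discounted cost categories, totals, LY, QALY, and ICERs for both
#'   arms plus the incremental column.
#' @export
as.data.frame.hk_cea <- function(x, ...) {
  rows <- list(
    c("Total costs (disc)", x$totals["a", "cost_disc"],
      x$totals["b", "cost_disc"], x$incremental[["cost_disc"]]))
  for (nm in colnames(x$ledger_disc)) {
    rows[[length(rows) + 1L]] <- c(nm, x$ledger_disc["a", nm],
                                   x$ledger_disc["b", nm],
                                   x$ledger_disc["a", nm] - x$ledger_disc["b", nm])
  }
  rows <- c(rows, list(
    c("Life years (disc)", x$totals["a", "ly_disc"], x$totals["b", "ly_disc"],
      x$incremental[["ly_disc"]]),
    c("QALYs (disc)", x$totals["a", "qaly_disc"], x$totals["b", "qaly_disc"],
      x$incremental[["qaly_disc"]]),
    c("ICER (disc, GBP/QALY)", NA, NA, x$icer),
    c("Total costs (undisc)", x$totals["a", "cost"], x$totals["b", "cost"],
      x$incremental[["cost"]]),
    c("QALYs (undisc)", x$totals["a", "qaly"], x$totals["b", "qaly"],
      x$incremental[["qaly"]]),
    c("ICER (undisc, GBP/QALY)", NA, NA, x$icer_undisc)))
  out <- data.frame(
    quantity = vapply(rows, `[`, character(1), 1),
    a = as.numeric(vapply(rows, `[`, character(1), 2)),
    b = as.numeric(vapply(rows, `[`, character(1), 3)),
    incremental = as.numeric(vapply(rows, `[`, character(1), 4)))
  names(out)[2:3] <- unname(x$arms)
  out
}
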