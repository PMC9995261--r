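# Result-generating analyses: base case, probabilistic and one-way
# deterministic sensitivity analyses, the HK-incidence sweep, and the
# lifetime optimal-RAASi value grid.

#' Base-case cost-effectiveness analysis
#'
#' Runs the cohort model for both arms on one parameter set and compares
#' them.
#'
#' @param p An `hk_params` object.
#' @param wtp Willingness-to-pay threshold for the net monetary benefit.
#' @param ... Passed to [run_cohort()] (e.g. `horizon_age`).
#' @return An `hk_cea`.
#' @export
run_base_case <- function(p, wtp = 20000, ...) {
  a <- run_cohort(p, "patiromer", ...)
  b <- run_cohort(p, "soc", ...)
  compute_cea(a, b, wtp = wtp)
}

#' Probabilistic sensitivity analysis
#'
#' Repeatedly samples the parameter set (beta for probabilities/utilities,
#' gamma for costs/hazard ratios, normal for demographics; see
#' [sample_parameters()]), reruns both arms per draw, and summarises the
#' incremental cost/QALY cloud as a cost-effectiveness acceptability curve:
#' the share of draws with positive net monetary benefit at each
#' willingness-to-pay value. Draws whose sampled set is infeasible for
#' moment matching are skipped and counted.
#'
#' @param p Base `hk_params`.
#' @param n_draws Number of PSA draws.
#' @param seed Integer seed (all randomness flows from it).
#' @param wtp_grid Willingness-to-pay grid for the CEAC (GBP/QALY).
#' @param ... Passed to [run_cohort()].
#' @return Object of class `hk_psa`: per-draw incrementals, the CEAC, seed,
#'   draw counts.
#' @export
run_psa <- function(p, n_draws = 1000, seed, wtp_grid = seq(0, 50000, 2500),
                    ...) {
  stopifnot(n_draws >= 1)
  set.seed(seed)
  d_cost <- d_qaly <- numeric(n_draws)
  skipped <- 0L
  for (i in seq_len(n_draws)) {
    pi_ <- tryCatch(sample_parameters(p), error = function(e) NULL)
    if (is.null(pi_)) { skipped <- skipped + 1L; d_cost[i] <- NA; d_qaly[i] <- NA; next }
    a <- run_cohort(pi_, "patiromer", ...)
    b <- run_cohort(pi_, "soc", ...)
    d_cost[i] <- sum(a$ledger_disc) - sum(b$ledger_disc)
    d_qaly[i] <- sum(a$qaly_disc) - sum(b$qaly_disc)
  }
  ok <- !is.na(d_qaly)
  ceac <- vapply(wtp_grid, function(w) {
    mean(w * d_qaly[ok] - d_cost[ok] > 0)
  }, numeric(1))
  structure(list(d_cost = d_cost, d_qaly = d_qaly,
                 wtp_grid = wtp_grid, ceac = ceac,
                 n_draws = n_draws, n_skipped = skipped, seed = seed),
            class = "hk_psa")
}

#' Probability of cost-effectiveness at a threshold
#' @param x An `hk_psa`.
#' @param wtp Willingness-to-pay value (GBP/QALY).
#' @return Share of (non-skipped) draws with positive net monetary benefit.
#' @export
ceac_at <- function(x, wtp) {
  stopifnot(inherits(x, "hk_psa"))
  ok <- !is.na(x$d_qaly)
  mean(wtp * x$d_qaly[ok] - x$d_cost[ok] > 0)
}

#' @export
print.hk_psa <- function(x, ...) {
  cat("<hk_psa>", x$n_draws, "draws (", x$n_skipped, "skipped ), seed",
      x$seed, "\n")
  cat(sprintf("  mean dCost %0.0f, mean dQALY %0.4f\n",
              mean(x$d_cost, na.rm = TRUE), mean(x$d_qaly, na.rm = TRUE)))
  for (w in c(20000, 30000)) {
    cat(sprintf("  P(cost-effective at GBP %d/QALY) = %.3f\n", w, ceac_at(x, w)))
  }
  invisible(x)
}

#' @export
plot.hk_psa <- function(x, which = c("ceac", "plane"), ...) {
  which <- match.arg(which)
  if (which == "ceac") {
    graphics::plot(x$wtp_grid, x$ceac, type = "l", lwd = 2, ylim = c(0, 1),
                   xlab = "Willingness to pay (GBP/QALY)",
                   ylab = "Probability cost-effective",
                   main = "Cost-effectiveness acceptability curve", ...)
    graphics::abline(h = c(0, 1), col = "grey80", lty = 3)
  } else {
    graphics::plot(x$d_qaly, x$d_cost, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.4),
                   xlab = "Incremental QALYs", ylab = "Incremental cost (GBP)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey60")
  }
  invisible(x)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the base-case ICER with each listed parameter set to a low
#' and a high value, all else held at base. The default range for a
#' registry parameter is mean ± 1.96·SE clamped to its valid domain;
#' explicit ranges override. The special name `"@horizon_age"` varies the
#' horizon setting. Parameters whose range collapses (zero SE and no
#' explicit range) report a zero span; invalid ranges are skipped and
#' flagged.
#'
#' @param p Base `hk_params`.
#' @param param_ranges Named list: each element either `NULL` (use the
#'   default ± 1.96·SE range) or `c(low, high)`. Defaults to the most
#'   influential model inputs: discount rate, horizon, baseline age, the
#'   RAASi CKD-progression modifier, RAASi discontinuation and treatment
#'   discontinuation/response.
#' @param wtp Willingness-to-pay for the NMB column.
#' @param ... Passed to [run_cohort()].
#' @return Object of class `hk_owsa`: a tornado table sorted by ICER span.
#' @export
run_owsa <- function(p, param_ranges = NULL, wtp = 20000, ...) {
  if (is.null(param_ranges)) {
    param_ranges <- list(
      "econ.discount_annual" = c(0, 0.06),
      "@horizon_age" = c(80, 100),
      "demo.age_mean" = NULL,
      "mod.raasi.disc.ckd_prog" = NULL,
      "raasi.m23.soc.disc_max" = NULL,
      "tx.disc_monthly" = NULL,
      "tx.response" = NULL)
  }
  base <- run_base_case(p, wtp = wtp, ...)
  rows <- list()
  for (nm in names(param_ranges)) {
    rg <- param_ranges[[nm]]
    if (is.null(rg)) {
      if (nm == "@horizon_age") next
      i <- match(nm, p$params$name)
      if (is.na(i)) { warning("unknown parameter skipped: ", nm); next }
      m <- p$params$mean[i]; s <- p$params$se[i]
      rg <- c(m - 1.96 * s, m + 1.96 * s)
      if (p$params$kind[i] %in% c("prob", "utility")) {
        rg <- pmin(1, pmax(0, rg))
      } else if (p$params$kind[i] %in% c("cost", "disutility")) {
        rg <- pmax(0, rg)
      } else if (p$params$kind[i] == "hr") {
        rg <- pmax(1e-6, rg)
      }
    }
    if (!all(is.finite(rg)) || rg[1] > rg[2]) {
      warning("invalid range skipped for ", nm); next
    }
    icers <- vapply(rg, function(v) {
      pl <- p
      if (nm == "@horizon_age") {
        cea <- run_base_case(pl, wtp = wtp, horizon_age = v)
      } else {
        pl <- set_param(pl, nm, mean = v)
        cea <- tryCatch(run_base_case(pl, wtp = wtp, ...),
                        error = function(e) NULL)
        if (is.null(cea)) return(NA_real_)
      }
      cea$icer
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = nm, low = rg[1], high = rg[2],
      icer_low = icers[1], icer_high = icers[2],
      span = abs(icers[2] - icers[1]))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$span), ]
  rownames(tab) <- NULL
  structure(list(table = tab, base_icer = base$icer, wtp = wtp),
            class = "hk_owsa")
}

#' @export
print.hk_owsa <- function(x, ...) {
  cat("One-way sensitivity analysis (base ICER GBP",
      formatC(x$base_icer, format = "f", digits = 0, big.mark = ","), "/QALY)\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
plot.hk_owsa <- function(x, ...) {
  tab <- x$table[nrow(x$table):1, ]
  lo <- pmin(tab$icer_low, tab$icer_high)
  hi <- pmax(tab$icer_low, tab$icer_high)
  graphics::par(mar = c(4, 12, 2, 2))
  graphics::plot(NA, xlim = range(c(lo, hi, x$base_icer), finite = TRUE),
                 ylim = c(0.5, nrow(tab) + 0.5), yaxt = "n",
                 xlab = "ICER (GBP/QALY)", ylab = "", main = "Tornado diagram")
  graphics::abline(v = x$base_icer, col = "grey50", lty = 2)
  for (i in seq_len(nrow(tab))) {
    graphics::segments(lo[i], i, hi[i], i, lwd = 8, col = "steelblue")
  }
  graphics::axis(2, at = seq_len(nrow(tab)), labels = tab$parameter, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}

#' Impact of HK incidence: rate sweep
#'
#' Evaluates lifetime incremental outcomes as the annual rate of HK events
#' in one severity category is varied, against a reference cohort with no HK
#' incidence at all. The analysis is run without patiromer (SoC inputs):
#' month-1 and months-2-3 incidence rows are zeroed, and the swept
#' category's subsequent-month probability is set to
#' `1 - exp(-rate/12)` with the other categories held at zero. Because the
#' engine is deterministic, increments at rate 0 are exactly zero.
#'
#' @param p An `hk_params` object.
#' @param rates Annual rate grid (default 0 to 0.5).
#' @param categories Severity categories to sweep.
#' @param ... Passed to [run_cohort()].
#' @return Object of class `hk_sweep`: data.frame of incremental cost, QALY
#'   and LY (swept minus no-HK reference) per category and rate.
#' @export
run_hk_sweep <- function(p, rates = seq(0, 0.5, by = 0.1),
                         categories = c("K_5_55", "K_55_6", "K_gt6"), ...) {
  p0 <- .zero_hk(p)
  ref <- run_cohort(p0, "soc", ...)
  ref_tot <- c(cost = sum(ref$ledger_disc), qaly = sum(ref$qaly_disc),
               ly = sum(ref$ly_disc))
  out <- list()
  for (cat_ in categories) {
    nm <- paste0("hk.sub.soc.", tolower(sub("K_", "k_", cat_)))
    for (r in rates) {
      tot <- if (r == 0) ref_tot else {
        pr <- set_param(p0, nm, mean = annual_rate_to_monthly_prob(r))
        tr <- run_cohort(pr, "soc", ...)
        c(cost = sum(tr$ledger_disc), qaly = sum(tr$qaly_disc),
          ly = sum(tr$ly_disc))
      }
      out[[length(out) + 1L]] <- data.frame(
        category = cat_, annual_rate = r,
        d_cost = tot[["cost"]] - ref_tot[["cost"]],
        d_qaly = tot[["qaly"]] - ref_tot[["qaly"]],
        d_ly = tot[["ly"]] - ref_tot[["ly"]])
    }
  }
  structure(list(table = do.call(rbind, out), rates = rates,
                 categories = categories), class = "hk_sweep")
}

# zero every HK incidence input (the "no HK incidence" reference)
.zero_hk <- function(p) {
  sel <- grepl("^hk\\.", p$params$name)
  p$params$mean[sel] <- 0
  # baseline potassium occupancy influences only cycle 1 and is common to
  # every sweep run; leave it at base
  p
}

#' @export
print.hk_sweep <- function(x, ...) {
  cat("HK incidence sweep (increments vs no-HK reference)\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.hk_sweep <- function(x, what = c("d_qaly", "d_cost", "d_ly"), ...) {
  what <- match.arg(what)
  tab <- x$table
  cols <- stats::setNames(c("forestgreen", "orange", "firebrick"),
                          c("K_5_55", "K_55_6", "K_gt6"))
  graphics::plot(NA, xlim = range(tab$annual_rate), ylim = range(tab[[what]]),
                 xlab = "Annual HK rate", ylab = what,
                 main = "Impact of HK incidence", ...)
  for (cat_ in unique(tab$category)) {
    s <- tab[tab$category == cat_, ]
    graphics::lines(s$annual_rate, s[[what]], col = cols[[cat_]], lwd = 2)
  }
  graphics::legend("bottomleft", legend = unique(tab$category),
                   col = cols[unique(tab$category)], lwd = 2, bty = "n")
  invisible(x)
}

#' Lifetime value of optimal RAASi management
#'
#' Compares two hypothetical management approaches — lifelong optimal RAASi
#' use (maximum dose maintained, no discontinuation or down-titration) and
#' no RAASi use from model entry (discontinued throughout) — across cohorts
#' defined by baseline age (40/50/60/70), starting CKD stage (3/4/5, stage 5
#' pre-RRT) and HF status, using SoC inputs and the age-dependent ESRD
#' parameters. 48 cells in total.
#'
#' @param p An `hk_params` object.
#' @param ages,stages,hf Grid definition (defaults per the analysis design).
#' @param ... Passed to [run_cohort()].
#' @return Object of class `hk_raasi_value`: data.frame with one row per
#'   (age, stage, HF, management) cell holding total discounted cost and
#'   QALYs.
#' @export
run_raasi_value <- function(p, ages = c(40, 50, 60, 70), stages = c(3, 4, 5),
                            hf = c(TRUE, FALSE), ...) {
  out <- list()
  for (a in ages) for (s in stages) for (h in hf) {
    ps <- p
    ps <- set_param(ps, "demo.age_mean", mean = a, se = 0)
    ps <- set_param(ps, "start.hf", mean = as.numeric(h))
    ps <- set_param(ps, "start.ckd3", mean = as.numeric(s == 3), se = 0)
    ps <- set_param(ps, "start.ckd4", mean = as.numeric(s == 4), se = 0)
    ps <- set_param(ps, "start.ckd5", mean = as.numeric(s == 5), se = 0)
    for (mgmt in c("optimal", "none")) {
      tr <- run_cohort(ps, "soc", raasi_override = mgmt, ...)
      out[[length(out) + 1L]] <- data.frame(
        age = a, stage = s, hf = h, management = mgmt,
        cost_disc = sum(tr$ledger_disc), qaly_disc = sum(tr$qaly_disc),
        ly_disc = sum(tr$ly_disc))
    }
  }
  structure(list(table = do.call(rbind, out)), class = "hk_raasi_value")
}

#' QALY gains from optimal RAASi management
#' @param x An `hk_raasi_value`.
#' @return data.frame per (age, stage, hf) with the optimal-minus-none
#'   differences in discounted QALYs and costs.
#' @export
raasi_value_gains <- function(x) {
  stopifnot(inherits(x, "hk_raasi_value"))
  tab <- x$table
  opt <- tab[tab$management == "optimal", ]
  non <- tab[tab$management == "none", ]
  key <- c("age", "stage", "hf")
  m <- merge(opt, non, by = key, suffixes = c("_opt", "_none"))
  data.frame(m[key],
             qaly_gain = m$qaly_disc_opt - m$qaly_disc_none,
             cost_diff = m$cost_disc_opt - m$cost_disc_none,
             ly_gain = m$ly_disc_opt - m$ly_disc_none)
}

#' @export
print.hk_raasi_value <- function(x, ...) {
  cat("Lifetime value of optimal RAASi management (48-cell grid)\n")
  print(raasi_value_gains(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.hk_raasi_value <- function(x, what = c("qaly_gain", "cost_diff"), ...) {
  what <- match.arg(what)
  g <- raasi_value_gains(x)
  g$grp <- interaction(g$stage, g$hf)
  cols <- grDevices::hcl.colors(6, "Dark 3")
  graphics::plot(NA, xlim = range(g$age), ylim = range(g[[what]]),
                 xlab = "Baseline age", ylab = what,
                 main = "Value of lifetime optimal RAASi management")
  i <- 0L
  for (lv in levels(g$grp)) {
    i <- i + 1L
    s <- g[g$grp == lv, ]
    s <- s[order(s$age), ]
    graphics::lines(s$age, s[[what]], col = cols[i], lwd = 2,
                    lty = if (s$hf[1]) 1 else 2)
    graphics::points(s$age, s[[what]], col = cols[i], pch = 16)
  }
  graphics::legend("topright", legend = levels(g$grp), col = cols,
                   lwd = 2, bty = "n", cex = 0.8,
                   title = "stage.HF")
  invisible(x)
}
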