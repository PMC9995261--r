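# Monthly-cycle cohort engine and individual-level microsimulation oracle.
#
# Within-cycle ordering (the model's canonical convention):
#   1. potassium category re-drawn from the phase/exposure incidence row
#      (cycle 1 keeps the baseline category distribution; month-1 incident
#      events are counted from the month-1 incidence row),
#   2. RAASi status transition given the new potassium category (from cycle 2),
#   3. treatment exposure update (month-1 response split; discontinuation,
#      forced stop at ESRD, potassium-triggered re-treatment from cycle 2),
#   4. clinical events (MACE, hospitalisation), death with the life-table
#      floor, then CKD and NYHA chain transitions for survivors.
# State-occupancy accruals (life years, utilities, state costs) use the
# start-of-cycle occupancy; event accruals use the cycle's expected events.

EVENT_KINDS <- c("hk_k_5_55", "hk_k_55_6", "hk_k_gt6", "mace",
                 "hospitalisation", "raasi_discontinuation",
                 "raasi_downtitration", "raasi_return",
                 "dialysis_entry", "transplant_entry", "death")
LEDGER_CATEGORIES <- c("treatment", "HK", "CKD", "RRT", "MACE",
                       "hospitalisation", "RAASi_drug", "RAASi_titration")

## ---------------------------------------------------------------------------
## pre-computation shared by the cohort engine and the microsimulation

# scalar lookups used every cycle, extracted once from the registry
.engine_inputs <- function(p) {
  pv <- param_vector(p)
  g <- function(nm) unname(pv[nm])
  list(
    pv = pv,
    prop_female = g("demo.prop_female"),
    age0 = g("demo.age_mean"),
    response = g("tx.response"),
    tx_exit = g("tx.disc_monthly"),
    prop_raasi_m1 = c(pat = g("tx.prop_raasi_m1.pat"),
                      soc = g("tx.prop_raasi_m1.soc")),
    ret = g("raasi.return_to_max"),
    hr_hk = c(1, g("mod.raasi.submax.hk"), g("mod.raasi.disc.hk")),
    hr_prog = c(1, g("mod.raasi.submax.ckd_prog"), g("mod.raasi.disc.ckd_prog")),
    hr_r = list(
      mace  = c(1, g("mod.raasi.submax.mace"),  g("mod.raasi.disc.mace")),
      hosp  = c(1, g("mod.raasi.submax.hosp"),  g("mod.raasi.disc.hosp")),
      death = c(1, g("mod.raasi.submax.death"), g("mod.raasi.disc.death"))),
    hr_k = list(
      mace  = c(1, g("mod.k.k_5_55.mace"),  g("mod.k.k_55_6.mace"),  g("mod.k.k_gt6.mace")),
      hosp  = c(1, g("mod.k.k_5_55.hosp"),  g("mod.k.k_55_6.hosp"),  g("mod.k.k_gt6.hosp")),
      death = c(1, g("mod.k.k_5_55.death"), g("mod.k.k_55_6.death"), g("mod.k.k_gt6.death"))),
    ev_ckd = list(
      mace = c(g("ev.mace.ckd3"), g("ev.mace.ckd4"), g("ev.mace.ckd5"),
               g("ev.mace.dialysis"), g("ev.mace.transplant")),
      hosp = c(g("ev.hosp.ckd3"), g("ev.hosp.ckd4"), g("ev.hosp.ckd5"),
               g("ev.hosp.dialysis"), g("ev.hosp.transplant")),
      death3 = c(g("ev.death.ckd3"), g("ev.death.ckd4"), g("ev.death.ckd5"))),
    ev_nyha = list(
      mace = g(paste0("ev.mace.nyha", 1:4)),
      hosp = g(paste0("ev.hosp.nyha", 1:4)),
      death = g(paste0("ev.death.nyha", 1:4))),
    prog = c(g("prog.ckd3_to_ckd4"), g("prog.ckd4_to_ckd5"),
             g("prog.ckd5_to_dialysis")),
    nyha_tp = list(worsen = g(paste0("prog.nyha.worsen_", c("1to2", "2to3", "3to4"))),
                   improve = g(paste0("prog.nyha.improve_", c("2to1", "3to2", "4to3")))),
    u_ckd = g(paste0("util.state.", c("ckd3", "ckd4", "ckd5", "dialysis", "transplant"))),
    u_nyha = g(paste0("util.state.nyha", 1:4)),
    c_state_ckd = g(paste0("cost.state.", c("ckd3", "ckd4", "ckd5"))),
    c_state_rrt = g(paste0("cost.state.", c("dialysis", "transplant"))),
    c_state_nyha = g(paste0("cost.state.nyha", 1:4)),
    c_hk = g(paste0("cost.event.hk.", c("k_5_55", "k_55_6", "k_gt6"))),
    c_mace = g("cost.event.mace"), c_hosp = g("cost.event.hosp"),
    c_transplant_entry = g("cost.event.transplant_entry"),
    c_raasi_change = g("cost.event.raasi_change"),
    c_patiromer = g("cost.drug.patiromer"),
    c_raasi_drug = c(g("cost.drug.raasi_max"), g("cost.drug.raasi_submax"), 0),
    du_hk = g(paste0("disutil.event.hk.", c("k_5_55", "k_55_6", "k_gt6"))),
    du_mace = g("disutil.event.mace"), du_hosp = g("disutil.event.hosp"),
    discount = g("econ.discount_annual"),
    esrd = lapply(c("transplant_ckd5", "transplant_dial", "death_dial",
                    "death_transplant"),
                  function(nm) g(paste0("esrd.", nm, ".a", ESRD_AGE_KNOTS)))
  )
}

# ESRD quadruple at a given age from pre-extracted knot values
.esrd_at_age <- function(ei, age, rule) {
  a <- min(max(age, min(ESRD_AGE_KNOTS)), max(ESRD_AGE_KNOTS))
  v <- vapply(ei$esrd, function(vals) {
    if (identical(rule, "linear")) {
      stats::approx(ESRD_AGE_KNOTS, vals, xout = a, rule = 2)$y
    } else {
      vals[max(which(ESRD_AGE_KNOTS <= a))]
    }
  }, numeric(1))
  names(v) <- c("transplant_ckd5", "transplant_dial", "death_dial",
                "death_transplant")
  v
}

# per-cell index grids and static per-cell probability/cost vectors for one
# subcohort (nn = 1 for CKD-only with a dummy NYHA axis, 4 for CKD+HF)
.static_cells <- function(ei, nn) {
  dims <- c(5L, 4L, nn, 3L, 2L)
  N <- prod(dims)
  g <- expand.grid(ckd = 1:5, k = 1:4, nyha = 1:nn, raasi = 1:3, tx = 1:2,
                   KEEP.OUT.ATTRS = FALSE)
  ev_nyha <- function(v) if (nn == 1L) rep(0, 1) else v
  u_nyha <- if (nn == 1L) 1 else ei$u_nyha
  c_nyha <- if (nn == 1L) 0 else ei$c_state_nyha

  hrm <- ei$hr_r$mace[g$raasi] * ei$hr_k$mace[g$k]
  hrh <- ei$hr_r$hosp[g$raasi] * ei$hr_k$hosp[g$k]
  base_m <- pmax(ei$ev_ckd$mace[g$ckd], ev_nyha(ei$ev_nyha$mace)[g$nyha])
  base_h <- pmax(ei$ev_ckd$hosp[g$ckd], ev_nyha(ei$ev_nyha$hosp)[g$nyha])

  list(
    dims = dims, N = N, g = g,
    p_mace = 1 - (1 - base_m)^hrm,
    p_hosp = 1 - (1 - base_h)^hrh,
    hr_death = ei$hr_r$death[g$raasi] * ei$hr_k$death[g$k],
    d_nyha_cell = ev_nyha(ei$ev_nyha$death)[g$nyha],
    u_cell = pmin(ei$u_ckd[g$ckd], u_nyha[g$nyha]),
    c_ckd_cell = c(ei$c_state_ckd, 0, 0)[g$ckd] + c_nyha[g$nyha],
    c_rrt_cell = c(0, 0, 0, ei$c_state_rrt)[g$ckd],
    c_raasi_cell = ei$c_raasi_drug[g$raasi],
    on_cell = as.numeric(g$tx == 1L),
    # retrigger mask: off-treatment, K >= 5.5, not in ESRD
    trig_arr = array(as.numeric(g$k >= 3L & g$ckd <= 3L)[g$tx == 2L],
                     dim = dims[1:4]),
    # (raasi, tx) combo id for each column after putting K first
    rt_idx = {
      gk <- expand.grid(ckd = 1:5, nyha = 1:nn, raasi = 1:3, tx = 1:2)
      (gk$tx - 1L) * 3L + gk$raasi
    },
    # (k, tx) combo id for each column after putting RAASi first
    kt_idx = {
      gr <- expand.grid(ckd = 1:5, k = 1:4, nyha = 1:nn, tx = 1:2)
      (gr$tx - 1L) * 4L + gr$k
    },
    # columns of matrix(occ, nrow = 5) belonging to each RAASi status
    cols_by_raasi = {
      gc <- expand.grid(k = 1:4, nyha = 1:nn, raasi = 1:3, tx = 1:2)
      lapply(1:3, function(r) which(gc$raasi == r))
    }
  )
}

# age-dependent pieces: monthly death probability per cell and the CKD
# transition matrices (one per RAASi status)
.age_cells <- function(ei, st, lt_m, esrd_q) {
  d_ckd <- c(ei$ev_ckd$death3, esrd_q[["death_dial"]], esrd_q[["death_transplant"]])
  base_d <- pmax(d_ckd[st$g$ckd], st$d_nyha_cell)
  p_die <- pmax(lt_m, 1 - (1 - base_d)^st$hr_death)

  T_ckd <- vector("list", 3L)
  for (r in 1:3) {
    q34 <- 1 - (1 - ei$prog[1])^ei$hr_prog[r]
    q45 <- 1 - (1 - ei$prog[2])^ei$hr_prog[r]
    q5d <- 1 - (1 - ei$prog[3])^ei$hr_prog[r]
    q5t <- esrd_q[["transplant_ckd5"]]
    if (q5d + q5t > 1) stop("CKD5 exit probabilities exceed 1 (inconsistent config)")
    qdt <- esrd_q[["transplant_dial"]]
    T_ckd[[r]] <- matrix(c(
      1 - q34, q34, 0, 0, 0,
      0, 1 - q45, q45, 0, 0,
      0, 0, 1 - q5d - q5t, q5d, q5t,
      0, 0, 0, 1 - qdt, qdt,
      0, 0, 0, 0, 1), nrow = 5, byrow = TRUE)
  }
  list(p_die = p_die, T_ckd = T_ckd)
}

# phase-dependent pieces: the potassium re-draw matrix and the RAASi
# transition components, laid out by (raasi,tx) and (k,tx) combos
.phase_cells <- function(ei, phase, retrigger_threshold = NULL) {
  pv <- ei$pv
  tri <- function(arm) {
    key <- if (phase == "m1") "hk.m1." else paste0("hk.", phase, ".", arm, ".")
    unname(pv[paste0(key, c("k_5_55", "k_55_6", "k_gt6"))])
  }
  tri_by_tx <- list(tri("pat"), tri("soc"))
  # P_k[k', combo]: combo = (tx-1)*3 + raasi; severity rows get the RAASi->HK
  # hazard ratio on the rate scale, residual goes to K <= 5
  P_k <- matrix(0, 4, 6)
  sev <- matrix(0, 3, 6)
  for (t in 1:2) for (r in 1:3) {
    cb <- (t - 1L) * 3L + r
    s <- 1 - (1 - tri_by_tx[[t]])^ei$hr_hk[r]
    if (sum(s) > 1) stop("modified HK severity probabilities exceed 1")
    sev[, cb] <- s
    P_k[, cb] <- c(1 - sum(s), s)
  }

  # RAASi rows by (k, tx): combo = (tx-1)*4 + k
  dmax <- down <- dsub <- numeric(8)
  for (t in 1:2) for (k in 1:4) {
    cb <- (t - 1L) * 4L + k
    arm <- if (t == 1L) "pat" else "soc"
    if (phase == "m23") {
      dmax[cb] <- pv[[paste0("raasi.m23.", arm, ".disc_max")]]
      down[cb] <- pv[[paste0("raasi.m23.", arm, ".down_max")]]
      dsub[cb] <- pv[[paste0("raasi.m23.", arm, ".disc_sub")]]
    } else if (phase == "sub") {
      klo <- tolower(K_LEVELS[k])
      dmax[cb] <- pv[[paste0("raasi.sub.", arm, ".disc_max.", klo)]]
      down[cb] <- pv[[paste0("raasi.sub.", arm, ".down_max.", klo)]]
      dsub[cb] <- pv[[paste0("raasi.sub.", arm, ".disc_sub.", klo)]]
    }
    if (dmax[cb] + down[cb] > 1) {
      stop("from-max RAASi probabilities exceed 1 (inconsistent config)")
    }
  }
  # M3flat[(to-1)*3 + from, combo]
  M3 <- matrix(0, 9, 8)
  for (cb in 1:8) {
    m <- matrix(c(1 - dmax[cb] - down[cb], down[cb], dmax[cb],
                  0, 1 - dsub[cb], dsub[cb],
                  ei$ret, 0, 1 - ei$ret), nrow = 3, byrow = TRUE)
    M3[, cb] <- as.vector(m)  # column-major: (from,to) pairs stacked by 'to'
  }
  list(P_k = P_k, sev = sev, M3 = M3, dmax = dmax, down = down, dsub = dsub)
}

## ---------------------------------------------------------------------------
## cohort engine

#' Run the Markov cohort model for one arm
#'
#' Propagates the baseline cohort through the monthly-cycle model until the
#' horizon rule is met (cohort age reaches `horizon_age`, or alive mass falls
#' below `horizon_min_alive`), accumulating per-cycle occupancy summaries,
#' expected event counts, the eight-category cost ledger, and (discounted and
#' undiscounted) life years and QALYs. Fully deterministic.
#'
#' @param p An `hk_params` object.
#' @param arm `"patiromer"` or `"soc"`.
#' @param horizon_age Optional override of the settings horizon age.
#' @param keep_trace Keep the full per-cycle occupancy arrays (memory-heavy;
#'   off by default).
#' @param raasi_override `NULL` (normal dynamics), `"optimal"` (RAASi pinned
#'   at maximum dose: no discontinuation or down-titration), or `"none"`
#'   (cohort starts discontinued and never returns) — used by the optimal
#'   RAASi value analysis.
#' @return An object of class `hk_trajectory`.
#' @export
run_cohort <- function(p, arm = c("patiromer", "soc"), horizon_age = NULL,
                       keep_trace = FALSE, raasi_override = NULL) {
  arm <- match.arg(arm)
  st_t <- p$settings
  if (!is.null(horizon_age)) st_t$horizon_age <- horizon_age
  if (!is.null(raasi_override)) {
    stopifnot(raasi_override %in% c("optimal", "none"))
    p <- .apply_raasi_override(p, raasi_override)
  }
  ei <- .engine_inputs(p)
  cohort <- build_initial_cohort(p, arm)
  if (!is.null(raasi_override) && raasi_override == "none") {
    cohort <- .pin_raasi_status(cohort, 3L)
  }

  sub_names <- c("ckd_only", "ckd_hf")
  st <- list(ckd_only = .static_cells(ei, 1L), ckd_hf = .static_cells(ei, 4L))
  NY_T <- .nyha_matrix(ei)

  max_cycles <- ceiling((st_t$horizon_age - cohort$age) * 12) + 1L
  if (max_cycles < 1L) max_cycles <- 1L
  n_ev <- length(EVENT_KINDS)
  ev_mat <- matrix(0, max_cycles, n_ev, dimnames = list(NULL, EVENT_KINDS))
  led_u <- matrix(0, max_cycles, length(LEDGER_CATEGORIES),
                  dimnames = list(NULL, LEDGER_CATEGORIES))
  led_d <- led_u
  alive_v <- on_v <- ly_u <- ly_d <- qaly_u <- qaly_d <- numeric(max_cycles)
  ckd_trace <- matrix(0, max_cycles, 6,
                      dimnames = list(NULL, c(CKD_LEVELS, "Dead")))
  trace <- if (keep_trace) vector("list", max_cycles) else NULL
  qaly_clamped <- 0L

  rate <- ei$discount
  age <- cohort$age
  cur_floor <- -1L
  cur_phase <- ""
  ac <- ph <- NULL
  m <- 0L

  repeat {
    alive <- alive_mass(cohort)
    if (m >= max_cycles || alive < st_t$horizon_min_alive ||
        age >= st_t$horizon_age - 1e-9) break
    m <- m + 1L

    # refresh age-dependent pieces when the integer age changes
    if (floor(age) != cur_floor || identical(st_t$age_rule, "linear")) {
      cur_floor <- floor(age)
      lt_q <- .life_table_annual_q(age, ei$prop_female, p$life_table)
      lt_m <- 1 - (1 - lt_q)^(1 / 12)
      esrd_q <- .esrd_at_age(ei, age, st_t$age_rule)
      ac <- lapply(st, function(s) .age_cells(ei, s, lt_m, esrd_q))
    }
    phase <- .hk_phase(m)
    if (!identical(phase, cur_phase)) {
      cur_phase <- phase
      ph <- .phase_cells(ei, phase)
      phx <- lapply(st, function(s) .phase_expand(ph, s))
    }
    df <- (1 + rate)^(-(m - 1) / 12)

    ## start-of-cycle state accruals
    occv <- lapply(cohort$occ, as.vector)
    on_mass <- sum(occv$ckd_only * st$ckd_only$on_cell) +
      sum(occv$ckd_hf * st$ckd_hf$on_cell)
    util_mass <- sum(occv$ckd_only * st$ckd_only$u_cell) +
      sum(occv$ckd_hf * st$ckd_hf$u_cell)
    c_ckd <- sum(occv$ckd_only * st$ckd_only$c_ckd_cell) +
      sum(occv$ckd_hf * st$ckd_hf$c_ckd_cell)
    c_rrt <- sum(occv$ckd_only * st$ckd_only$c_rrt_cell) +
      sum(occv$ckd_hf * st$ckd_hf$c_rrt_cell)
    c_rdrug <- sum(occv$ckd_only * st$ckd_only$c_raasi_cell) +
      sum(occv$ckd_hf * st$ckd_hf$c_raasi_cell)

    ev <- stats::setNames(numeric(n_ev), EVENT_KINDS)

    ## step 1: potassium category
    if (m == 1L) {
      # baseline categories persist through cycle 1; incident month-1 events
      # are counted from the (arm-common) month-1 row
      tri <- ph$sev[, 4L]  # tx=2, raasi=MaxDose (hazard ratio 1) column
      ev[c("hk_k_5_55", "hk_k_55_6", "hk_k_gt6")] <- alive * tri
    } else {
      for (sc in sub_names) {
        r <- .k_redraw(cohort$occ[[sc]], st[[sc]], phx[[sc]])
        cohort$occ[[sc]] <- r$occ
        ev[c("hk_k_5_55", "hk_k_55_6", "hk_k_gt6")] <-
          ev[c("hk_k_5_55", "hk_k_55_6", "hk_k_gt6")] + r$events
      }
    }

    ## step 2: RAASi transition
    if (m >= 2L) {
      for (sc in sub_names) {
        r <- .raasi_step(cohort$occ[[sc]], st[[sc]], phx[[sc]], ei$ret)
        cohort$occ[[sc]] <- r$occ
        ev["raasi_discontinuation"] <- ev["raasi_discontinuation"] + r$disc
        ev["raasi_downtitration"] <- ev["raasi_downtitration"] + r$down
        ev["raasi_return"] <- ev["raasi_return"] + r$ret
      }
    }

    ## step 3: treatment exposure
    if (arm == "patiromer" && m == 1L) {
      cohort <- resolve_month1_response(cohort, p)
    }
    if (m == 1L && any(ei$prop_raasi_m1 < 1)) {
      for (sc in sub_names) {
        r <- .month1_raasi_hold(cohort$occ[[sc]], ei$prop_raasi_m1, arm)
        cohort$occ[[sc]] <- r$occ
        ev["raasi_discontinuation"] <- ev["raasi_discontinuation"] + r$disc
      }
    }
    if (arm == "patiromer" && m >= 2L) {
      for (sc in sub_names) {
        cohort$occ[[sc]] <- .treatment_step(cohort$occ[[sc]], st[[sc]],
                                            ei$tx_exit, st_t$retrigger_enabled)
      }
    }

    ## step 4: clinical events, death, chain transitions
    for (sc in sub_names) {
      occ <- cohort$occ[[sc]]
      ov <- as.vector(occ)
      ev["mace"] <- ev["mace"] + sum(ov * st[[sc]]$p_mace)
      ev["hospitalisation"] <- ev["hospitalisation"] + sum(ov * st[[sc]]$p_hosp)
      d <- sum(ov * ac[[sc]]$p_die)
      ev["death"] <- ev["death"] + d
      cohort$dead[[sc]] <- cohort$dead[[sc]] + d
      occ <- array(ov * (1 - ac[[sc]]$p_die), dim = st[[sc]]$dims)

      r <- .ckd_step(occ, st[[sc]], ac[[sc]]$T_ckd)
      occ <- r$occ
      ev["dialysis_entry"] <- ev["dialysis_entry"] + r$dial_in
      ev["transplant_entry"] <- ev["transplant_entry"] + r$trans_in
      # treatment stops on ESRD entry
      occ[4:5, , , , 2] <- occ[4:5, , , , 2] + occ[4:5, , , , 1]
      occ[4:5, , , , 1] <- 0

      if (sc == "ckd_hf") occ <- .nyha_step(occ, NY_T)
      cohort$occ[[sc]] <- occ
    }

    ## accruals
    ly <- alive / 12
    qaly <- util_mass / 12 -
      sum(ev[c("hk_k_5_55", "hk_k_55_6", "hk_k_gt6")] * ei$du_hk) -
      ev[["mace"]] * ei$du_mace - ev[["hospitalisation"]] * ei$du_hosp
    if (qaly < 0) { qaly <- 0; qaly_clamped <- qaly_clamped + 1L }

    if (isTRUE(st_t$half_cycle)) {
      # average start- and end-of-cycle occupancy for state-based accruals
      occv2 <- lapply(cohort$occ, as.vector)
      alive2 <- sum(occv2$ckd_only) + sum(occv2$ckd_hf)
      ly <- (alive + alive2) / 2 / 12
      um2 <- sum(occv2$ckd_only * st$ckd_only$u_cell) +
        sum(occv2$ckd_hf * st$ckd_hf$u_cell)
      qaly <- qaly - util_mass / 12 + (util_mass + um2) / 2 / 12
      qaly <- max(0, qaly)
      c_ckd <- (c_ckd + sum(occv2$ckd_only * st$ckd_only$c_ckd_cell) +
                  sum(occv2$ckd_hf * st$ckd_hf$c_ckd_cell)) / 2
      c_rrt <- (c_rrt + sum(occv2$ckd_only * st$ckd_only$c_rrt_cell) +
                  sum(occv2$ckd_hf * st$ckd_hf$c_rrt_cell)) / 2
      c_rdrug <- (c_rdrug + sum(occv2$ckd_only * st$ckd_only$c_raasi_cell) +
                    sum(occv2$ckd_hf * st$ckd_hf$c_raasi_cell)) / 2
    }

    led <- c(
      treatment = on_mass * ei$c_patiromer,
      HK = sum(ev[c("hk_k_5_55", "hk_k_55_6", "hk_k_gt6")] * ei$c_hk),
      CKD = c_ckd, RRT = c_rrt + ev[["transplant_entry"]] * ei$c_transplant_entry,
      MACE = ev[["mace"]] * ei$c_mace,
      hospitalisation = ev[["hospitalisation"]] * ei$c_hosp,
      RAASi_drug = c_rdrug,
      RAASi_titration = (ev[["raasi_discontinuation"]] +
                           ev[["raasi_downtitration"]] +
                           ev[["raasi_return"]]) * ei$c_raasi_change)

    if (any(!is.finite(c(led, ly, qaly, alive)))) {
      stop("non-finite occupancy or accrual at cycle ", m)
    }

    ev_mat[m, ] <- ev
    led_u[m, ] <- led
    led_d[m, ] <- led * df
    alive_v[m] <- alive; on_v[m] <- on_mass
    ly_u[m] <- ly; ly_d[m] <- ly * df
    qaly_u[m] <- qaly; qaly_d[m] <- qaly * df
    ckd_trace[m, ] <- c(
      .rowSums(cohort$occ$ckd_only, 5L, st$ckd_only$N / 5L) +
        .rowSums(cohort$occ$ckd_hf, 5L, st$ckd_hf$N / 5L),
      sum(cohort$dead))
    if (keep_trace) trace[[m]] <- cohort$occ

    age <- age + 1 / 12
    cohort$age <- age
    cohort$month <- m
  }

  keep <- seq_len(m)
  structure(list(
    arm = arm, n_cycles = m, age0 = ei$age0, initial_mass = 1,
    alive = alive_v[keep], on_treatment = on_v[keep],
    ly = ly_u[keep], ly_disc = ly_d[keep],
    qaly = qaly_u[keep], qaly_disc = qaly_d[keep],
    events = ev_mat[keep, , drop = FALSE],
    ledger = led_u[keep, , drop = FALSE],
    ledger_disc = led_d[keep, , drop = FALSE],
    ckd_trace = ckd_trace[keep, , drop = FALSE],
    trace = if (keep_trace) trace[keep] else NULL,
    qaly_clamped_cycles = qaly_clamped,
    discount_annual = rate, settings = st_t,
    final_cohort = cohort), class = "hk_trajectory")
}

# RAASi-override plumbing for the optimal-RAASi value analysis
.apply_raasi_override <- function(p, mode) {
  reg <- p$params
  if (mode == "optimal") {
    sel <- grepl("^raasi\\.(m23|sub)\\.", reg$name) &
      grepl("(disc_max|down_max|disc_sub)", reg$name)
    reg$mean[sel] <- 0
  } else {
    reg$mean[reg$name == "raasi.return_to_max"] <- 0
  }
  # month-1 hold parameters must not reintroduce transitions
  reg$mean[reg$name %in% c("tx.prop_raasi_m1.pat", "tx.prop_raasi_m1.soc")] <- 1
  p$params <- reg
  p
}

.pin_raasi_status <- function(cohort, r_idx) {
  for (sc in names(cohort$occ)) {
    occ <- cohort$occ[[sc]]
    tot <- apply(occ, c(1, 2, 3, 5), sum)
    occ[] <- 0
    occ[, , , r_idx, ] <- tot
    cohort$occ[[sc]] <- occ
  }
  cohort
}

# per-subcohort expansion of the phase pieces onto column layouts
.phase_expand <- function(ph, st) {
  list(Pk_e = ph$P_k[, st$rt_idx, drop = FALSE],
       sev_e = ph$sev[, st$rt_idx, drop = FALSE],
       M3_e = ph$M3[, st$kt_idx, drop = FALSE],
       dmax_e = ph$dmax[st$kt_idx], down_e = ph$down[st$kt_idx],
       dsub_e = ph$dsub[st$kt_idx])
}

# step 1: potassium redraw with event expectations
.k_redraw <- function(occ, st, phx) {
  dims <- st$dims
  mk <- matrix(aperm(occ, c(2, 1, 3, 4, 5)), nrow = 4L)
  marg <- colSums(mk)
  events <- as.vector(phx$sev_e %*% marg)
  newm <- phx$Pk_e * matrix(marg, 4L, length(marg), byrow = TRUE)
  occ <- aperm(array(newm, dim = c(4L, dims[1], dims[3], dims[4], dims[5])),
               c(2, 1, 3, 4, 5))
  list(occ = occ, events = events)
}

# step 2: RAASi transition with event expectations
.raasi_step <- function(occ, st, phx, ret) {
  dims <- st$dims
  mr <- matrix(aperm(occ, c(4, 1, 2, 3, 5)), nrow = 3L)
  disc <- sum(mr[1, ] * phx$dmax_e) + sum(mr[2, ] * phx$dsub_e)
  down <- sum(mr[1, ] * phx$down_e)
  retv <- sum(mr[3, ]) * ret
  M3 <- phx$M3_e
  newm <- mr
  newm[1, ] <- mr[1, ] * M3[1, ] + mr[2, ] * M3[2, ] + mr[3, ] * M3[3, ]
  newm[2, ] <- mr[1, ] * M3[4, ] + mr[2, ] * M3[5, ] + mr[3, ] * M3[6, ]
  newm[3, ] <- mr[1, ] * M3[7, ] + mr[2, ] * M3[8, ] + mr[3, ] * M3[9, ]
  occ <- aperm(array(newm, dim = c(3L, dims[1], dims[2], dims[3], dims[5])),
               c(2, 3, 4, 1, 5))
  list(occ = occ, disc = disc, down = down, ret = retv)
}

# optional end-of-month-1 RAASi hold release (no-op at the default of 1)
.month1_raasi_hold <- function(occ, prop, arm) {
  disc <- 0
  for (t in 1:2) {
    pr <- if (arm == "patiromer" && t == 1L) prop[["pat"]] else prop[["soc"]]
    if (pr < 1) {
      mx <- occ[, , , 1L, t]
      occ[, , , 3L, t] <- occ[, , , 3L, t] + (1 - pr) * mx
      occ[, , , 1L, t] <- pr * mx
      disc <- disc + (1 - pr) * sum(mx)
    }
  }
  list(occ = occ, disc = disc)
}

# step 3 (cycles >= 2): treatment exit and potassium-triggered re-treatment.
# Re-treatment applies to mass off treatment at the start of the step; mass
# exiting this cycle stays off for at least one cycle.
.treatment_step <- function(occ, st, exit_p, retrigger) {
  d4 <- st$dims[1:4]
  on <- array(occ[, , , , 1L, drop = FALSE], d4)
  off0 <- array(occ[, , , , 2L, drop = FALSE], d4)
  e <- c(exit_p, exit_p, exit_p, 1, 1)  # forced stop in ESRD
  leaving <- on * e  # recycles along the CKD (first) axis
  back <- if (retrigger) off0 * st$trig_arr else 0
  occ[, , , , 1L] <- on - leaving + back
  occ[, , , , 2L] <- off0 - back + leaving
  occ
}

# step 4: CKD chain transition with ESRD entry counts
.ckd_step <- function(occ, st, T_ckd) {
  m5 <- matrix(occ, nrow = 5L)
  dial_in <- trans_in <- 0
  for (r in 1:3) {
    cb <- st$cols_by_raasi[[r]]
    sub <- m5[, cb, drop = FALSE]
    Tm <- T_ckd[[r]]
    s5 <- sum(sub[3, ]); sD <- sum(sub[4, ])
    dial_in <- dial_in + s5 * Tm[3, 4]
    trans_in <- trans_in + s5 * Tm[3, 5] + sD * Tm[4, 5]
    m5[, cb] <- crossprod(Tm, sub)
  }
  list(occ = array(m5, dim = st$dims), dial_in = dial_in,
       trans_in = trans_in)
}

.nyha_matrix <- function(ei) {
  w <- ei$nyha_tp$worsen; im <- ei$nyha_tp$improve
  matrix(c(1 - w[1], w[1], 0, 0,
           im[1], 1 - im[1] - w[2], w[2], 0,
           0, im[2], 1 - im[2] - w[3], w[3],
           0, 0, im[3], 1 - im[3]), nrow = 4, byrow = TRUE)
}

.nyha_step <- function(occ, NY_T) {
  d <- dim(occ)
  ap <- aperm(occ, c(3, 1, 2, 4, 5))
  mn <- matrix(ap, nrow = 4L)
  aperm(array(crossprod(NY_T, mn), dim = c(4L, d[1], d[2], d[4], d[5])),
        c(2, 3, 1, 4, 5))
}

## ---------------------------------------------------------------------------
## trajectory summaries

#' @export
print.hk_trajectory <- function(x, ...) {
  cat("<hk_trajectory> arm:", x$arm, " cycles:", x$n_cycles, "\n")
  cat(sprintf("  LY  %.3f (disc %.3f)   QALY %.3f (disc %.3f)\n",
              sum(x$ly), sum(x$ly_disc), sum(x$qaly), sum(x$qaly_disc)))
  cat(sprintf("  total cost GBP %.0f (disc %.0f)\n",
              sum(x$ledger), sum(x$ledger_disc)))
  invisible(x)
}

#' @export
summary.hk_trajectory <- function(object, ...) {
  out <- list(
    arm = object$arm, n_cycles = object$n_cycles,
    ly = sum(object$ly), ly_disc = sum(object$ly_disc),
    qaly = sum(object$qaly), qaly_disc = sum(object$qaly_disc),
    cost = sum(object$ledger), cost_disc = sum(object$ledger_disc),
    ledger = colSums(object$ledger), ledger_disc = colSums(object$ledger_disc),
    events = colSums(object$events),
    mean_treatment_months = mean_treatment_duration(object))
  class(out) <- "summary.hk_trajectory"
  out
}

#' @export
print.summary.hk_trajectory <- function(x, ...) {
  cat("Cohort trajectory —", x$arm, "arm,", x$n_cycles, "cycles\n")
  cat(sprintf("  life years          %8.3f  (discounted %8.3f)\n", x$ly, x$ly_disc))
  cat(sprintf("  QALYs               %8.3f  (discounted %8.3f)\n", x$qaly, x$qaly_disc))
  cat(sprintf("  total cost (GBP)    %8.0f  (discounted %8.0f)\n", x$cost, x$cost_disc))
  cat(sprintf("  months on patiromer %8.2f\n", x$mean_treatment_months))
  cat("  discounted cost ledger:\n")
  for (nm in names(x$ledger_disc)) {
    cat(sprintf("    %-16s %10.0f\n", nm, x$ledger_disc[nm]))
  }
  invisible(x)
}

#' Per-cycle trajectory summary as a data.frame
#' @param x An `hk_trajectory`.
#' @param ... Unused.
#' @return data.frame with one row per cycle: occupancy summaries, accruals
#'   and expected event counts.
#' @export
as.data.frame.hk_trajectory <- function(x, ...) {
  data.frame(cycle = seq_len(x$n_cycles),
             age = x$age0 + (seq_len(x$n_cycles) - 1) / 12,
             alive = x$alive, on_treatment = x$on_treatment,
             ly = x$ly, ly_disc = x$ly_disc,
             qaly = x$qaly, qaly_disc = x$qaly_disc,
             cost = rowSums(x$ledger), cost_disc = rowSums(x$ledger_disc),
             x$events, check.names = FALSE)
}

#' Export a trajectory as tidy CSV plus a summary JSON
#'
#' @param x An `hk_trajectory`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the two file paths.
#' @export
write_trajectory <- function(x, dir, prefix = paste0("trajectory_", x$arm)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  utils::write.csv(as.data.frame(x), csv, row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  s <- summary(x)
  jsonlite::write_json(list(arm = s$arm, n_cycles = s$n_cycles,
                            ly = s$ly, ly_disc = s$ly_disc,
                            qaly = s$qaly, qaly_disc = s$qaly_disc,
                            cost = s$cost, cost_disc = s$cost_disc,
                            ledger_disc = as.list(s$ledger_disc),
                            events = as.list(s$events)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Mean months on patiromer
#'
#' Treatment exposure accumulated as the on-treatment mass at the start of
#' each cycle, divided by the initial cohort mass.
#'
#' @param x An `hk_trajectory`.
#' @return Mean exposure in months (0 for the SoC arm).
#' @export
mean_treatment_duration <- function(x) {
  stopifnot(inherits(x, "hk_trajectory"))
  sum(x$on_treatment) / x$initial_mass
}

#' Cumulative event difference per 1,000 patients
#'
#' @param a,b `hk_trajectory` objects (conventionally `a` = patiromer,
#'   `b` = SoC); positive values mean fewer events under `a`.
#' @param kind One of the tracked event kinds (see `EVENT_KINDS`), e.g.
#'   `"hk_k_55_6"`, `"raasi_discontinuation"`.
#' @return 1000 x (cumulative expected events in `b` minus in `a`).
#' @export
events_per_1000 <- function(a, b, kind) {
  stopifnot(inherits(a, "hk_trajectory"), inherits(b, "hk_trajectory"),
            kind %in% EVENT_KINDS)
  1000 * (sum(b$events[, kind]) - sum(a$events[, kind]))
}

## ---------------------------------------------------------------------------
## microsimulation oracle

#' Individual-level microsimulation of the cohort model
#'
#' Simulates `n` individuals through the identical per-cycle probabilities
#' used by the cohort engine (the two share one set of probability builders),
#' drawing states (potassium category, RAASi status, treatment exposure, CKD
#' and NYHA transitions, death) individually. MACE and hospitalisation — pure
#' events with no state consequence — and their costs/disutilities are
#' accrued in expectation given each realised path, which leaves the
#' estimator unbiased for the cohort expectation while reducing Monte-Carlo
#' noise. Used as the validation oracle for the cohort engine.
#'
#' @param p An `hk_params` object.
#' @param arm `"patiromer"` or `"soc"`.
#' @param n Number of simulated individuals.
#' @param seed Integer seed (mandatory; the run is reproducible given it).
#' @param horizon_age Optional override of the settings horizon age.
#' @return A list of class `hk_microsim`: per-individual discounted totals
#'   (`ly_disc`, `qaly_disc`, `cost_disc`) and event counts (`events`,
#'   an `n x 11` matrix), plus their means and standard errors.
#' @export
run_microsimulation <- function(p, arm = c("patiromer", "soc"), n, seed,
                                horizon_age = NULL) {
  arm <- match.arg(arm)
  stopifnot(n >= 1)
  set.seed(seed)
  st_t <- p$settings
  if (!is.null(horizon_age)) st_t$horizon_age <- horizon_age
  ei <- .engine_inputs(p)
  pv <- ei$pv
  st <- list(ckd_only = .static_cells(ei, 1L), ckd_hf = .static_cells(ei, 4L))
  NY_T <- .nyha_matrix(ei)
  NY_cum <- t(apply(NY_T, 1, cumsum))

  ## baseline draws (product of the printed marginals)
  hf <- stats::runif(n) < pv[["start.hf"]]
  rcat <- function(n, probs) {
    findInterval(stats::runif(n), cumsum(probs)[-length(probs)]) + 1L
  }
  ckd <- rcat(n, c(pv[["start.ckd3"]], pv[["start.ckd4"]], pv[["start.ckd5"]], 0, 0))
  kc <- rcat(n, c(pv[["start.k_le5"]], pv[["start.k_5_55"]],
                  pv[["start.k_55_6"]], pv[["start.k_gt6"]]))
  nyha <- ifelse(hf, rcat(n, c(pv[["start.nyha1"]], pv[["start.nyha2"]],
                               pv[["start.nyha3"]], pv[["start.nyha4"]])), 1L)
  raasi <- rep(1L, n)
  on_tx <- rep(arm == "patiromer", n)
  alive <- rep(TRUE, n)

  ly_d <- qaly_d <- cost_d <- numeric(n)
  evc <- matrix(0, n, length(EVENT_KINDS), dimnames = list(NULL, EVENT_KINDS))
  on_months <- numeric(n)

  cell_idx <- function(w) {
    nn <- ifelse(hf[w], 4L, 1L)
    ny <- ifelse(hf[w], nyha[w], 1L)
    # index into the subcohort's cell vectors (CKD fastest)
    ckd[w] + 5L * ((kc[w] - 1L) + 4L * ((ny - 1L) + nn *
      ((raasi[w] - 1L) + 3L * (ifelse(on_tx[w], 0L, 1L)))))
  }
  pick <- function(field, w) {
    idx <- cell_idx(w)
    out <- numeric(length(w))
    o_hf <- hf[w]
    out[!o_hf] <- st$ckd_only[[field]][idx[!o_hf]]
    out[o_hf] <- st$ckd_hf[[field]][idx[o_hf]]
    out
  }

  age <- ei$age0
  rate <- ei$discount
  cur_floor <- -1L
  cur_phase <- ""
  ph <- NULL
  ac <- NULL
  m <- 0L
  max_cycles <- ceiling((st_t$horizon_age - age) * 12) + 1L

  repeat {
    n_alive <- sum(alive)
    if (m >= max_cycles || n_alive < 1L || age >= st_t$horizon_age - 1e-9) break
    m <- m + 1L
    w <- which(alive)
    df <- (1 + rate)^(-(m - 1) / 12)

    if (floor(age) != cur_floor) {
      cur_floor <- floor(age)
      lt_q <- .life_table_annual_q(age, ei$prop_female, p$life_table)
      lt_m <- 1 - (1 - lt_q)^(1 / 12)
      esrd_q <- .esrd_at_age(ei, age, st_t$age_rule)
      ac <- lapply(st, function(s) .age_cells(ei, s, lt_m, esrd_q))
      Tcum <- lapply(ac$ckd_only$T_ckd, function(Tm) t(apply(Tm, 1, cumsum)))
    }
    phase <- .hk_phase(m)
    if (!identical(phase, cur_phase)) {
      cur_phase <- phase
      ph <- .phase_cells(ei, phase)
      Pk_cum <- apply(ph$P_k, 2, cumsum)
    }

    ## start-of-cycle accruals
    ly_d[w] <- ly_d[w] + df / 12
    u <- pick("u_cell", w)
    q_inc <- u / 12
    c_state <- pick("c_ckd_cell", w) + pick("c_rrt_cell", w) +
      pick("c_raasi_cell", w) + ifelse(on_tx[w], ei$c_patiromer, 0)
    on_months[w] <- on_months[w] + as.numeric(on_tx[w])
    c_inc <- c_state

    ## step 1: potassium
    if (m == 1L) {
      tri <- ph$sev[, 4L]
      evc[w, 1:3] <- evc[w, 1:3] + matrix(tri, length(w), 3, byrow = TRUE)
      c_inc <- c_inc + sum(tri * ei$c_hk)
      q_inc <- q_inc - sum(tri * ei$du_hk)
    } else {
      cb <- (ifelse(on_tx[w], 0L, 1L)) * 3L + raasi[w]
      uu <- stats::runif(length(w))
      cum <- Pk_cum[, cb, drop = FALSE]
      knew <- 1L + (uu > cum[1, ]) + (uu > cum[2, ]) + (uu > cum[3, ])
      kc[w] <- knew
      hit <- knew >= 2L
      if (any(hit)) {
        rows <- w[hit]; sev <- knew[hit] - 1L
        evc[cbind(rows, sev)] <- evc[cbind(rows, sev)] + 1
        c_inc[hit] <- c_inc[hit] + ei$c_hk[sev]
        q_inc[hit] <- q_inc[hit] - ei$du_hk[sev]
      }
    }

    ## step 2: RAASi
    if (m >= 2L) {
      cb <- (ifelse(on_tx[w], 0L, 1L)) * 4L + kc[w]
      uu <- stats::runif(length(w))
      r0 <- raasi[w]
      rnew <- r0
      i_max <- r0 == 1L
      if (any(i_max)) {
        dm <- ph$dmax[cb[i_max]]; dn <- ph$down[cb[i_max]]
        uu_m <- uu[i_max]
        rnew[i_max] <- ifelse(uu_m < dm, 3L, ifelse(uu_m < dm + dn, 2L, 1L))
      }
      i_sub <- r0 == 2L
      if (any(i_sub)) {
        rnew[i_sub] <- ifelse(uu[i_sub] < ph$dsub[cb[i_sub]], 3L, 2L)
      }
      i_dis <- r0 == 3L
      if (any(i_dis)) rnew[i_dis] <- ifelse(uu[i_dis] < ei$ret, 1L, 3L)
      evc[w, "raasi_discontinuation"] <- evc[w, "raasi_discontinuation"] +
        as.numeric(r0 != 3L & rnew == 3L)
      evc[w, "raasi_downtitration"] <- evc[w, "raasi_downtitration"] +
        as.numeric(r0 == 1L & rnew == 2L)
      evc[w, "raasi_return"] <- evc[w, "raasi_return"] +
        as.numeric(r0 == 3L & rnew == 1L)
      n_chg <- as.numeric(r0 != rnew)
      c_inc <- c_inc + n_chg * ei$c_raasi_change
      raasi[w] <- rnew
    } else {
      c_inc <- c_inc  # RAASi held in month 1
    }

    ## step 3: treatment
    if (arm == "patiromer") {
      if (m == 1L) {
        on_tx[w] <- on_tx[w] & (stats::runif(length(w)) < ei$response)
      } else {
        i_on <- on_tx[w]
        exit <- ifelse(ckd[w] >= 4L, 1, ei$tx_exit)
        drop_tx <- i_on & (stats::runif(length(w)) < exit)
        on_tx[w][drop_tx] <- FALSE
        if (isTRUE(st_t$retrigger_enabled)) {
          # re-treatment applies to individuals off at the start of the step
          re <- !i_on & kc[w] >= 3L & ckd[w] <= 3L
          on_tx[w][re] <- TRUE
        }
      }
    }
    if (m == 1L && any(ei$prop_raasi_m1 < 1)) {
      pr <- ifelse(on_tx[w], ei$prop_raasi_m1[["pat"]],
                   ei$prop_raasi_m1[["soc"]])
      hold_disc <- raasi[w] == 1L & stats::runif(length(w)) < (1 - pr)
      raasi[w][hold_disc] <- 3L
      evc[w, "raasi_discontinuation"] <- evc[w, "raasi_discontinuation"] +
        as.numeric(hold_disc)
      c_inc <- c_inc + as.numeric(hold_disc) * ei$c_raasi_change
    }

    ## step 4: clinical
    pm <- pick("p_mace", w); phs <- pick("p_hosp", w)
    # p_die sits in the age cache, not the static cache
    idx <- cell_idx(w)
    pd <- numeric(length(w))
    pd[!hf[w]] <- ac$ckd_only$p_die[idx[!hf[w]]]
    pd[hf[w]] <- ac$ckd_hf$p_die[idx[hf[w]]]

    evc[w, "mace"] <- evc[w, "mace"] + pm
    evc[w, "hospitalisation"] <- evc[w, "hospitalisation"] + phs
    c_inc <- c_inc + pm * ei$c_mace + phs * ei$c_hosp
    q_inc <- q_inc - pm * ei$du_mace - phs * ei$du_hosp

    die <- stats::runif(length(w)) < pd
    evc[w, "death"] <- evc[w, "death"] + as.numeric(die)

    q_inc <- pmax(0, q_inc)
    qaly_d[w] <- qaly_d[w] + q_inc * df
    cost_d[w] <- cost_d[w] + c_inc * df
    alive[w[die]] <- FALSE
    ws <- w[!die]

    if (length(ws) > 0L) {
      uu <- stats::runif(length(ws))
      c0 <- ckd[ws]
      cnew <- integer(length(ws))
      for (r in 1:3) {
        sel <- raasi[ws] == r
        if (any(sel)) {
          cm <- Tcum[[r]][c0[sel], , drop = FALSE]
          cnew[sel] <- 1L + rowSums(uu[sel] > cm[, 1:4, drop = FALSE])
        }
      }
      evc[ws, "dialysis_entry"] <- evc[ws, "dialysis_entry"] +
        as.numeric(c0 != 4L & cnew == 4L)
      new_trans <- c0 != 5L & cnew == 5L
      evc[ws, "transplant_entry"] <- evc[ws, "transplant_entry"] +
        as.numeric(new_trans)
      cost_d[ws] <- cost_d[ws] + as.numeric(new_trans) * ei$c_transplant_entry * df
      ckd[ws] <- cnew
      on_tx[ws][cnew >= 4L] <- FALSE

      sel_hf <- ws[hf[ws]]
      if (length(sel_hf) > 0L) {
        cm <- NY_cum[nyha[sel_hf], , drop = FALSE]
        nyha[sel_hf] <- 1L +
          rowSums(stats::runif(length(sel_hf)) > cm[, 1:3, drop = FALSE])
      }
    }
    age <- age + 1 / 12
  }

  means <- c(ly_disc = mean(ly_d), qaly_disc = mean(qaly_d),
             cost_disc = mean(cost_d))
  ses <- c(ly_disc = stats::sd(ly_d), qaly_disc = stats::sd(qaly_d),
           cost_disc = stats::sd(cost_d)) / sqrt(n)
  ev_mean <- colMeans(evc)
  ev_se <- apply(evc, 2, stats::sd) / sqrt(n)
  structure(list(arm = arm, n = n, seed = seed, n_cycles = m,
                 ly_disc = ly_d, qaly_disc = qaly_d, cost_disc = cost_d,
                 events = evc, mean = means, se = ses,
                 event_mean = ev_mean, event_se = ev_se,
                 mean_on_months = mean(on_months)),
            class = "hk_microsim")
}

#' @export
print.hk_microsim <- function(x, ...) {
  cat("<hk_microsim> arm:", x$arm, " n:", x$n, " seed:", x$seed, "\n")
  cat(sprintf("  LY(disc) %.3f ± %.4f   QALY(disc) %.3f ± %.4f\n",
              x$mean["ly_disc"], x$se["ly_disc"],
              x$mean["qaly_disc"], x$se["qaly_disc"]))
  cat(sprintf("  cost(disc) %.0f ± %.0f\n",
              x$mean["cost_disc"], x$se["cost_disc"]))
  invisible(x)
}
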