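# Clinical progression: CKD stage transitions, ESRD dynamics, NYHA chain,
# and the mortality / event probability machinery with effect modifiers.

#' Apply a hazard ratio to a monthly probability
#'
#' Hazard ratios act on the rate scale: the probability is converted to a
#' rate, scaled, and converted back, giving `1 - (1 - p)^hr`. This is the
#' standard consistent mapping when effects are reported as (approximate)
#' hazard ratios but the model works in per-cycle probabilities.
#'
#' @param base_prob Monthly probability in \[0,1).
#' @param modifier Hazard ratio (> 0).
#' @return Modified monthly probability.
#' @export
apply_modifier <- function(base_prob, modifier) {
  stopifnot(all(base_prob >= 0 & base_prob < 1), all(modifier > 0))
  1 - (1 - base_prob)^modifier
}

#' Combine CKD-chain and HF-chain event probabilities
#'
#' For the CKD+HF subcohort the per-cycle probability of MACE,
#' hospitalisation or death is estimated separately from the CKD state and
#' the NYHA state, and the higher of the two is applied.
#'
#' @param ckd_prob,hf_prob Probabilities in \[0,1\] (vectorised).
#' @return `pmax(ckd_prob, hf_prob)`.
#' @export
combined_event_prob <- function(ckd_prob, hf_prob) {
  stopifnot(all(ckd_prob >= 0 & ckd_prob <= 1),
            all(hf_prob >= 0 & hf_prob <= 1))
  pmax(ckd_prob, hf_prob)
}

#' Convert an annual probability to a monthly probability
#'
#' Constant-rate conversion: `1 - (1 - q)^(1/12)`.
#'
#' @param q Annual probability in \[0,1\].
#' @return Monthly probability.
#' @export
annual_prob_to_monthly <- function(q) {
  stopifnot(all(q >= 0 & q <= 1))
  1 - (1 - q)^(1 / 12)
}

#' Age-dependent ESRD parameters
#'
#' Looks up the four ESRD input probabilities (monthly probability of
#' transplant from pre-RRT CKD stage 5, transplant from dialysis, death on
#' dialysis, death with a functioning transplant) at a given age. Values are
#' tabulated at the age knots 40/50/60/70; the default `"step"` rule holds
#' the value from the nearest knot at or below the (clamped) age, while
#' `"linear"` interpolates between knots.
#'
#' @param age Age in years (clamped to the knot span).
#' @param p An `hk_params` object.
#' @return Named vector `transplant_ckd5`, `transplant_dial`, `death_dial`,
#'   `death_transplant` of monthly probabilities.
#' @export
esrd_params_for_age <- function(age, p) {
  pv <- param_vector(p)
  rule <- p$settings$age_rule
  a <- min(max(age, min(ESRD_AGE_KNOTS)), max(ESRD_AGE_KNOTS))
  out <- numeric(4)
  nms <- c("transplant_ckd5", "transplant_dial", "death_dial", "death_transplant")
  for (j in seq_along(nms)) {
    vals <- pv[paste0("esrd.", nms[j], ".a", ESRD_AGE_KNOTS)]
    out[j] <- if (identical(rule, "linear")) {
      stats::approx(ESRD_AGE_KNOTS, vals, xout = a, rule = 2)$y
    } else {
      vals[max(which(ESRD_AGE_KNOTS <= a))]
    }
  }
  stats::setNames(out, nms)
}

#' Monthly CKD state transition distribution
#'
#' Forward-only chain CKD3 -> CKD4 -> CKD5 -> Dialysis/Transplant, plus
#' Dialysis -> Transplant, conditional on surviving the cycle (death is
#' handled separately; see [mortality_prob()]). The RAASi progression
#' modifier (a hazard ratio relative to maximum-dose use) is applied on the
#' rate scale to the stage-progression probabilities (CKD3->4, CKD4->5,
#' CKD5->Dialysis); transplant probabilities are organ-supply driven and are
#' taken from the age-dependent ESRD table unmodified.
#'
#' @param state CKD state name (not `"Dead"`).
#' @param age Age in years.
#' @param raasi RAASi status name.
#' @param p An `hk_params` object.
#' @return Named probability vector over the five alive CKD states, summing
#'   to one.
#' @export
ckd_transition_probs <- function(state, age, raasi, p) {
  stopifnot(state %in% CKD_LEVELS, raasi %in% RAASI_LEVELS)
  pv <- param_vector(p)
  hr <- switch(raasi, MaxDose = 1,
               SubMaxDose = pv[["mod.raasi.submax.ckd_prog"]],
               Discontinued = pv[["mod.raasi.disc.ckd_prog"]])
  es <- esrd_params_for_age(age, p)
  out <- stats::setNames(numeric(5), CKD_LEVELS)
  if (state == "CKD3") {
    q <- apply_modifier(pv[["prog.ckd3_to_ckd4"]], hr)
    out["CKD4"] <- q; out["CKD3"] <- 1 - q
  } else if (state == "CKD4") {
    q <- apply_modifier(pv[["prog.ckd4_to_ckd5"]], hr)
    out["CKD5"] <- q; out["CKD4"] <- 1 - q
  } else if (state == "CKD5") {
    qd <- apply_modifier(pv[["prog.ckd5_to_dialysis"]], hr)
    qt <- es[["transplant_ckd5"]]
    if (qd + qt > 1) stop("CKD5 exit probabilities exceed 1 (inconsistent config)")
    out["Dialysis"] <- qd; out["Transplant"] <- qt; out["CKD5"] <- 1 - qd - qt
  } else if (state == "Dialysis") {
    qt <- es[["transplant_dial"]]
    out["Transplant"] <- qt; out["Dialysis"] <- 1 - qt
  } else {
    out["Transplant"] <- 1
  }
  out
}

# life-table annual q blended over sex, at floor(age) (clamped to table span)
.life_table_annual_q <- function(age, prop_female, life_table) {
  a <- floor(age)
  a <- min(max(a, min(life_table$age)), max(life_table$age))
  qm <- life_table$qx[life_table$sex == "male" & life_table$age == a]
  qf <- life_table$qx[life_table$sex == "female" & life_table$age == a]
  prop_female * qf + (1 - prop_female) * qm
}

#' Monthly mortality probability with the life-table floor
#'
#' The modelled (disease-based) death probability is the higher of the
#' CKD-chain and HF-chain baseline probabilities, scaled on the rate scale
#' by the RAASi-status and potassium-category hazard ratios. Background
#' all-cause mortality from the life table (annual `q` blended by the
#' proportion female, converted via `1 - (1-q)^(1/12)`) acts as a floor:
#' the greater of the two monthly probabilities is applied.
#'
#' @param ckd_state CKD state name (not `"Dead"`).
#' @param nyha_state NYHA state name, or `NA` for the CKD-only subcohort.
#' @param age Age in years.
#' @param k_cat Potassium category name.
#' @param raasi RAASi status name.
#' @param p An `hk_params` object.
#' @return Monthly probability of death.
#' @export
mortality_prob <- function(ckd_state, nyha_state, age, k_cat, raasi, p) {
  stopifnot(ckd_state %in% CKD_LEVELS, k_cat %in% K_LEVELS,
            raasi %in% RAASI_LEVELS)
  pv <- param_vector(p)
  es <- esrd_params_for_age(age, p)
  d_ckd <- switch(ckd_state,
                  CKD3 = pv[["ev.death.ckd3"]], CKD4 = pv[["ev.death.ckd4"]],
                  CKD5 = pv[["ev.death.ckd5"]],
                  Dialysis = es[["death_dial"]],
                  Transplant = es[["death_transplant"]])
  d_hf <- if (is.na(nyha_state)) 0 else {
    pv[[paste0("ev.death.nyha", match(nyha_state, NYHA_LEVELS))]]
  }
  hr_r <- switch(raasi, MaxDose = 1,
                 SubMaxDose = pv[["mod.raasi.submax.death"]],
                 Discontinued = pv[["mod.raasi.disc.death"]])
  hr_k <- if (k_cat == "K_le5") 1 else pv[[paste0("mod.", tolower(sub("K_", "k.k_", k_cat)), ".death")]]
  modelled <- apply_modifier(combined_event_prob(d_ckd, d_hf), hr_r * hr_k)
  lt_q <- .life_table_annual_q(age, pv[["demo.prop_female"]], p$life_table)
  max(annual_prob_to_monthly(lt_q), modelled)
}
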