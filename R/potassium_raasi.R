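# Monthly potassium-category incidence and RAASi dose-status dynamics.

# phase label for a cycle index
.hk_phase <- function(month) {
  if (month <= 1L) "m1" else if (month <= 3L) "m23" else "sub"
}

#' Monthly HK incidence by severity
#'
#' Returns the monthly probabilities of an incident hyperkalaemia event in
#' each severity category (5-5.5, 5.5-6, > 6 mmol/l) for a given cycle and
#' effective treatment exposure. Month 1 uses the common (arm-independent)
#' row; months 2-3 and subsequent months use exposure-specific rows. The
#' residual probability is the probability of staying/returning in the
#' normokalaemic category (K <= 5).
#'
#' @param month Cycle index (>= 1).
#' @param on_patiromer Logical; `TRUE` for mass currently exposed to
#'   patiromer (responders on treatment), `FALSE` for SoC-equivalent mass
#'   (SoC arm, non-responders, post-discontinuation).
#' @param p An `hk_params` object.
#' @return Named vector `c(K_5_55, K_55_6, K_gt6)` of monthly probabilities.
#' @export
hk_incidence <- function(month, on_patiromer, p) {
  stopifnot(month >= 1)
  pv <- param_vector(p)
  ph <- .hk_phase(month)
  key <- if (ph == "m1") "hk.m1." else {
    paste0("hk.", ph, ".", if (on_patiromer) "pat." else "soc.")
  }
  stats::setNames(pv[paste0(key, c("k_5_55", "k_55_6", "k_gt6"))],
                  c("K_5_55", "K_55_6", "K_gt6"))
}

#' Convert an annual event rate to a monthly probability
#'
#' Constant-rate (exponential) conversion `1 - exp(-rate/12)`, used when
#' annual HK rates are supplied (e.g. in the HK-incidence sweep).
#'
#' @param rate Annual event rate (events per patient-year, >= 0).
#' @return Monthly probability.
#' @export
annual_rate_to_monthly_prob <- function(rate) {
  stopifnot(all(rate >= 0))
  1 - exp(-rate / 12)
}

#' Monthly RAASi status transition distribution
#'
#' From a maximum dose, patients may down-titrate to a sub-maximal dose or
#' discontinue; from a sub-maximal dose they may discontinue (but never
#' return to the maximum dose); from discontinuation they may return to
#' optimal (maximum-dose) use with a potassium-independent monthly
#' probability. Months 2-3 use pooled (potassium-independent) trial rates;
#' from month 4 rates are stratified by the current potassium category.
#' Month 1 holds RAASi use fixed pending treatment response resolution.
#'
#' @param k_cat Potassium category name.
#' @param status Current RAASi status name.
#' @param month Cycle index (>= 2).
#' @param on_patiromer Logical effective exposure (see [hk_incidence()]).
#' @param p An `hk_params` object.
#' @return Named probability vector over `MaxDose`, `SubMaxDose`,
#'   `Discontinued`, summing to one.
#' @export
raasi_transition <- function(k_cat, status, month, on_patiromer, p) {
  stopifnot(k_cat %in% K_LEVELS, status %in% RAASI_LEVELS, month >= 2)
  pv <- param_vector(p)
  arm <- if (on_patiromer) "pat" else "soc"
  if (month <= 3L) {
    disc_max <- pv[[paste0("raasi.m23.", arm, ".disc_max")]]
    down_max <- pv[[paste0("raasi.m23.", arm, ".down_max")]]
    disc_sub <- pv[[paste0("raasi.m23.", arm, ".disc_sub")]]
  } else {
    klo <- tolower(k_cat)
    disc_max <- pv[[paste0("raasi.sub.", arm, ".disc_max.", klo)]]
    down_max <- pv[[paste0("raasi.sub.", arm, ".down_max.", klo)]]
    disc_sub <- pv[[paste0("raasi.sub.", arm, ".disc_sub.", klo)]]
  }
  if (disc_max + down_max > 1) {
    stop("from-max RAASi probabilities exceed 1 (inconsistent config)")
  }
  ret <- pv[["raasi.return_to_max"]]
  out <- stats::setNames(numeric(3), RAASI_LEVELS)
  if (status == "MaxDose") {
    out["SubMaxDose"] <- down_max
    out["Discontinued"] <- disc_max
    out["MaxDose"] <- 1 - down_max - disc_max
  } else if (status == "SubMaxDose") {
    out["Discontinued"] <- disc_sub
    out["SubMaxDose"] <- 1 - disc_sub
  } else {
    out["MaxDose"] <- ret
    out["Discontinued"] <- 1 - ret
  }
  out
}
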