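# Factored health-state space and initial cohort construction.
#
# The cohort is split once, at baseline, into a CKD-only subcohort and a
# CKD+HF subcohort (no incident HF). Within a subcohort the state is the
# product CKD stage x potassium category x RAASi status x treatment status,
# with NYHA class as an extra axis for the CKD+HF subcohort, and one shared
# absorbing Dead state per subcohort. Occupancy is stored as a 5-dimensional
# array dim = (CKD, K, NYHA, RAASi, Tx); the CKD-only subcohort carries a
# dummy NYHA axis of length 1 so that both subcohorts share one engine path.

#' Enumerate the factored state space
#'
#' Returns the ordered list of model states for one subcohort: every
#' combination of CKD stage (CKD3, CKD4, CKD5, Dialysis, Transplant),
#' potassium category, RAASi status and treatment status — crossed with NYHA
#' class I-IV when `has_hf` — followed by the single collapsed Dead state.
#' The ordering is the array storage order (CKD fastest, then K, NYHA,
#' RAASi, Tx) and is deterministic.
#'
#' @param has_hf Logical; enumerate the CKD+HF subcohort (adds the NYHA axis).
#' @return A data.frame with columns `state_id`, `ckd`, `k`, `nyha` (NA for
#'   the CKD-only subcohort), `raasi`, `tx`; the final row is Dead (all
#'   factor columns NA, `ckd = "Dead"`). 121 rows without HF, 481 with.
#' @export
enumerate_states <- function(has_hf = FALSE) {
  g <- expand.grid(ckd = CKD_LEVELS, k = K_LEVELS,
                   nyha = if (has_hf) NYHA_LEVELS else NA_character_,
                   raasi = RAASI_LEVELS, tx = TX_LEVELS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- rbind(g, data.frame(ckd = "Dead", k = NA_character_,
                           nyha = NA_character_, raasi = NA_character_,
                           tx = NA_character_))
  data.frame(state_id = seq_len(nrow(g)), g, stringsAsFactors = FALSE)
}

# empty occupancy array for one subcohort
.empty_occ <- function(n_nyha) {
  array(0, dim = c(length(CKD_LEVELS), length(K_LEVELS), n_nyha,
                   length(RAASI_LEVELS), length(TX_LEVELS)))
}

#' Build the initial cohort
#'
#' Distributes unit mass across the factored state space according to the
#' baseline marginals: HF split, CKD stage shares, NYHA shares (CKD+HF
#' subcohort only), and potassium category shares, taken as independent at
#' baseline (the joint distribution is the product of the printed marginals).
#' All patients start on a maximum RAASi dose. In the patiromer arm the whole
#' cohort starts on treatment, pending the end-of-month-1 response split; in
#' the SoC arm everyone is off treatment throughout.
#'
#' @param p An `hk_params` object.
#' @param arm `"patiromer"` or `"soc"`.
#' @return An object of class `hk_cohort`: list with elements `occ` (list of
#'   subcohort occupancy arrays `ckd_only`, `ckd_hf`), `dead` (named vector of
#'   dead mass per subcohort), `age` (cohort age, years), `month` (completed
#'   cycles), `arm`, and `response_resolved` (logical).
#' @export
build_initial_cohort <- function(p, arm = c("patiromer", "soc")) {
  arm <- match.arg(arm)
  pv <- param_vector(p)

  ckd <- c(pv[["start.ckd3"]], pv[["start.ckd4"]], pv[["start.ckd5"]], 0, 0)
  nyha <- c(pv[["start.nyha1"]], pv[["start.nyha2"]], pv[["start.nyha3"]],
            pv[["start.nyha4"]])
  k <- c(pv[["start.k_le5"]], pv[["start.k_5_55"]], pv[["start.k_55_6"]],
         pv[["start.k_gt6"]])
  hf <- pv[["start.hf"]]
  for (blk in list(c(sum(ckd), "CKD stage"), c(sum(nyha), "NYHA"),
                   c(sum(k), "potassium"))) {
    if (abs(as.numeric(blk[1]) - 1) > 1e-9) {
      stop("starting ", blk[2], " distribution does not sum to 1")
    }
  }

  i_tx <- if (arm == "patiromer") 1L else 2L  # On vs Off

  occ_only <- .empty_occ(1L)
  occ_only[, , 1L, 1L, i_tx] <- (1 - hf) * outer(ckd, k)
  occ_hf <- .empty_occ(length(NYHA_LEVELS))
  for (n in seq_along(NYHA_LEVELS)) {
    occ_hf[, , n, 1L, i_tx] <- hf * outer(ckd, k) * nyha[n]
  }

  structure(list(occ = list(ckd_only = occ_only, ckd_hf = occ_hf),
                 dead = c(ckd_only = 0, ckd_hf = 0),
                 age = pv[["demo.age_mean"]], month = 0L, arm = arm,
                 response_resolved = FALSE),
            class = "hk_cohort")
}

#' Total cohort mass (alive + dead)
#' @param cohort An `hk_cohort`.
#' @return Scalar total mass.
#' @export
cohort_mass <- function(cohort) {
  sum(cohort$occ$ckd_only) + sum(cohort$occ$ckd_hf) + sum(cohort$dead)
}

#' Alive mass of a cohort
#' @param cohort An `hk_cohort`.
#' @return Scalar alive mass.
#' @export
alive_mass <- function(cohort) {
  sum(cohort$occ$ckd_only) + sum(cohort$occ$ckd_hf)
}

#' @export
print.hk_cohort <- function(x, ...) {
  cat("<hk_cohort> arm:", x$arm, " age:", round(x$age, 2),
      " completed cycles:", x$month, "\n")
  cat("  alive mass:", format(alive_mass(x), digits = 6),
      " dead mass:", format(sum(x$dead), digits = 6), "\n")
  invisible(x)
}

#' Marginal occupancy of a cohort
#'
#' Collapses the factored occupancy onto one axis (for audit and tests).
#'
#' @param cohort An `hk_cohort`.
#' @param axis One of `"ckd"`, `"k"`, `"nyha"`, `"raasi"`, `"tx"`,
#'   `"subcohort"`.
#' @return Named numeric vector of alive mass by level (NYHA marginal covers
#'   the CKD+HF subcohort only).
#' @export
cohort_marginal <- function(cohort, axis = c("ckd", "k", "nyha", "raasi",
                                             "tx", "subcohort")) {
  axis <- match.arg(axis)
  if (axis == "subcohort") {
    return(c(ckd_only = sum(cohort$occ$ckd_only), ckd_hf = sum(cohort$occ$ckd_hf)))
  }
  if (axis == "nyha") {
    m <- apply(cohort$occ$ckd_hf, 3, sum)
    return(stats::setNames(m, NYHA_LEVELS))
  }
  d <- switch(axis, ckd = 1L, k = 2L, raasi = 4L, tx = 5L)
  m <- apply(cohort$occ$ckd_only, d, sum) + apply(cohort$occ$ckd_hf, d, sum)
  stats::setNames(m, switch(axis, ckd = CKD_LEVELS, k = K_LEVELS,
                            raasi = RAASI_LEVELS, tx = TX_LEVELS))
}
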