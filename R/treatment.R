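# Patiromer exposure dynamics: month-1 response stratification, ongoing
# discontinuation, forced stopping at ESRD, and potassium-triggered
# re-treatment.

#' Resolve the end-of-month-1 treatment response split
#'
#' In the patiromer arm, all patients receive treatment for the first month;
#' at the end of that month the on-treatment mass is stratified into
#' responders (who continue on patiromer) and non-responders (who stop and
#' incur SoC-equivalent risks thereafter, with no legacy effect). The split
#' is applied once; calling it again, or on the SoC arm, is an error.
#'
#' @param cohort An `hk_cohort` (patiromer arm, end of cycle 1).
#' @param p An `hk_params` object.
#' @return The cohort with on-treatment mass split by the response
#'   proportion and `response_resolved = TRUE`.
#' @export
resolve_month1_response <- function(cohort, p) {
  if (cohort$arm != "patiromer") {
    stop("response resolution applies to the patiromer arm only")
  }
  if (isTRUE(cohort$response_resolved)) {
    stop("month-1 response has already been resolved for this cohort")
  }
  resp <- get_param(p, "tx.response")
  for (sc in names(cohort$occ)) {
    occ <- cohort$occ[[sc]]
    on <- .tx_slice(occ, 1L)
    .tx_slice(occ, 2L) <- .tx_slice(occ, 2L) + (1 - resp) * on
    .tx_slice(occ, 1L) <- resp * on
    cohort$occ[[sc]] <- occ
  }
  cohort$response_resolved <- TRUE
  cohort
}

# extract/assign the treatment axis (dim 5) of an occupancy array
.tx_slice <- function(occ, i) {
  occ[, , , , i, drop = FALSE]
}
`.tx_slice<-` <- function(occ, i, value) {
  occ[, , , , i] <- value
  occ
}

#' Monthly probability of leaving patiromer treatment
#'
#' Responders on patiromer stop with certainty on reaching ESRD (dialysis or
#' transplant) and otherwise discontinue at a constant monthly rate from
#' month 2 onwards; month 1 is a guaranteed minimum exposure.
#'
#' @param state CKD state name.
#' @param month Cycle index (>= 2).
#' @param p An `hk_params` object.
#' @return Monthly probability of moving off treatment.
#' @export
treatment_exit_prob <- function(state, month, p) {
  stopifnot(state %in% CKD_LEVELS)
  if (month < 2) {
    stop("treatment exit applies from month 2 (month 1 is guaranteed exposure)")
  }
  if (state %in% c("Dialysis", "Transplant")) 1 else get_param(p, "tx.disc_monthly")
}

#' Re-treatment trigger
#'
#' Off-treatment patients in the patiromer arm restart therapy in any month
#' in which their potassium is 5.5 mmol/l or above (and they are not in
#' ESRD). Re-treated patients re-enter at responder event rates; the month-1
#' response split is not re-applied.
#'
#' @param k_cat Potassium category name.
#' @return Logical; `TRUE` iff `k_cat` is `K_55_6` or `K_gt6`.
#' @export
retreatment_trigger <- function(k_cat) {
  stopifnot(all(k_cat %in% K_LEVELS))
  k_cat %in% c("K_55_6", "K_gt6")
}
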