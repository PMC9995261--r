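# Shared fixtures and config surgery helpers for the test suite.

fx <- make_reference_fixture()

# zero all mortality: disease baselines, ESRD death rates, and the life table
no_death <- function(p) {
  sel <- grepl("^ev\\.death\\.", p$params$name) |
    grepl("^esrd\\.death_", p$params$name)
  p$params$mean[sel] <- 0
  p$life_table$qx <- 0
  p
}

# no routes into ESRD (so patiromer treatment is never force-stopped)
no_esrd <- function(p) {
  sel <- grepl("^esrd\\.transplant_", p$params$name)
  p$params$mean[sel] <- 0
  p <- set_param(p, "prog.ckd5_to_dialysis", mean = 0)
  p
}

# make the patiromer arm behaviourally identical to SoC (columns equalised,
# drug cost zero) so arm differences must collapse to zero
neutralise_arms <- function(p) {
  nm <- p$params$name
  for (suff in c("k_5_55", "k_55_6", "k_gt6")) {
    for (ph in c("m23", "sub")) {
      p$params$mean[nm == paste0("hk.", ph, ".pat.", suff)] <-
        p$params$mean[nm == paste0("hk.", ph, ".soc.", suff)]
    }
  }
  for (col in c("disc_max", "down_max", "disc_sub")) {
    p$params$mean[nm == paste0("raasi.m23.pat.", col)] <-
      p$params$mean[nm == paste0("raasi.m23.soc.", col)]
    for (k in c("k_le5", "k_5_55", "k_55_6", "k_gt6")) {
      p$params$mean[nm == paste0("raasi.sub.pat.", col, ".", k)] <-
        p$params$mean[nm == paste0("raasi.sub.soc.", col, ".", k)]
    }
  }
  p <- set_param(p, "cost.drug.patiromer", mean = 0)
  p
}

# degenerate single-state start: everyone CKD-only, stage 3, normokalaemic
degenerate_start <- function(p) {
  p <- set_param(p, "start.hf", mean = 0)
  p <- set_param(p, "start.ckd3", mean = 1, se = 0)
  p <- set_param(p, "start.ckd4", mean = 0, se = 0)
  p <- set_param(p, "start.ckd5", mean = 0, se = 0)
  p <- set_param(p, "start.k_le5", mean = 1)
  p <- set_param(p, "start.k_5_55", mean = 0)
  p <- set_param(p, "start.k_55_6", mean = 0, se = 0)
  p <- set_param(p, "start.k_gt6", mean = 0, se = 0)
  p
}

# zero every HK incidence row
zero_hk_rows <- function(p) {
  p$params$mean[grepl("^hk\\.", p$params$name)] <- 0
  p
}
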