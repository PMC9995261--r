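# Parameter registry, validation, config I/O and PSA sampling.

test_that("reference fixture carries the printed estimates and passes validation", {
  expect_s3_class(fx, "hk_params")
  expect_equal(get_param(fx, "start.hf"), 0.4198)
  expect_equal(get_param(fx, "demo.age_mean"), 65.30)
  expect_equal(get_param(fx, "cost.event.hk.k_5_55"), 0)
  expect_equal(get_param(fx, "cost.event.hk.k_55_6"), 223.11)
  expect_equal(get_param(fx, "cost.event.hk.k_gt6"), 2933.49)
  expect_equal(get_param(fx, "raasi.return_to_max"), 0.0351)
  expect_equal(get_param(fx, "tx.response"), 0.6093)
  expect_equal(get_param(fx, "tx.disc_monthly"), 0.1033)
  expect_equal(get_param(fx, "econ.discount_annual"), 0.035)

  # month-1 HK incidence is a single arm-common row
  expect_identical(unname(hk_incidence(1, TRUE, fx)),
                   unname(hk_incidence(1, FALSE, fx)))

  # placeholder provenance flags distinguish supplementary stand-ins
  expect_true(all(c("main-text", "placeholder") %in% fx$params$provenance))
  expect_equal(fx$params$provenance[fx$params$name == "util.state.ckd3"],
               "placeholder")
  expect_equal(fx$params$provenance[fx$params$name == "hk.m1.k_5_55"],
               "main-text")

  expect_equal(nrow(validate_parameters(fx)), 0L)
})

test_that("validation reports violations as data with field and rule", {
  p <- fx
  p$params$mean[p$params$name == "util.state.ckd3"] <- 1.2
  v <- validate_parameters(p)
  expect_equal(nrow(v), 1L)
  expect_equal(v$field, "util.state.ckd3")
  expect_match(v$rule, "utility")

  p2 <- fx
  p2$params$mean[p2$params$name == "hk.sub.soc.k_gt6"] <- -0.01
  v2 <- validate_parameters(p2)
  expect_true("hk.sub.soc.k_gt6" %in% v2$field)

  p3 <- set_param(fx, "start.ckd3", mean = 0.4514)  # stages now sum to 0.9
  v3 <- validate_parameters(p3)
  expect_true(any(grepl("start.ckd", v3$field)))
})

test_that("config round-trip is value-identical and partial configs fall back to the fixture", {
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("cfg.", ext))
    write_parameters(fx, path)
    p2 <- load_parameters(path)
    expect_equal(p2$params$mean, fx$params$mean, tolerance = 1e-12)
    expect_equal(p2$params$se, fx$params$se, tolerance = 1e-12)
    expect_equal(p2$settings, fx$settings)
    expect_equal(p2$life_table$qx, fx$life_table$qx, tolerance = 1e-12)
  }

  # partial config: only one override; everything else keeps fixture values
  # and provenance flags
  path <- file.path(tempdir(), "partial.yaml")
  writeLines(c("parameters:", "  cost.state.dialysis: {mean: 3000}"), path)
  p3 <- load_parameters(path)
  expect_equal(get_param(p3, "cost.state.dialysis"), 3000)
  expect_equal(p3$params$provenance[p3$params$name == "cost.state.dialysis"],
               "user")
  expect_equal(get_param(p3, "util.state.ckd3"), get_param(fx, "util.state.ckd3"))
  expect_equal(p3$params$provenance[p3$params$name == "util.state.ckd3"],
               "placeholder")

  # unknown fields and invalid values are named errors
  writeLines(c("parameters:", "  not.a.param: 1"), path)
  expect_error(load_parameters(path), "not.a.param")
  writeLines(c("parameters:", "  start.ckd3: {mean: 0.4514}"), path)
  expect_error(load_parameters(path), "start.ckd")

  # packaged reference config and life-table CSV load cleanly
  ref <- system.file("extdata", "reference_config.yaml", package = "hkcea")
  expect_equal(load_parameters(ref)$params$mean, fx$params$mean,
               tolerance = 1e-12)
  lt_path <- system.file("extdata", "lifetable_synthetic_uk.csv",
                         package = "hkcea")
  writeLines(c("parameters: {}", paste0("life_table: ", lt_path)), path)
  p4 <- load_parameters(path)
  expect_equal(nrow(p4$life_table), nrow(make_life_table()))
})

test_that("beta/gamma moment matching recovers mean and SE analytically", {
  cases <- list(c(0.5514, 0.0319), c(0.1033, 0.0103), c(0.8135, 0.0317),
                c(0.00543, 0.00054))
  for (cs in cases) {
    sh <- beta_moments(cs[1], cs[2])
    a <- sh[["shape1"]]; b <- sh[["shape2"]]
    expect_equal(a / (a + b), cs[1], tolerance = 1e-10)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), cs[2],
                 tolerance = 1e-10)
  }
  for (cs in list(c(223.11, 22.311), c(1.3, 0.195))) {
    g <- gamma_moments(cs[1], cs[2])
    expect_equal(g[["shape"]] / g[["rate"]], cs[1], tolerance = 1e-10)
    expect_equal(sqrt(g[["shape"]]) / g[["rate"]], cs[2], tolerance = 1e-10)
  }
  expect_error(beta_moments(0.5, 0.6), "infeasible")
})

test_that("PSA sampling is reproducible, respects degeneracy, and moment-matches", {
  set.seed(7); s1 <- sample_parameters(fx)
  set.seed(7); s2 <- sample_parameters(fx)
  expect_identical(s1$params$mean, s2$params$mean)
  expect_false(identical(s1$params$mean, fx$params$mean))

  # structural zeros stay exactly zero; zero-SE parameters unchanged
  expect_identical(get_param(s1, "start.nyha4"), 0)
  expect_identical(get_param(s1, "start.k_le5"), 0)
  expect_identical(get_param(s1, "start.hf"), 0.4198)

  # all SEs zero: the draw equals the base exactly
  p0 <- fx; p0$params$se[] <- 0
  set.seed(1)
  expect_identical(sample_parameters(p0)$params$mean, p0$params$mean)

  # sampled starting blocks stay on the simplex and sets stay valid
  set.seed(11)
  for (i in 1:20) {
    s <- sample_parameters(fx)
    expect_equal(nrow(validate_parameters(s)), 0L)
  }

  # infeasible beta request names the offending parameter
  pbad <- set_param(fx, "tx.response", se = 0.9)
  set.seed(2)
  expect_error(sample_parameters(pbad), "tx.response")
})

test_that("sampled age draws have the specified normal mean", {
  n <- 2000
  set.seed(123)
  ages <- vapply(seq_len(n), function(i) {
    get_param(sample_parameters(fx), "demo.age_mean")
  }, numeric(1))
  expect_lt(abs(mean(ages) - 65.30), 3 * 0.89 / sqrt(n))
  expect_lt(abs(sd(ages) - 0.89), 0.1)
})

test_that("synthetic life table is well-formed", {
  lt <- make_life_table()
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_setequal(unique(lt$sex), c("male", "female"))
  # female mortality below male at every age in the synthetic table
  m <- lt$qx[lt$sex == "male"]; f <- lt$qx[lt$sex == "female"]
  expect_true(all(f <= m))
})
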