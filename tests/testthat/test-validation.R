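test_that("RSD and RE match hand-computed sample statistics", {
  curve <- fit_weighted_line(c(1, 10, 100), c(0.01, 0.1, 1))  # y = 0.01 x
  inj <- dplyr::bind_rows(lapply(c(9, 10, 11), function(v) {
    inj_row("naringenin", area = 0.01 * v * 1e5, nominal = 10,
            level = "MQC")
  }))
  curves <- tibble::tibble(analyte = "naringenin", batch = 1L,
                           curve = list(curve))
  pa <- precision_accuracy(inj, curves)
  intra <- pa[pa$scope == "intra", ]
  expect_equal(intra$mean, 10, tolerance = 1e-9)
  expect_equal(intra$sd, 1, tolerance = 1e-9)      # sample sd, n - 1
  expect_equal(intra$rsd_pct, 10, tolerance = 1e-9)
  expect_equal(intra$re_pct, 0, tolerance = 1e-9)
  expect_true(intra$passed)
  # fewer than two replicates cannot yield an sd
  expect_error(precision_accuracy(inj[1, ], curves), "2 replicates")
})

test_that("carry-over ratios follow the generator arithmetic exactly", {
  # hand-assembled noise-free sequence: LLOQ, then ULOQ, then blank whose
  # analyte response is carryover_fraction x the ULOQ area
  lloq_area <- 200
  build <- function(cf) {
    dplyr::bind_rows(
      inj_row("naringenin", lloq_area, role = "lloq_ref"),
      inj_row("naringenin", lloq_area * 500, role = "uloq"),
      inj_row("naringenin", cf * lloq_area * 500, is_area = NA,
              role = "carryover_blank"))
  }
  co <- assess_carryover(build(2e-4))
  expect_equal(co$analytes$residual_ratio, 0.10, tolerance = 1e-12)
  expect_true(co$analytes$passed)
  expect_equal(co$is$residual_ratio, 0)   # IS added fresh; none in blank
  expect_true(co$passed)

  co2 <- assess_carryover(build(5e-4))
  expect_equal(co2$analytes$residual_ratio, 0.25, tolerance = 1e-12)
  expect_false(co2$analytes$passed)
  expect_error(assess_carryover(build(1e-4)[-1, ]), "LLOQ reference")
})

test_that("IS-MF cancels shared lot factors and tracks independent ones", {
  # shared factor: analyte and IS both scaled 0.8 -> MF 0.8/0.8, IS-MF 1
  mk <- function(lot, a_fac, is_fac, level = "LQC") {
    dplyr::bind_rows(
      inj_row("naringenin", 100 * a_fac, is_area = 1e5 * is_fac,
              role = "matrix_spiked", lot = lot, level = level),
      inj_row("naringenin", 100, is_area = 1e5,
              role = "matrix_neat", lot = "neat", level = level))
  }
  shared <- dplyr::bind_rows(lapply(1:6, function(i) mk(paste0("L", i),
                                                        0.8, 0.8)))
  me <- matrix_effect(shared)
  expect_equal(me$mean_ismf, 1, tolerance = 1e-12)
  expect_equal(me$rsd_pct, 0, tolerance = 1e-9)
  expect_true(me$passed)
  expect_equal(me$per_lot[[1]]$mf_analyte, rep(0.8, 6), tolerance = 1e-12)

  # independent analyte factors with unit IS factors: IS-MF = the factor
  facs <- c(0.90, 0.94, 0.98, 1.02, 1.06, 1.10)
  indep <- dplyr::bind_rows(lapply(1:6, function(i) mk(paste0("L", i),
                                                       facs[i], 1)))
  me2 <- matrix_effect(indep)
  expect_equal(sort(me2$per_lot[[1]]$ismf), facs, tolerance = 1e-12)
  expect_equal(me2$rsd_pct, 100 * stats::sd(facs) / mean(facs),
               tolerance = 1e-9)

  bad <- shared
  bad$area[bad$role == "matrix_neat"] <- 0
  expect_error(matrix_effect(bad), "zero neat")
})

test_that("IS-MF is invariant to rescaling all areas of a lot", {
  m <- instrument_model(default_panel, noise_cv = 0.03, seed = 21)
  suite <- simulate_validation_suite(default_panel, m, seed = 21)
  me1 <- matrix_effect(suite)
  scaled <- suite
  pick <- scaled$lot == "melot3"
  scaled$area[pick] <- scaled$area[pick] * 3.7
  scaled$is_area[pick] <- scaled$is_area[pick] * 3.7
  me2 <- matrix_effect(scaled)
  expect_equal(me1$mean_ismf, me2$mean_ismf, tolerance = 1e-12)
  expect_equal(me1$rsd_pct, me2$rsd_pct, tolerance = 1e-9)
})

test_that("dilution integrity multiplies back-calculated values by the factor", {
  curve <- fit_weighted_line(c(1, 10, 100), c(0.01, 0.1, 1))
  curves <- tibble::tibble(analyte = "naringenin", batch = 1L,
                           curve = list(curve))
  inj <- dplyr::bind_rows(lapply(1:3, function(i) {
    inj_row("naringenin", area = 0.01 * 75 * 1e5, role = "dilution",
            nominal = 750, level = "HQC", dilution = 10)
  }))
  di <- dilution_integrity(inj, curves)
  expect_equal(di$mean, 750, tolerance = 1e-9)
  expect_equal(di$re_pct, 0, tolerance = 1e-9)
  expect_true(di$passed)
  bad <- inj
  bad$dilution_factor <- 1
  expect_error(dilution_integrity(bad, curves), "exceed 1")
})

test_that("stability flags degradation beyond 15% and unknown conditions", {
  m0 <- noise_free_model()
  plan_deg <- validation_plan(stability_conditions = c(
    "long_term_1_month" = 1, "freeze_thaw_2_cycles" = 0.8))
  suite <- simulate_validation_suite(default_panel, m0, plan = plan_deg,
                                     seed = 4)
  curves <- fit_calibration(suite)
  stb <- stability_evaluate(suite, curves)
  fresh <- stb[stb$condition == "long_term_1_month", ]
  degraded <- stb[stb$condition == "freeze_thaw_2_cycles", ]
  expect_equal(fresh$re_pct, rep(0, nrow(fresh)), tolerance = 1e-9)
  expect_true(all(fresh$passed))
  expect_equal(degraded$re_pct, rep(-20, nrow(degraded)), tolerance = 1e-9)
  expect_false(any(degraded$passed))

  renamed <- suite
  renamed$condition[renamed$role == "stability"] <- "room_temp_1_week"
  expect_error(stability_evaluate(renamed, curves), "unknown condition")
})

test_that("selectivity passes clean blanks and fails interfering ones", {
  clean <- dplyr::bind_rows(
    inj_row("naringenin", 0, is_area = NA, role = "blank"),
    inj_row("naringenin", 100, role = "lloq_ref"))
  sel <- check_selectivity(clean)
  expect_true(sel$passed)
  dirty <- clean
  dirty$area[dirty$role == "blank"] <- 30
  sel2 <- check_selectivity(dirty)
  expect_false(sel2$analytes$passed)
})

test_that("replicate RSD estimates follow the n = 6 chi approximation", {
  # 50 sets of 6 injections x 10 analytes at the MQC level, cv 4%
  m <- instrument_model(default_panel, noise_cv = 0.04, seed = 31)
  conc <- default_panel$analytes$base_level_ng_per_ml[
    !default_panel$analytes$is_internal_standard] * 30
  analytes <- default_panel$analytes$name[
    !default_panel$analytes$is_internal_standard]
  rsds <- withr::with_seed(31, {
    unlist(lapply(1:50, function(s) {
      ratios <- sapply(1:6, function(i) {
        rec <- simulate_injection(conc, analytes, m)
        rec$area / rec$is_area
      })
      apply(ratios, 1, function(v) 100 * stats::sd(v) / mean(v))
    }))
  })
  n <- 6
  c4 <- sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  expected <- 100 * 0.04 * c4
  se <- stats::sd(rsds) / sqrt(length(rsds))
  expect_lt(abs(mean(rsds) - expected), 3 * se)
})

test_that("the orchestrated battery passes noise-free and isolates faults", {
  m0 <- noise_free_model()
  suite <- simulate_validation_suite(default_panel, m0, seed = 8)
  report <- run_validation(suite)
  expect_s3_class(report, "validation_report")
  expect_true(report$overall_pass)
  for (b in setdiff(names(report), "overall_pass")) {
    expect_true(report[[b]]$passed)
  }

  # injecting a 5e-4 carry-over fraction fails only the carry-over block
  mco <- instrument_model(default_panel, noise_cv = 0,
                          carryover_fraction = 5e-4, seed = 8)
  suite2 <- simulate_validation_suite(default_panel, mco, seed = 8)
  report2 <- run_validation(suite2)
  expect_false(report2$carryover$passed)
  expect_false(report2$overall_pass)
  expect_true(report2$matrix_effect$passed)
  expect_true(report2$stability$passed)
  expect_true(report2$precision_accuracy$passed)

  expect_error(run_validation(suite[suite$role != "standard", ]),
               "standard")
})
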