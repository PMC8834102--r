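test_that("noise-free injections reproduce the linear response exactly", {
  m <- noise_free_model()
  rec <- withr::with_seed(1, simulate_injection(
    true_conc = c(10, 0), analyte = c("naringenin", "apigenin"), m))
  expect_equal(rec$area[1] / rec$is_area[1], m$slope[["naringenin"]] * 10)
  expect_equal(rec$area[2], 0)  # zero conc, zero intercept, no carry-over
  expect_error(simulate_injection(-1, "naringenin", m),
               "negative concentration")
})

test_that("the lognormal noise factor has mean 1 and CV equal to noise_cv", {
  m <- instrument_model(default_panel, noise_cv = 0.05, seed = 7)
  n <- 10000
  rec <- withr::with_seed(7, simulate_injection(
    true_conc = rep(50, n), analyte = rep("naringenin", n), m))
  ratio <- rec$area / rec$is_area
  cv_hat <- stats::sd(ratio) / mean(ratio)
  expect_lt(abs(cv_hat - 0.05), 0.002)
  expect_equal(mean(ratio), m$slope[["naringenin"]] * 50, tolerance = 0.01)
})

test_that("equal seeds give identical tables, different seeds differ", {
  m <- instrument_model(default_panel, noise_cv = 0.05, seed = 11)
  b1 <- simulate_calibration_batch(default_panel, m, seed = 11)
  b2 <- simulate_calibration_batch(default_panel, m, seed = 11)
  b3 <- simulate_calibration_batch(default_panel, m, seed = 12)
  expect_identical(b1, b2)
  expect_false(isTRUE(all.equal(b1$area, b3$area)))

  # byte-identical CSV output under equal seeds
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_injections(b1, p1)
  write_injections(b2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("calibration batches carry blank, zero, and the 8 design levels", {
  m <- noise_free_model()
  b <- simulate_calibration_batch(default_panel, m)
  roles <- unique(b[, c("sample_id", "role")])$role
  expect_equal(sum(roles == "blank"), 1L)
  expect_equal(sum(roles == "zero"), 1L)
  expect_equal(sum(roles == "standard"), 8L)
  # blank processed without IS; zero has IS but zero nominal
  expect_true(all(is.na(b$is_area[b$role == "blank"])))
  expect_true(all(!is.na(b$is_area[b$role == "zero"])))
  expect_true(all(b$nominal_ng_per_ml[b$role == "zero"] == 0))
  # noise-free data recover slope/intercept to machine precision
  curves <- fit_calibration(b)
  expect_equal(curves$slope,
               unname(m$slope[curves$analyte]), tolerance = 1e-9)
  expect_equal(curves$intercept, rep(0, nrow(curves)), tolerance = 1e-12)
})

test_that("validation suite has the planned replicate structure", {
  m <- noise_free_model()
  suite <- simulate_validation_suite(default_panel, m, seed = 5)
  per_analyte <- dplyr::count(
    dplyr::filter(suite, analyte == "naringenin"), role)
  counts <- stats::setNames(per_analyte$n, per_analyte$role)
  expect_equal(counts[["qc"]], 3L * 6L * 4L)        # batches x reps x levels
  expect_equal(counts[["matrix_spiked"]], 6L * 3L * 2L)
  expect_equal(counts[["matrix_neat"]], 6L * 3L * 2L)
  expect_equal(counts[["dilution"]], 2L * 3L)
  expect_equal(counts[["stability"]], 5L * 2L * 3L)
  expect_equal(counts[["carryover_blank"]], 1L)
  # stability with unit degradation is exactly the nominal, noise-free
  st <- dplyr::filter(suite, role == "stability")
  expect_equal(st$area / st$is_area,
               unname(m$slope[st$analyte]) * st$nominal_ng_per_ml,
               tolerance = 1e-12)
})

test_that("carry-over residual is linear in the carryover fraction", {
  a <- default_panel$analytes[!default_panel$analytes$is_internal_standard, ]
  residual_for <- function(cf) {
    m <- instrument_model(default_panel, noise_cv = 0,
                          carryover_fraction = cf, seed = 3)
    uloq <- simulate_injection(a$base_level_ng_per_ml * 500, a$name, m,
                               prev_area = 0)
    blank <- simulate_injection(rep(0, nrow(a)), a$name, m,
                                prev_area = uloq$area, with_is = FALSE)
    lloq <- simulate_injection(a$base_level_ng_per_ml, a$name, m,
                               prev_area = 0)
    mean(blank$area / lloq$area)
  }
  r1 <- residual_for(1e-4)
  r2 <- residual_for(2e-4)
  expect_equal(r2 / r1, 2, tolerance = 1e-12)
  expect_equal(r1, 0.05, tolerance = 1e-12)  # 1e-4 x the 500-fold range
})

test_that("excretion truth telescopes to the configured dose fractions", {
  em <- excretion_model(rat_cv = 0, seed = 9)
  study <- simulate_excretion_study(default_panel, em)
  totals <- dplyr::summarise(
    dplyr::group_by(study$truth, rat_id, analyte),
    total = sum(amount_nmol_true), .groups = "drop")
  dose_nmol <- dose_to_nmol(em$body_weight_kg[1], em$dose_mg_per_kg,
                            default_panel$design$dose_compound_molar_mass)
  k <- em$elimination_rate[totals$analyte[1]]
  expected <- em$fractions[totals$analyte] * dose_nmol * (1 - exp(-k * 48))
  r1 <- totals[totals$rat_id == "rat1", ]
  dose1 <- dose_to_nmol(em$body_weight_kg[1], em$dose_mg_per_kg,
                        default_panel$design$dose_compound_molar_mass)
  expect_equal(r1$total,
               unname(em$fractions[r1$analyte] * dose1 * (1 - exp(-0.15 * 48))),
               tolerance = 1e-9)
  # zero-volume intervals report zero concentration but keep the row
  em0 <- excretion_model(rat_cv = 0, seed = 9,
                         urine_volume_ml = matrix(
                           c(rep(3, 5), 0, rep(3, 24)), nrow = 5))
  st0 <- simulate_excretion_study(default_panel, em0)
  zero_rows <- st0$urine[st0$urine$volume_ml == 0, ]
  expect_gt(nrow(zero_rows), 0)
  expect_true(all(zero_rows$conc_ng_per_ml == 0))
})

test_that("excretion model rejects malformed inputs", {
  expect_error(excretion_model(intervals = cbind(c(0, 5), c(4, 8))),
               "contiguous")
  expect_error(excretion_model(intervals = cbind(c(1, 4), c(4, 8))),
               "start at 0")
  expect_error(excretion_model(fractions = c("naringenin" = 1.2)))
  expect_warning(excretion_model(body_weight_kg = 0.1), "body weight")
})
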