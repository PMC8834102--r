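# Seeded synthetic data generator. Emulates the statistical structure the
# analysis assumes: linear instrument response in the analyte/IS area ratio,
# multiplicative lognormal measurement noise with mean 1, per-lot matrix
# factors, additive carry-over from the immediately preceding injection on
# the analyte channel, and first-order urinary elimination.

#' Per-lot matrix factors
#'
#' Multiplicative ionization factors applied to areas measured in a given
#' urine lot. When `is_factor` equals `analyte_factor` the factors cancel in
#' the IS-normalized matrix factor (IS-MF = 1); independent values exercise
#' matrix-effect failure paths.
#'
#' @param lot Character vector of lot labels.
#' @param analyte_factor,is_factor Positive multipliers, recycled.
#' @return Tibble with columns lot, analyte_factor, is_factor.
#' @export
lot_factors <- function(lot = "lot1", analyte_factor = 1,
                        is_factor = analyte_factor) {
  stopifnot(all(analyte_factor > 0), all(is_factor > 0))
  tibble::tibble(lot = lot, analyte_factor = analyte_factor,
                 is_factor = is_factor)
}

#' Instrument response model
#'
#' The measured analyte area for a sample at true concentration x in lot L is
#' \deqn{A = (a + b x) \cdot A_{IS}^{nom} \cdot f_L \cdot e^{\eta}
#'        \cdot e^{\epsilon} + c \cdot A_{prev}}
#' with slope b and intercept a expressed on the area-ratio scale. Two
#' lognormal factors act per injection: \eqn{e^{\eta}} is the shared
#' injection-level factor (ion source and injection volume fluctuation,
#' common to all channels, the variability the internal standard corrects),
#' and \eqn{e^{\epsilon}} is the analyte channel's own factor. Both have
#' mean 1 and coefficient of variation `noise_cv`
#' (\eqn{\sigma^2 = \log(1 + cv^2)}, mean \eqn{-\sigma^2/2}). The IS area
#' is \eqn{A_{IS}^{nom} \cdot g_L \cdot e^{\eta}}, so the analyte/IS area
#' ratio is \eqn{(a + b x)(f_L/g_L) e^{\epsilon}} with CV exactly
#' `noise_cv`. \eqn{f_L, g_L} are the lot's analyte and IS matrix factors
#' and c the carry-over fraction of the previous injection's analyte area
#' (analyte channel only: IS is added fresh to every processed sample).
#'
#' @param panel An `mrm_panel`; slopes default per analyte to
#'   `1 / (500 * base_level)` so the area ratio reaches 1 at the top
#'   standard regardless of the analyte's range.
#' @param slope Named numeric vector of slopes (ratio per ng/mL) for the
#'   non-IS analytes, or a scalar recycled to all.
#' @param intercept Intercept on the ratio scale (default 0).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param carryover_fraction Fraction of the previous injection's analyte
#'   area carried into the next injection.
#' @param is_area_nominal Nominal IS peak area (arbitrary units).
#' @param lots A [lot_factors()] table; defaults to one unit lot.
#' @param seed Integer seed; identical seed and parameters give
#'   byte-identical simulated tables.
#' @return A list of class `instrument_model`.
#' @export
instrument_model <- function(panel, slope = NULL, intercept = 0,
                             noise_cv = 0.05, carryover_fraction = 0,
                             is_area_nominal = 1e5, lots = lot_factors(),
                             seed = 1L) {
  analytes <- panel$analytes$name[!panel$analytes$is_internal_standard]
  base <- panel$analytes$base_level_ng_per_ml[!panel$analytes$is_internal_standard]
  top_mult <- max(panel$design$level_multipliers)
  if (is.null(slope)) slope <- 1 / (top_mult * base)
  if (length(slope) == 1L) slope <- rep(slope, length(analytes))
  if (is.null(names(slope))) names(slope) <- analytes
  if (length(intercept) == 1L) intercept <- rep(intercept, length(analytes))
  if (is.null(names(intercept))) names(intercept) <- analytes
  stopifnot(all(slope > 0), noise_cv >= 0, carryover_fraction >= 0,
            is_area_nominal > 0)
  structure(
    list(slope = slope, intercept = intercept, noise_cv = noise_cv,
         carryover_fraction = carryover_fraction,
         is_area_nominal = is_area_nominal, lots = lots,
         seed = as.integer(seed)),
    class = "instrument_model")
}

# One multiplicative lognormal noise factor per element of n; mean 1,
# CV = cv. cv = 0 degenerates to exactly 1.
.noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -sigma2 / 2, sd = sqrt(sigma2)))
}

.lot_row <- function(model, lot) {
  row <- model$lots[model$lots$lot == lot, ]
  if (nrow(row) == 0L) {
    tibble::tibble(lot = lot, analyte_factor = 1, is_factor = 1)
  } else {
    row
  }
}

#' Simulate one injection
#'
#' Draws areas for every requested analyte channel plus the IS channel of a
#' single injection, using the current RNG state (seed handling belongs to
#' the batch-level simulators). Carry-over adds
#' `carryover_fraction * prev_area` on the analyte channel only: the IS is
#' added fresh to every processed sample via the precipitation solvent, so
#' a sample processed without IS shows no IS signal.
#'
#' @param true_conc Numeric vector of true concentrations (ng/mL), one per
#'   analyte; must be non-negative.
#' @param analyte Character vector of analyte names, parallel to `true_conc`.
#' @param model An [instrument_model()].
#' @param prev_area Previous injection's analyte areas (same order), for
#'   carry-over; default 0.
#' @param lot Lot label looked up in the model's lot factors.
#' @param with_is Was IS added to this sample? `FALSE` for a true blank.
#' @return Tibble with columns analyte, area, is_area (NA when `with_is`
#'   is `FALSE`).
#' @export
simulate_injection <- function(true_conc, analyte, model, prev_area = 0,
                               lot = "lot1", with_is = TRUE) {
  if (any(true_conc < 0)) stop("negative concentration", call. = FALSE)
  stopifnot(length(true_conc) == length(analyte))
  prev_area <- rep_len(prev_area, length(analyte))
  lf <- .lot_row(model, lot)
  ratio_true <- model$intercept[analyte] + model$slope[analyte] * true_conc
  shared <- .noise_factor(1, model$noise_cv)  # injection-level factor
  area <- ratio_true * model$is_area_nominal * lf$analyte_factor * shared *
    .noise_factor(length(analyte), model$noise_cv) +
    model$carryover_fraction * prev_area
  is_area <- if (with_is) {
    model$is_area_nominal * lf$is_factor * shared
  } else {
    NA_real_
  }
  tibble::tibble(analyte = analyte, area = unname(area), is_area = is_area)
}

# Simulate an ordered injection sequence. `samples` is a tibble with one row
# per injection: role, level_label, lot, with_is, dilution_factor, condition,
# and a list-column conc of named concentration vectors (ng/mL). Carry-over
# is chained through the sequence per analyte channel.
.simulate_sequence <- function(samples, model, batch = 1L, start_index = 1L) {
  analytes <- names(model$slope)
  prev <- stats::setNames(rep(0, length(analytes)), analytes)
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    conc <- samples$conc[[i]][analytes]
    rec <- simulate_injection(unname(conc), analytes, model,
                              prev_area = prev[analytes],
                              lot = samples$lot[i],
                              with_is = samples$with_is[i])
    prev <- stats::setNames(rec$area, rec$analyte)
    nominal <- samples$nominal[[i]][analytes]
    out[[i]] <- tibble::tibble(
      sample_id = samples$sample_id[i],
      role = samples$role[i],
      batch = batch,
      lot = samples$lot[i],
      injection_index = start_index + i - 1L,
      analyte = rec$analyte,
      area = rec$area,
      is_area = rec$is_area,
      nominal_ng_per_ml = unname(nominal),
      level_label = samples$level_label[i],
      dilution_factor = samples$dilution_factor[i],
      condition = samples$condition[i]
    )
  }
  dplyr::bind_rows(out)
}

# Build the `samples` scaffold used by .simulate_sequence.
.sample_row <- function(sample_id, role, conc, nominal = conc, lot = "lot1",
                        with_is = TRUE, level_label = NA_character_,
                        dilution_factor = 1, condition = NA_character_) {
  tibble::tibble(sample_id = sample_id, role = role, conc = list(conc),
                 nominal = list(nominal), lot = lot, with_is = with_is,
                 level_label = level_label, dilution_factor = dilution_factor,
                 condition = condition)
}

.panel_conc <- function(panel, multiplier) {
  a <- panel$analytes[!panel$analytes$is_internal_standard, ]
  stats::setNames(a$base_level_ng_per_ml * multiplier, a$name)
}

#' Simulate one calibration batch
#'
#' Emits an ordered injection sequence: one blank (processed without
#' analytes and IS), one zero-concentration sample (IS only), then the
#' eight standards from the panel's level design, all analytes spiked
#' together at their own concentrations. Carry-over chains through the
#' sequence.
#'
#' @param panel An `mrm_panel`.
#' @param model An [instrument_model()].
#' @param batch Integer batch label.
#' @param lot Urine lot used for the batch.
#' @param seed Seed for this batch; defaults to `model$seed + batch - 1`.
#'   `NULL` draws from the current RNG state instead of reseeding (used by
#'   [simulate_validation_suite()], which seeds one stream for the whole
#'   suite).
#' @return Injection tibble (one row per analyte per injection).
#' @export
simulate_calibration_batch <- function(panel, model, batch = 1L,
                                       lot = "lot1",
                                       seed = model$seed + batch - 1L) {
  zero <- .panel_conc(panel, 0)
  rows <- dplyr::bind_rows(
    .sample_row(sprintf("b%d_blank", batch), "blank", zero, lot = lot,
                with_is = FALSE),
    .sample_row(sprintf("b%d_zero", batch), "zero", zero, lot = lot),
    dplyr::bind_rows(lapply(seq_along(panel$design$level_multipliers),
      function(i) {
        m <- panel$design$level_multipliers[i]
        .sample_row(sprintf("b%d_std%d", batch, i), "standard",
                    .panel_conc(panel, m), lot = lot,
                    level_label = sprintf("S%d", i))
      }))
  )
  if (is.null(seed)) {
    .simulate_sequence(rows, model, batch = batch)
  } else {
    withr::with_seed(seed, .simulate_sequence(rows, model, batch = batch))
  }
}

#' Validation study plan
#'
#' Replicate structure of the validation battery: precision/accuracy with
#' `pa_batches` batches of `pa_replicates` replicates at LLOQ/LQC/MQC/HQC;
#' matrix effect over `me_lots` urine lots with `me_replicates` replicates
#' at LQC and HQC (post-extraction spiked and matched neat solutions);
#' dilution integrity at `dilution_factors` times HQC; stability conditions
#' with per-condition degradation factors (1 = no degradation).
#'
#' @param pa_batches,pa_replicates Precision/accuracy batches and replicates.
#' @param me_lots,me_replicates Matrix-effect lots and replicates per lot.
#' @param dilution_factors Fold-concentrations above HQC assayed after
#'   dilution back to HQC.
#' @param dilution_replicates Replicates per dilution factor.
#' @param stability_conditions Named numeric vector: condition label ->
#'   degradation factor applied to the true concentration.
#' @param stability_replicates Replicates per condition and level.
#' @return A list of class `validation_plan`.
#' @export
validation_plan <- function(pa_batches = 3L, pa_replicates = 6L,
                            me_lots = 6L, me_replicates = 3L,
                            dilution_factors = c(5, 10),
                            dilution_replicates = 3L,
                            stability_conditions = c(
                              "long_term_1_month" = 1,
                              "long_term_3_months" = 1,
                              "freeze_thaw_1_cycle" = 1,
                              "freeze_thaw_2_cycles" = 1,
                              "autosampler_24_h" = 1),
                            stability_replicates = 3L) {
  stopifnot(pa_batches >= 1, pa_replicates >= 1, me_lots >= 1,
            me_replicates >= 1, all(dilution_factors > 1),
            dilution_replicates >= 1, all(stability_conditions > 0))
  structure(list(pa_batches = pa_batches, pa_replicates = pa_replicates,
                 me_lots = me_lots, me_replicates = me_replicates,
                 dilution_factors = dilution_factors,
                 dilution_replicates = dilution_replicates,
                 stability_conditions = stability_conditions,
                 stability_replicates = stability_replicates),
            class = "validation_plan")
}

#' Simulate the full validation suite
#'
#' Generates every injection the validation battery needs, in one table
#' keyed by `role`: calibration batches (roles blank/zero/standard), QC
#' replicates for precision/accuracy (role qc), carry-over sequences (roles
#' lloq_ref, uloq, carryover_blank), matrix-effect sets (roles
#' matrix_spiked, matrix_neat), dilution-integrity samples (role dilution)
#' and stability samples (role stability). Matrix-effect injections use
#' lots `melot1..melotK` from the model's lot-factor table; everything else
#' uses `lot1`.
#'
#' @param panel An `mrm_panel`.
#' @param model An [instrument_model()].
#' @param plan A [validation_plan()].
#' @param seed Master seed; sub-experiments draw from it deterministically.
#' @return Injection tibble covering all roles.
#' @export
simulate_validation_suite <- function(panel, model, plan = validation_plan(),
                                      seed = model$seed) {
  qc_mult <- stats::setNames(c(1, panel$design$qc_multipliers),
                             c("LLOQ", "LQC", "MQC", "HQC"))
  hqc_mult <- panel$design$qc_multipliers[3]
  uloq_mult <- max(panel$design$level_multipliers)

  withr::local_seed(seed)

  cal <- dplyr::bind_rows(lapply(seq_len(plan$pa_batches), function(b) {
    simulate_calibration_batch(panel, model, batch = b, seed = NULL)
  }))

  qc_rows <- function(batch) {
    dplyr::bind_rows(lapply(names(qc_mult), function(lv) {
      dplyr::bind_rows(lapply(seq_len(plan$pa_replicates), function(r) {
        .sample_row(sprintf("b%d_%s_r%d", batch, lv, r), "qc",
                    .panel_conc(panel, qc_mult[[lv]]), level_label = lv)
      }))
    }))
  }
  qc <- dplyr::bind_rows(lapply(seq_len(plan$pa_batches), function(b) {
    .simulate_sequence(qc_rows(b), model, batch = b)
  }))

  co_rows <- dplyr::bind_rows(
    lapply(1:3, function(r) {
      .sample_row(sprintf("co_lloq_r%d", r), "lloq_ref",
                  .panel_conc(panel, 1))
    }),
    .sample_row("co_uloq", "uloq", .panel_conc(panel, uloq_mult)),
    .sample_row("co_blank", "carryover_blank", .panel_conc(panel, 0),
                with_is = FALSE)
  )
  carryover <- .simulate_sequence(co_rows, model)

  me_lots <- sprintf("melot%d", seq_len(plan$me_lots))
  me_rows <- dplyr::bind_rows(lapply(me_lots, function(lt) {
    dplyr::bind_rows(lapply(c("LQC", "HQC"), function(lv) {
      conc <- .panel_conc(panel, qc_mult[[lv]])
      dplyr::bind_rows(lapply(seq_len(plan$me_replicates), function(r) {
        dplyr::bind_rows(
          .sample_row(sprintf("me_%s_%s_sp_r%d", lt, lv, r), "matrix_spiked",
                      conc, lot = lt, level_label = lv),
          .sample_row(sprintf("me_%s_%s_nt_r%d", lt, lv, r), "matrix_neat",
                      conc, lot = "neat", level_label = lv)
        )
      }))
    }))
  }))
  matrix_effect <- .simulate_sequence(me_rows, model)

  dil_rows <- dplyr::bind_rows(lapply(plan$dilution_factors, function(df) {
    hqc <- .panel_conc(panel, hqc_mult)
    dplyr::bind_rows(lapply(seq_len(plan$dilution_replicates), function(r) {
      # sample prepared at df x HQC then diluted back to HQC before injection
      .sample_row(sprintf("dil%gx_r%d", df, r), "dilution",
                  conc = hqc, nominal = hqc * df,
                  level_label = "HQC", dilution_factor = df)
    }))
  }))
  dilution <- .simulate_sequence(dil_rows, model)

  stab_rows <- dplyr::bind_rows(lapply(names(plan$stability_conditions),
    function(cond) {
      fac <- plan$stability_conditions[[cond]]
      dplyr::bind_rows(lapply(c("LQC", "HQC"), function(lv) {
        conc <- .panel_conc(panel, qc_mult[[lv]])
        dplyr::bind_rows(lapply(seq_len(plan$stability_replicates),
          function(r) {
            .sample_row(sprintf("st_%s_%s_r%d", cond, lv, r), "stability",
                        conc = conc * fac, nominal = conc,
                        level_label = lv, condition = cond)
          }))
      }))
    }))
  stability <- .simulate_sequence(stab_rows, model)

  dplyr::bind_rows(cal, qc, carryover, matrix_effect, dilution, stability)
}

#' Urinary excretion model
#'
#' First-order elimination of each metabolite into urine: the true amount
#' excreted in interval \[t1, t2\] is
#' \eqn{F_m \cdot D \cdot (e^{-k t_1} - e^{-k t_2})} nmol, where D is the
#' molar dose and \eqn{F_m} the metabolite's molar fraction of dose
#' recovered at infinite time. Per-rat fractions optionally get a lognormal
#' spread (mean 1, CV `rat_cv`) to emulate individual differences.
#'
#' @param n_rats Number of rats.
#' @param dose_mg_per_kg Oral dose (default 42 mg/kg).
#' @param body_weight_kg Per-rat body weights, recycled to `n_rats`.
#' @param fractions Named molar dose fractions per metabolite; the defaults
#'   total 0.0427 with the naringenin glucuronides dominating, then
#'   naringenin, then the minor metabolites.
#' @param elimination_rate First-order rate constant(s), 1/h; default 0.15
#'   (about 97% of the excreted material appears within 24 h).
#' @param urine_volume_ml Per-interval urine volumes (mL), either a vector
#'   recycled across rats or an `n_rats x n_intervals` matrix; zero volumes
#'   are legal.
#' @param intervals Two-column matrix of (start, end) hours; contiguous,
#'   starting at 0.
#' @param rat_cv Between-rat lognormal CV on the dose fractions (0 = none).
#' @param seed Integer seed.
#' @return A list of class `excretion_model`.
#' @export
excretion_model <- function(n_rats = 5L, dose_mg_per_kg = 42,
                            body_weight_kg = c(0.32, 0.35, 0.33, 0.38, 0.36),
                            fractions = default_dose_fractions(),
                            elimination_rate = 0.15,
                            urine_volume_ml = c(3.5, 3.0, 2.5, 6.0, 5.0, 4.5),
                            intervals = default_intervals(),
                            rat_cv = 0.25, seed = 1L) {
  body_weight_kg <- rep_len(body_weight_kg, n_rats)
  stopifnot(all(fractions >= 0), sum(fractions) <= 1,
            all(elimination_rate > 0), dose_mg_per_kg > 0,
            all(body_weight_kg > 0), rat_cv >= 0)
  if (any(body_weight_kg < 0.2 | body_weight_kg > 0.6)) {
    warning("body weight outside the plausible 0.2-0.6 kg window")
  }
  .check_intervals(intervals)
  if (is.matrix(urine_volume_ml)) {
    stopifnot(nrow(urine_volume_ml) == n_rats,
              ncol(urine_volume_ml) == nrow(intervals))
  } else {
    urine_volume_ml <- matrix(rep(rep_len(urine_volume_ml, nrow(intervals)),
                                  each = n_rats),
                              nrow = n_rats)
  }
  stopifnot(all(urine_volume_ml >= 0))
  if (length(elimination_rate) == 1L) {
    elimination_rate <- stats::setNames(rep(elimination_rate,
                                            length(fractions)),
                                        names(fractions))
  }
  structure(list(n_rats = n_rats, dose_mg_per_kg = dose_mg_per_kg,
                 body_weight_kg = body_weight_kg, fractions = fractions,
                 elimination_rate = elimination_rate,
                 urine_volume_ml = urine_volume_ml, intervals = intervals,
                 rat_cv = rat_cv, seed = as.integer(seed)),
            class = "excretion_model")
}

#' Default urine collection intervals (hours post dose)
#' @return Two-column matrix of the six intervals 0-4, 4-8, 8-12, 12-24,
#'   24-36 and 36-48 h.
#' @export
default_intervals <- function() {
  cbind(start = c(0, 4, 8, 12, 24, 36), end = c(4, 8, 12, 24, 36, 48))
}

#' Default molar dose fractions per metabolite
#'
#' Proportional to the observed qualitative ranking (the two naringenin
#' glucuronides dominate, then naringenin, then the minor metabolites),
#' scaled to a total urinary recovery of 4.27% of the molar dose.
#'
#' @param total Total molar fraction of dose recovered in urine.
#' @return Named numeric vector over the ten metabolites.
#' @export
default_dose_fractions <- function(total = 0.0427) {
  w <- c("naringenin" = 0.14,
         "naringenin-7-O-glucuronide" = 0.36,
         "naringenin-4'-O-glucuronide" = 0.30,
         "apigenin" = 0.015,
         "eriodictyol" = 0.02,
         "homoeriodictyol" = 0.02,
         "hesperetin" = 0.025,
         "hesperetin-7-O-glucuronide" = 0.045,
         "hesperetin-3'-O-glucuronide" = 0.04,
         "hesperetin-7-O-sulfate" = 0.035)
  total * w / sum(w)
}

.check_intervals <- function(intervals) {
  stopifnot(is.matrix(intervals), ncol(intervals) == 2)
  if (intervals[1, 1] != 0) stop("intervals must start at 0", call. = FALSE)
  if (any(intervals[, 2] <= intervals[, 1])) {
    stop("each interval needs end > start", call. = FALSE)
  }
  if (nrow(intervals) > 1 &&
      any(abs(intervals[-1, 1] - intervals[-nrow(intervals), 2]) > 1e-12)) {
    stop("intervals must be contiguous and non-overlapping", call. = FALSE)
  }
  invisible(intervals)
}

#' Simulate a urinary excretion study
#'
#' For each rat and collection interval the true excreted amount of each
#' metabolite follows the first-order model of [excretion_model()]; the
#' true urine concentration is amount x molar mass / volume (ng/mL; 0 when
#' the interval's volume is 0), and the measured concentration multiplies
#' in the instrument's lognormal noise factor (noise-free when `imodel` is
#' `NULL`).
#'
#' @param panel An `mrm_panel` (supplies molar masses).
#' @param emodel An [excretion_model()].
#' @param imodel Optional [instrument_model()]; only its `noise_cv` is used.
#' @return List with tibbles `urine` (rat_id, t_start_h, t_end_h, volume_ml,
#'   analyte, conc_ng_per_ml), `doses` (rat_id, body_weight_kg,
#'   dose_mg_per_kg) and `truth` (per rat/analyte/interval true amount in
#'   nmol and true concentration).
#' @export
simulate_excretion_study <- function(panel, emodel, imodel = NULL) {
  a <- panel$analytes[!panel$analytes$is_internal_standard, ]
  mm <- stats::setNames(a$molar_mass, a$name)
  mets <- names(emodel$fractions)
  stopifnot(all(mets %in% names(mm)))
  dose_mm <- panel$design$dose_compound_molar_mass
  noise_cv <- if (is.null(imodel)) 0 else imodel$noise_cv

  withr::with_seed(emodel$seed, {
    doses <- tibble::tibble(
      rat_id = sprintf("rat%d", seq_len(emodel$n_rats)),
      body_weight_kg = emodel$body_weight_kg,
      dose_mg_per_kg = emodel$dose_mg_per_kg)
    out <- vector("list", emodel$n_rats)
    for (r in seq_len(emodel$n_rats)) {
      dose_nmol <- dose_to_nmol(emodel$body_weight_kg[r],
                                emodel$dose_mg_per_kg, dose_mm)
      frac <- emodel$fractions *
        .noise_factor(length(emodel$fractions), emodel$rat_cv)
      grid <- tidyr::expand_grid(
        i = seq_len(nrow(emodel$intervals)), analyte = mets)
      k <- emodel$elimination_rate[grid$analyte]
      t1 <- emodel$intervals[grid$i, 1]
      t2 <- emodel$intervals[grid$i, 2]
      amount <- frac[grid$analyte] * dose_nmol * (exp(-k * t1) - exp(-k * t2))
      vol <- emodel$urine_volume_ml[r, grid$i]
      conc_true <- ifelse(vol > 0, amount * mm[grid$analyte] / vol, 0)
      conc_meas <- conc_true * .noise_factor(length(conc_true), noise_cv)
      out[[r]] <- tibble::tibble(
        rat_id = doses$rat_id[r], t_start_h = t1, t_end_h = t2,
        volume_ml = vol, analyte = grid$analyte,
        conc_ng_per_ml = conc_meas, conc_true = conc_true,
        amount_nmol_true = amount)
    }
    all <- dplyr::bind_rows(out)
    list(urine = all[, c("rat_id", "t_start_h", "t_end_h", "volume_ml",
                         "analyte", "conc_ng_per_ml")],
         doses = doses,
         truth = all[, c("rat_id", "t_start_h", "t_end_h", "volume_ml",
                         "analyte", "conc_true", "amount_nmol_true")])
  })
}
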