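# Molar mass-balance urinary excretion analysis: per-interval amounts in
# nmol, cumulative profiles, and percent of the molar naringin dose
# recovered, per rat and for the cohort.

#' Molar amount excreted in one collection interval
#'
#' nmol = concentration (ng/mL) x volume (mL) / molar mass (g/mol); the
#' units collapse exactly (ng / (g/mol) = nmol). A zero urine volume
#' contributes zero.
#'
#' @param conc Concentration in ng/mL (>= 0).
#' @param volume Urine volume in mL (>= 0).
#' @param molar_mass Metabolite average molar mass, g/mol (> 0).
#' @return Amount in nmol.
#' @export
#' @examples
#' interval_amount(448.38, 1, 448.38)  # 1 nmol
interval_amount <- function(conc, volume, molar_mass) {
  if (any(molar_mass <= 0)) stop("molar_mass must be positive", call. = FALSE)
  if (any(conc < 0) || any(volume < 0)) {
    stop("concentration and volume must be non-negative", call. = FALSE)
  }
  conc * volume / molar_mass
}

#' Molar dose from a dose record
#'
#' dose_nmol = 1e6 x body weight (kg) x dose (mg/kg) / molar mass (g/mol):
#' the administered milligrams converted to nanomoles of the dosed
#' compound.
#'
#' @param body_weight_kg Body weight, kg.
#' @param dose_mg_per_kg Dose, mg/kg (default 42).
#' @param molar_mass Molar mass of the dosed compound (naringin), g/mol.
#' @return Dose in nmol.
#' @export
#' @examples
#' dose_to_nmol(0.35, 42, formula_mass("C27H32O14"))  # ~25321 nmol
dose_to_nmol <- function(body_weight_kg, dose_mg_per_kg = 42, molar_mass) {
  if (any(is.na(body_weight_kg))) stop("missing body weight", call. = FALSE)
  stopifnot(all(body_weight_kg > 0), all(dose_mg_per_kg > 0),
            all(molar_mass > 0))
  1e6 * body_weight_kg * dose_mg_per_kg / molar_mass
}

#' Cumulative excretion profile
#'
#' Running molar sums over time-ordered, contiguous collection intervals,
#' per rat and analyte. Intervals with zero volume contribute zero but stay
#' in the series, so the profile is defined at every collection time.
#'
#' @param amounts Tibble with rat_id, analyte, t_start_h, t_end_h,
#'   amount_nmol.
#' @return The input, ordered by time within rat x analyte, with a
#'   `cumulative_nmol` column. Errors on overlapping intervals.
#' @export
cumulative_profile <- function(amounts) {
  out <- dplyr::arrange(amounts, .data$rat_id, .data$analyte,
                        .data$t_start_h)
  grouped <- dplyr::group_by(out, .data$rat_id, .data$analyte)
  chk <- dplyr::summarise(
    grouped,
    overlap = any(.data$t_start_h[-1] < .data$t_end_h[-length(.data$t_end_h)]),
    .groups = "drop")
  if (any(chk$overlap, na.rm = TRUE)) {
    stop("overlapping collection intervals", call. = FALSE)
  }
  dplyr::ungroup(dplyr::mutate(grouped,
                               cumulative_nmol = cumsum(.data$amount_nmol)))
}

#' Percent of dose recovered
#'
#' Per-rat percentage = 100 x total excreted nmol / dose nmol; the cohort
#' mean is the unweighted arithmetic mean of the per-rat percentages.
#'
#' @param total_nmol Per-rat total excreted amounts (nmol).
#' @param dose_nmol Per-rat molar doses (nmol), recycled.
#' @return List: `per_rat` percentages and `cohort_mean`.
#' @export
#' @examples
#' percent_recovery(c(691.6, 1296, 1428, 903.8, 1083),
#'                  100 * c(691.6, 1296, 1428, 903.8, 1083) /
#'                    c(2.68, 5.00, 6.14, 3.14, 4.42))
percent_recovery <- function(total_nmol, dose_nmol) {
  if (any(dose_nmol <= 0)) stop("zero or negative dose", call. = FALSE)
  per_rat <- 100 * total_nmol / dose_nmol
  list(per_rat = per_rat, cohort_mean = mean(per_rat))
}

#' Summarize a urinary excretion study
#'
#' Converts per-interval urine concentrations to molar amounts using each
#' metabolite's own average molar mass, builds cumulative profiles, totals
#' per rat, and expresses totals as percent of the molar naringin dose.
#' Concentrations below the analyte's LLOQ can be zeroed (`bql = "zero"`,
#' the conservative default, applied only when an `lloq` lookup is given)
#' or imputed at LLOQ/2.
#'
#' @param urine Tibble: rat_id, t_start_h, t_end_h, volume_ml, analyte,
#'   conc_ng_per_ml.
#' @param doses Tibble: rat_id, body_weight_kg, dose_mg_per_kg.
#' @param panel An `mrm_panel` (molar masses and the naringin dose mass).
#' @param bql `"zero"` or `"half_lloq"` treatment for sub-LLOQ values.
#' @param lloq Optional named vector of LLOQs (ng/mL) per analyte; when
#'   `NULL` all reported concentrations are used as-is.
#' @return List of class `excretion_summary`: `per_interval` (with nmol and
#'   cumulative nmol), `per_rat` (total_nmol, dose_nmol, percent_of_dose),
#'   `cohort_mean_percent`.
#' @export
summarize_excretion <- function(urine, doses, panel,
                                bql = c("zero", "half_lloq"), lloq = NULL) {
  bql <- match.arg(bql)
  missing_rats <- setdiff(unique(urine$rat_id), doses$rat_id)
  if (length(missing_rats) > 0) {
    stop("rat(s) present in urine but absent from doses: ",
         paste(missing_rats, collapse = ", "), call. = FALSE)
  }
  a <- panel$analytes[!panel$analytes$is_internal_standard, ]
  mm <- stats::setNames(a$molar_mass, a$name)
  stopifnot(all(urine$analyte %in% names(mm)))
  conc <- urine$conc_ng_per_ml
  if (!is.null(lloq)) {
    lim <- lloq[urine$analyte]
    low <- !is.na(lim) & conc < lim
    conc[low] <- if (bql == "zero") 0 else lim[low] / 2
  }
  per_interval <- tibble::tibble(
    rat_id = urine$rat_id, analyte = urine$analyte,
    t_start_h = urine$t_start_h, t_end_h = urine$t_end_h,
    volume_ml = urine$volume_ml, conc_ng_per_ml = conc,
    amount_nmol = interval_amount(conc, urine$volume_ml, mm[urine$analyte]))
  per_interval <- cumulative_profile(per_interval)
  totals <- dplyr::summarise(
    dplyr::group_by(per_interval, .data$rat_id),
    total_nmol = sum(.data$amount_nmol), .groups = "drop")
  per_rat <- dplyr::left_join(totals, doses, by = "rat_id")
  per_rat$dose_nmol <- dose_to_nmol(per_rat$body_weight_kg,
                                    per_rat$dose_mg_per_kg,
                                    panel$design$dose_compound_molar_mass)
  rec <- percent_recovery(per_rat$total_nmol, per_rat$dose_nmol)
  per_rat$percent_of_dose <- rec$per_rat
  structure(list(per_interval = per_interval, per_rat = per_rat,
                 cohort_mean_percent = rec$cohort_mean),
            class = "excretion_summary")
}

#' @export
print.excretion_summary <- function(x, ...) {
  cat("urinary excretion summary\n")
  df <- x$per_rat
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %s: %s nmol = %s%% of dose\n", df$rat_id[i],
                signif(df$total_nmol[i], 4),
                signif(df$percent_of_dose[i], 3)))
  }
  cat(sprintf("  cohort mean: %s%% of dose\n",
              signif(x$cohort_mean_percent, 4)))
  invisible(x)
}
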