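# Readers and writers for the pipeline's tabular artifacts. All CSVs carry
# a header row, UTF-8, period decimal separator and no thousands
# separators. Units are fixed throughout: concentrations ng/mL, volumes mL,
# masses g/mol, amounts nmol, times hours.

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

.read_csv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE, ...))
}

#' Write / read the analyte registry CSV
#'
#' One row per panel member: name, formula, q1, q3, dp, ce, rt_min,
#' base_level_ng_per_ml, shared_transition_group, is_internal_standard,
#' correction_factor. Molar masses are recomputed from the formulas on
#' read, so the round trip is lossless.
#'
#' @param panel An `mrm_panel`.
#' @param path File path.
#' @return `write_analytes`: the path, invisibly. `read_analytes`: an
#'   `mrm_panel` (with the default level design).
#' @export
write_analytes <- function(panel, path) {
  cols <- c("name", "formula", "q1", "q3", "dp", "ce", "rt_min",
            "base_level_ng_per_ml", "shared_transition_group",
            "is_internal_standard", "correction_factor")
  .write_csv(panel$analytes[, cols], path)
}

#' @rdname write_analytes
#' @param design A [panel_design()] to attach on read.
#' @export
read_analytes <- function(path, design = panel_design()) {
  df <- .read_csv(path)
  df$shared_transition_group[df$shared_transition_group == ""] <- NA
  df$is_internal_standard <- as.logical(df$is_internal_standard)
  mrm_panel(df, design)
}

#' Write / read an injection table CSV
#'
#' Columns: sample_id, role, batch, lot, injection_index, analyte, area,
#' is_area, nominal_ng_per_ml, level_label, dilution_factor, condition.
#'
#' @param injections Injection tibble.
#' @param path File path.
#' @export
write_injections <- function(injections, path) .write_csv(injections, path)

#' @rdname write_injections
#' @export
read_injections <- function(path) {
  df <- .read_csv(path)
  for (col in c("level_label", "condition")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA
  }
  df
}

#' Write / read urine and dose tables
#'
#' `urine.csv`: rat_id, t_start_h, t_end_h, volume_ml, analyte,
#' conc_ng_per_ml. `doses.csv`: rat_id, body_weight_kg, dose_mg_per_kg.
#'
#' @param urine,doses Tibbles in the formats above.
#' @param path File path.
#' @export
write_urine <- function(urine, path) .write_csv(urine, path)

#' @rdname write_urine
#' @export
read_urine <- function(path) .read_csv(path)

#' @rdname write_urine
#' @export
write_doses <- function(doses, path) .write_csv(doses, path)

#' @rdname write_urine
#' @export
read_doses <- function(path) .read_csv(path)

#' Write fitted calibration curves to CSV
#'
#' @param curves Output of [fit_calibration()].
#' @param path File path.
#' @export
write_curves <- function(curves, path) {
  .write_csv(curves[, c("analyte", "batch", "slope", "intercept", "r",
                        "r_unweighted", "lloq", "uloq", "accepted")], path)
}

# Convert a validation report into plain lists jsonlite can serialize.
.report_to_list <- function(report) {
  lapply(report, function(b) {
    if (is.list(b) && !is.data.frame(b)) {
      lapply(b, function(e) if (is.data.frame(e)) as.data.frame(e) else e)
    } else {
      b
    }
  })
}

#' Write a validation report as JSON (and optionally a flat CSV summary)
#'
#' @param report A `validation_report` from [run_validation()].
#' @param path JSON output path.
#' @param summary_path Optional CSV path for a flat block/pass summary.
#' @export
write_validation_report <- function(report, path, summary_path = NULL) {
  jsonlite::write_json(.report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  if (!is.null(summary_path)) {
    blocks <- setdiff(names(report), "overall_pass")
    .write_csv(tibble::tibble(
      block = blocks,
      passed = vapply(blocks, function(b) isTRUE(report[[b]]$passed),
                      logical(1))), summary_path)
  }
  invisible(path)
}

#' Write an excretion summary (CSV + cohort JSON)
#'
#' Numbers in the CSV keep full precision; the cohort JSON reports per-rat
#' totals and percentages rounded to 4 significant figures, the reporting
#' convention used throughout.
#'
#' @param summary An `excretion_summary`.
#' @param csv_path Per-interval CSV output path.
#' @param json_path Optional cohort JSON output path.
#' @export
write_excretion_summary <- function(summary, csv_path, json_path = NULL) {
  .write_csv(summary$per_interval, csv_path)
  if (!is.null(json_path)) {
    cohort <- list(
      per_rat = data.frame(
        rat_id = summary$per_rat$rat_id,
        total_nmol = signif(summary$per_rat$total_nmol, 4),
        dose_nmol = signif(summary$per_rat$dose_nmol, 4),
        percent_of_dose = signif(summary$per_rat$percent_of_dose, 4)),
      cohort_mean_percent = signif(summary$cohort_mean_percent, 4))
    jsonlite::write_json(cohort, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(csv_path)
}

#' Read a run configuration (JSON or YAML)
#'
#' The document may carry `seed`, an `instrument` block and an `excretion`
#' block whose fields override the corresponding model defaults.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
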