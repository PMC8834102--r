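# Bioanalytical validation battery: selectivity, carry-over,
# precision/accuracy, matrix effect (IS-normalized matrix factor),
# dilution integrity, and stability, each with its acceptance thresholds.

.rsd <- function(x) 100 * stats::sd(x) / mean(x)

# Single-pass QC statistics against a nominal value. Thresholds: 20% at
# LLOQ, 15% at the other levels, applied to RSD and |RE| alike.
.qc_eval <- function(measured, nominal, level_label, scope,
                     analyte = NA_character_, batch = NA_integer_,
                     extra_label = NA_character_) {
  n <- length(measured)
  if (n < 2) stop("need at least 2 replicates for sd", call. = FALSE)
  m <- mean(measured)
  s <- stats::sd(measured)
  rsd <- 100 * s / m
  re <- 100 * (m - nominal) / nominal
  lim <- if (identical(level_label, "LLOQ")) 20 else 15
  tibble::tibble(analyte = analyte, level_label = level_label,
                 nominal = nominal, scope = scope, batch = batch,
                 condition = extra_label, n = n, mean = m, sd = s,
                 rsd_pct = rsd, re_pct = re, limit_pct = lim,
                 passed = rsd <= lim & abs(re) <= lim)
}

# Join each injection row to its own batch's calibration curve and
# back-calculate the measured concentration from the area ratio.
.back_calc_rows <- function(tbl, curves, match_batch = TRUE) {
  tbl$measured <- NA_real_
  for (i in seq_len(nrow(tbl))) {
    sel <- curves$analyte == tbl$analyte[i]
    if (match_batch) sel <- sel & curves$batch == tbl$batch[i]
    if (!any(sel)) {
      stop("no calibration curve for analyte '", tbl$analyte[i],
           if (match_batch) sprintf("' in batch %s", tbl$batch[i]) else "'",
           call. = FALSE)
    }
    curve <- curves$curve[[which(sel)[1]]]
    tbl$measured[i] <- back_calculate(curve, tbl$area[i] / tbl$is_area[i])
  }
  tbl
}

#' Selectivity: blank-interference check
#'
#' Numeric surrogate for the visual chromatogram comparison: each analyte
#' channel's mean blank response must stay below 20% of the mean LLOQ-level
#' response, and the IS channel's blank response below 5% of the working IS
#' response. (The percentages mirror the carry-over criterion; the
#' guideline itself states no number for selectivity.)
#'
#' @param injections Injection table containing roles `"blank"` and either
#'   `"lloq_ref"` or LLOQ-level standards/QCs to reference against.
#' @return List: `analytes` tibble (analyte, blank_response, lloq_response,
#'   ratio, passed), `is` (ratio + passed), `passed` overall.
#' @export
check_selectivity <- function(injections) {
  blanks <- dplyr::filter(injections, .data$role == "blank")
  if (nrow(blanks) == 0) stop("no blank injections", call. = FALSE)
  ref <- dplyr::filter(injections,
                       .data$role == "lloq_ref" |
                         (.data$role == "standard" & .data$level_label == "S1") |
                         (.data$role == "qc" & .data$level_label == "LLOQ"))
  if (nrow(ref) == 0) stop("no LLOQ-level reference injections", call. = FALSE)
  per <- dplyr::summarise(
    dplyr::group_by(blanks, .data$analyte),
    blank_response = mean(.data$area), .groups = "drop")
  lloq <- dplyr::summarise(
    dplyr::group_by(ref, .data$analyte),
    lloq_response = mean(.data$area), .groups = "drop")
  per <- dplyr::left_join(per, lloq, by = "analyte")
  per$ratio <- per$blank_response / per$lloq_response
  per$passed <- per$ratio < 0.20
  is_blank <- mean(ifelse(is.na(blanks$is_area), 0, blanks$is_area))
  is_work <- mean(ref$is_area)
  is_ratio <- is_blank / is_work
  list(analytes = per,
       is = list(ratio = is_ratio, passed = is_ratio < 0.05),
       passed = all(per$passed) && is_ratio < 0.05)
}

#' Carry-over assessment
#'
#' A blank injected immediately after the ULOQ sample must show a residual
#' analyte response no greater than 20% of the LLOQ response, and the IS
#' residual no greater than 5% of the working IS response.
#'
#' @param injections Injection table with roles `"uloq"`,
#'   `"carryover_blank"` and `"lloq_ref"`.
#' @return List of class `carryover_result`: `analytes` tibble (analyte,
#'   residual_ratio, passed), `is` (ratio + passed), `passed` overall.
#' @export
assess_carryover <- function(injections) {
  blank <- dplyr::filter(injections, .data$role == "carryover_blank")
  ref <- dplyr::filter(injections, .data$role == "lloq_ref")
  if (nrow(ref) == 0) stop("missing LLOQ reference injections", call. = FALSE)
  if (nrow(blank) == 0) stop("missing post-ULOQ blank", call. = FALSE)
  per <- dplyr::left_join(
    dplyr::summarise(dplyr::group_by(blank, .data$analyte),
                     blank_response = mean(.data$area), .groups = "drop"),
    dplyr::summarise(dplyr::group_by(ref, .data$analyte),
                     lloq_response = mean(.data$area), .groups = "drop"),
    by = "analyte")
  per$residual_ratio <- per$blank_response / per$lloq_response
  per$passed <- per$residual_ratio <= 0.20
  is_ratio <- mean(ifelse(is.na(blank$is_area), 0, blank$is_area)) /
    mean(ref$is_area)
  structure(list(analytes = per,
                 is = list(residual_ratio = is_ratio,
                           passed = is_ratio <= 0.05),
                 passed = all(per$passed) && is_ratio <= 0.05),
            class = "carryover_result")
}

#' Precision and accuracy over the QC battery
#'
#' Back-calculates each QC replicate against its own batch's calibration
#' curve, then reports intra-batch statistics per batch and pooled
#' inter-batch statistics (all replicates of all batches together) per
#' analyte and level. Precision is RSD% (sample sd, n - 1); accuracy is
#' RE% of the mean against nominal. Thresholds: 20% at the LLOQ, 15% at
#' LQC/MQC/HQC, on RSD and |RE| alike.
#'
#' @param injections Injection table containing role `"qc"` rows with
#'   `batch`, `level_label` and `nominal_ng_per_ml`.
#' @param curves Output of [fit_calibration()] covering every batch.
#' @return Tibble of QC evaluations (scope `"intra"` rows per batch plus
#'   `"inter"` pooled rows).
#' @export
precision_accuracy <- function(injections, curves) {
  qc <- dplyr::filter(injections, .data$role == "qc")
  if (nrow(qc) == 0) stop("no QC injections", call. = FALSE)
  qc <- .back_calc_rows(qc, curves)
  intra <- dplyr::bind_rows(lapply(
    dplyr::group_split(dplyr::group_by(qc, .data$analyte, .data$level_label,
                                       .data$batch)),
    function(g) .qc_eval(g$measured, g$nominal_ng_per_ml[1],
                         g$level_label[1], "intra", g$analyte[1],
                         g$batch[1])))
  inter <- dplyr::bind_rows(lapply(
    dplyr::group_split(dplyr::group_by(qc, .data$analyte, .data$level_label)),
    function(g) .qc_eval(g$measured, g$nominal_ng_per_ml[1],
                         g$level_label[1], "inter", g$analyte[1])))
  dplyr::bind_rows(intra, inter)
}

#' Matrix effect via the IS-normalized matrix factor
#'
#' Per urine lot, the matrix factor is the ratio of the mean post-extraction
#' spiked area to the mean neat-solution area (means over the replicates,
#' taken before ratioing; set `replicate_level = TRUE` to ratio replicate
#' pairs instead). IS-MF = MF_analyte / MF_IS per lot; the acceptance
#' statistic is the RSD of the per-lot IS-MF values, required to be within
#' 15%.
#'
#' @param injections Injection table with roles `"matrix_spiked"` and
#'   `"matrix_neat"`, matched by `level_label`; spiked rows keyed by lot.
#' @param replicate_level Ratio replicate-by-replicate instead of from lot
#'   means.
#' @return Tibble per analyte x level: mean_ismf, rsd_pct, n_lots, passed,
#'   with a list-column `per_lot` (lot, mf_analyte, mf_is, ismf).
#' @export
matrix_effect <- function(injections, replicate_level = FALSE) {
  sp <- dplyr::filter(injections, .data$role == "matrix_spiked")
  nt <- dplyr::filter(injections, .data$role == "matrix_neat")
  if (nrow(sp) == 0 || nrow(nt) == 0) {
    stop("need both matrix_spiked and matrix_neat injections", call. = FALSE)
  }
  if (any(nt$area == 0)) stop("zero neat-solution area", call. = FALSE)
  neat <- dplyr::summarise(
    dplyr::group_by(nt, .data$analyte, .data$level_label),
    neat_area = mean(.data$area), neat_is = mean(.data$is_area),
    .groups = "drop")
  agg <- if (replicate_level) {
    sp2 <- dplyr::left_join(sp, neat, by = c("analyte", "level_label"))
    dplyr::summarise(
      dplyr::group_by(sp2, .data$analyte, .data$level_label, .data$lot),
      ismf = mean((.data$area / .data$neat_area) /
                    (.data$is_area / .data$neat_is)),
      mf_analyte = mean(.data$area / .data$neat_area),
      mf_is = mean(.data$is_area / .data$neat_is),
      .groups = "drop")
  } else {
    lotmeans <- dplyr::summarise(
      dplyr::group_by(sp, .data$analyte, .data$level_label, .data$lot),
      spiked_area = mean(.data$area), spiked_is = mean(.data$is_area),
      .groups = "drop")
    lotmeans <- dplyr::left_join(lotmeans, neat,
                                 by = c("analyte", "level_label"))
    dplyr::mutate(lotmeans,
                  mf_analyte = .data$spiked_area / .data$neat_area,
                  mf_is = .data$spiked_is / .data$neat_is,
                  ismf = .data$mf_analyte / .data$mf_is)
  }
  dplyr::bind_rows(lapply(
    dplyr::group_split(dplyr::group_by(agg, .data$analyte,
                                       .data$level_label)),
    function(g) {
      tibble::tibble(
        analyte = g$analyte[1], level_label = g$level_label[1],
        mean_ismf = mean(g$ismf), rsd_pct = .rsd(g$ismf),
        n_lots = nrow(g), passed = .rsd(g$ismf) <= 15,
        per_lot = list(g[, c("lot", "mf_analyte", "mf_is", "ismf")]))
    }))
}

#' Dilution integrity
#'
#' Samples prepared above the ULOQ and diluted to the HQC level are
#' back-calculated and multiplied by the dilution factor; accuracy (RE
#' against the pre-dilution nominal) must be within 15%, and precision
#' (RSD) is reported alongside.
#'
#' @param injections Injection table with role `"dilution"`;
#'   `dilution_factor` > 1 and `nominal_ng_per_ml` carrying the
#'   pre-dilution nominal.
#' @param curves Output of [fit_calibration()] (batch 1 curve used).
#' @return Tibble of QC evaluations per analyte x dilution factor.
#' @export
dilution_integrity <- function(injections, curves) {
  dil <- dplyr::filter(injections, .data$role == "dilution")
  if (nrow(dil) == 0) stop("no dilution samples", call. = FALSE)
  if (any(dil$dilution_factor <= 1)) {
    stop("dilution factor must exceed 1", call. = FALSE)
  }
  dil <- .back_calc_rows(dil, curves, match_batch = FALSE)
  dil$measured <- dil$measured * dil$dilution_factor
  dplyr::bind_rows(lapply(
    dplyr::group_split(dplyr::group_by(dil, .data$analyte,
                                       .data$dilution_factor)),
    function(g) {
      ev <- .qc_eval(g$measured, g$nominal_ng_per_ml[1], "HQC", "dilution",
                     g$analyte[1])
      ev$dilution_factor <- g$dilution_factor[1]
      ev
    }))
}

.known_conditions <- c("long_term_1_month", "long_term_3_months",
                       "freeze_thaw_1_cycle", "freeze_thaw_2_cycles",
                       "autosampler_24_h")

#' Stability evaluation
#'
#' QC samples stored under each condition are quantified against the fresh
#' calibration curve; per condition and level the RSD and RE must both be
#' within 15%.
#'
#' @param injections Injection table with role `"stability"`, `condition`
#'   labels and `nominal_ng_per_ml` (the fresh nominal).
#' @param curves Output of [fit_calibration()] from freshly prepared
#'   standards.
#' @param known_conditions Permitted condition labels.
#' @return Tibble of QC evaluations per analyte x condition x level.
#' @export
stability_evaluate <- function(injections, curves,
                               known_conditions = .known_conditions) {
  st <- dplyr::filter(injections, .data$role == "stability")
  if (nrow(st) == 0) stop("no stability samples", call. = FALSE)
  bad <- setdiff(unique(st$condition), known_conditions)
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  st <- .back_calc_rows(st, curves, match_batch = FALSE)
  dplyr::bind_rows(lapply(
    dplyr::group_split(dplyr::group_by(st, .data$analyte, .data$condition,
                                       .data$level_label)),
    function(g) .qc_eval(g$measured, g$nominal_ng_per_ml[1],
                         g$level_label[1], "stability", g$analyte[1],
                         extra_label = g$condition[1])))
}

#' Run the full validation battery
#'
#' Orchestrates calibration evaluation, selectivity, carry-over,
#' precision/accuracy, matrix effect, dilution integrity and stability on
#' one injection table (as produced by [simulate_validation_suite()] or
#' read from disk). Blocks whose roles are absent are skipped with a note
#' rather than an error, except calibration standards, which are required.
#'
#' @param injections Injection table covering the validation roles.
#' @param r_min Linearity threshold.
#' @return List of class `validation_report`: one block per test, each with
#'   its statistics and `passed` flag, plus `overall_pass`.
#' @export
run_validation <- function(injections, r_min = 0.99) {
  if (!any(injections$role == "standard")) {
    stop("missing calibration batch (role 'standard')", call. = FALSE)
  }
  curves <- fit_calibration(injections, r_min = r_min)
  blocks <- list()
  blocks$calibration <- list(
    curves = curves[, c("analyte", "batch", "slope", "intercept", "r",
                        "r_unweighted", "lloq", "uloq", "accepted")],
    passed = all(curves$accepted))
  has <- function(role) any(injections$role == role)
  if (has("blank") && (has("lloq_ref") || has("standard"))) {
    sel <- check_selectivity(injections)
    blocks$selectivity <- list(analytes = sel$analytes, is = sel$is,
                               passed = sel$passed)
  }
  if (has("carryover_blank")) {
    co <- assess_carryover(injections)
    blocks$carryover <- list(analytes = co$analytes, is = co$is,
                             passed = co$passed)
  }
  if (has("qc")) {
    pa <- precision_accuracy(injections, curves)
    blocks$precision_accuracy <- list(evaluations = pa,
                                      passed = all(pa$passed))
  }
  if (has("matrix_spiked")) {
    me <- matrix_effect(injections)
    blocks$matrix_effect <- list(
      evaluations = me[, setdiff(names(me), "per_lot")],
      passed = all(me$passed))
  }
  if (has("dilution")) {
    di <- dilution_integrity(injections, curves)
    blocks$dilution_integrity <- list(evaluations = di,
                                      passed = all(di$passed))
  }
  if (has("stability")) {
    stb <- stability_evaluate(injections, curves)
    blocks$stability <- list(evaluations = stb, passed = all(stb$passed))
  }
  overall <- all(vapply(blocks, function(b) isTRUE(b$passed), logical(1)))
  structure(c(blocks, list(overall_pass = overall)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  for (nm in setdiff(names(x), "overall_pass")) {
    cat(sprintf("%-20s %s\n", nm, if (isTRUE(x[[nm]]$passed)) "PASS" else "FAIL"))
  }
  cat(sprintf("overall: %s\n", if (x$overall_pass) "PASS" else "FAIL"))
  invisible(x)
}
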