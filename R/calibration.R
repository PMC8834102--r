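# Weighted (1/x) least-squares calibration on the analyte/IS area ratio,
# back-calculation, and the batch acceptance rules: per-level deviation
# within +/-20% at the LLOQ and +/-15% elsewhere, correlation coefficient
# r >= 0.99.

#' Fit a weighted least-squares calibration line
#'
#' Fits y = a + b x minimizing the weighted sum of squares
#' \eqn{\sum w_i (y_i - a - b x_i)^2} with the bioanalytical default
#' w = 1/x. The reported correlation coefficient is the weighted r computed
#' with the same weights (the unweighted Pearson r is carried alongside for
#' transparency). LLOQ and ULOQ are the smallest and largest nominal
#' concentrations in the fit.
#'
#' @param nominal_x Nominal concentrations (ng/mL); must be positive under
#'   1/x weighting.
#' @param response_y Analyte/IS peak area ratios.
#' @param weights Weights; default `1 / nominal_x`.
#' @return An object of class `calibration_curve`: slope, intercept, r
#'   (weighted), r_unweighted, lloq, uloq, n.
#' @export
#' @examples
#' fit_weighted_line(c(1, 10, 100), c(3, 21, 201))  # exact y = 2x + 1
fit_weighted_line <- function(nominal_x, response_y,
                              weights = 1 / nominal_x) {
  stopifnot(length(nominal_x) == length(response_y),
            length(nominal_x) >= 2)
  if (any(nominal_x <= 0)) {
    stop("nonpositive nominal concentration is incompatible with 1/x weighting",
         call. = FALSE)
  }
  if (length(unique(nominal_x)) < 2) {
    stop("degenerate design: all nominal concentrations identical",
         call. = FALSE)
  }
  stopifnot(all(weights > 0))
  fit <- stats::lm(response_y ~ nominal_x, weights = weights)
  cw <- stats::cov.wt(cbind(nominal_x, response_y), wt = weights,
                      cor = TRUE)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = cw$cor[1, 2],
         r_unweighted = stats::cor(nominal_x, response_y),
         lloq = min(nominal_x), uloq = max(nominal_x),
         n = length(nominal_x)),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve: y = %.6g + %.6g x (r = %.5f, n = %d)\n",
              x$intercept, x$slope, x$r, x$n))
  cat(sprintf("  range %.4g - %.4g ng/mL\n", x$lloq, x$uloq))
  invisible(x)
}

#' Back-calculate concentration from an area ratio
#'
#' Inverts the calibration relation: (y - intercept) / slope. Negative
#' results are reported as-is so deviation audits stay faithful; use
#' [range_flag()] for BQL / above-range annotation.
#'
#' @param curve A `calibration_curve`.
#' @param response_y Area ratio(s).
#' @return Measured concentration(s), ng/mL.
#' @export
back_calculate <- function(curve, response_y) {
  if (curve$slope == 0) stop("zero slope", call. = FALSE)
  (response_y - curve$intercept) / curve$slope
}

#' Flag back-calculated concentrations against the validated range
#'
#' @param curve A `calibration_curve`.
#' @param conc Back-calculated concentrations.
#' @return Character vector: `"below_zero"`, `"BQL"` (below LLOQ),
#'   `"in_range"`, or `"above_range"` (dilution required).
#' @export
range_flag <- function(curve, conc) {
  dplyr::case_when(conc < 0 ~ "below_zero",
                   conc < curve$lloq ~ "BQL",
                   conc > curve$uloq ~ "above_range",
                   TRUE ~ "in_range")
}

#' Percent deviation of a measured concentration from nominal
#'
#' Deviation = 100 x (measured - nominal) / nominal.
#'
#' @param measured,nominal Concentrations (ng/mL); nominal must be positive.
#' @return Signed percentage.
#' @export
deviation <- function(measured, nominal) {
  if (any(nominal <= 0)) stop("nominal must be positive", call. = FALSE)
  100 * (measured - nominal) / nominal
}

#' Evaluate a calibration batch against the acceptance rules
#'
#' Back-calculates every standard with the fitted curve and applies the
#' per-level deviation limits (within 20% at the LLOQ, 15% at all other
#' levels) and the linearity requirement r >= `r_min`. The batch is
#' accepted iff all levels pass and linearity passes. An optional
#' drop-one-level relaxation (off by default) re-fits without the single
#' worst-failing non-LLOQ level.
#'
#' @param curve A `calibration_curve` fitted on these standards.
#' @param standards Tibble with columns `nominal` and `response` (one row
#'   per standard replicate).
#' @param r_min Linearity threshold on the weighted r.
#' @param allow_drop_one Permit rejecting one failing interior level.
#' @return List of class `calibration_evaluation`: `levels` tibble
#'   (nominal, measured, deviation_pct, limit_pct, pass), `r`,
#'   `linearity_pass`, `accepted`, and `dropped_level` (NA unless used).
#' @export
evaluate_calibration_batch <- function(curve, standards, r_min = 0.99,
                                       allow_drop_one = FALSE) {
  stopifnot(all(c("nominal", "response") %in% names(standards)))
  lloq <- min(standards$nominal)
  measured <- back_calculate(curve, standards$response)
  dev <- deviation(measured, standards$nominal)
  limit <- ifelse(standards$nominal == lloq, 20, 15)
  levels <- tibble::tibble(
    nominal = standards$nominal, measured = measured,
    deviation_pct = dev, limit_pct = limit, pass = abs(dev) <= limit)
  linearity_pass <- curve$r >= r_min
  accepted <- all(levels$pass) && linearity_pass
  dropped <- NA_real_
  if (!accepted && allow_drop_one) {
    failing <- levels$nominal[!levels$pass & levels$nominal != lloq]
    if (length(failing) == 1L) {
      keep <- standards$nominal != failing
      curve2 <- fit_weighted_line(standards$nominal[keep],
                                  standards$response[keep])
      ev2 <- evaluate_calibration_batch(curve2, standards[keep, ],
                                        r_min = r_min)
      if (ev2$accepted) {
        ev2$dropped_level <- failing
        return(ev2)
      }
    }
  }
  structure(list(levels = levels, r = curve$r,
                 linearity_pass = linearity_pass, accepted = accepted,
                 dropped_level = dropped),
            class = "calibration_evaluation")
}

#' Fit calibration curves for every analyte and batch in an injection table
#'
#' Filters rows with role `"standard"`, forms the area ratio y = area /
#' is_area, and fits the weighted (1/x) line per analyte within each batch.
#'
#' @param injections Injection tibble (see [simulate_calibration_batch()]
#'   or [read_injections()]).
#' @param r_min Linearity threshold passed to the per-batch evaluation.
#' @return Tibble with one row per analyte x batch: slope, intercept, r,
#'   r_unweighted, lloq, uloq, accepted, plus list-columns `curve` and
#'   `evaluation`.
#' @export
fit_calibration <- function(injections, r_min = 0.99) {
  std <- dplyr::filter(injections, .data$role == "standard")
  if (nrow(std) == 0) stop("no calibration standards in table", call. = FALSE)
  std <- dplyr::mutate(std, response = .data$area / .data$is_area)
  groups <- dplyr::group_split(dplyr::group_by(std, .data$analyte, .data$batch))
  dplyr::bind_rows(lapply(groups, function(g) {
    curve <- fit_weighted_line(g$nominal_ng_per_ml, g$response)
    ev <- evaluate_calibration_batch(
      curve, tibble::tibble(nominal = g$nominal_ng_per_ml,
                            response = g$response),
      r_min = r_min)
    tibble::tibble(analyte = g$analyte[1], batch = g$batch[1],
                   slope = curve$slope, intercept = curve$intercept,
                   r = curve$r, r_unweighted = curve$r_unweighted,
                   lloq = curve$lloq, uloq = curve$uloq,
                   accepted = ev$accepted,
                   curve = list(curve), evaluation = list(ev))
  }))
}
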