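# Panel registry: the ten flavonoid metabolites of naringin quantified in
# rat urine plus the internal standard (isoquercitrin), with their MRM
# transitions, tuning voltages, retention times and calibration design.

# Neutral-loss masses used to sanity-check conjugate transitions (Da).
.glucuronide_loss <- 176.03209
.sulfate_loss <- 79.95682
.mass_tol_da <- 0.5

#' Concentration-level design shared by the whole panel
#'
#' Every analyte's calibration ladder and QC triplet are its base (LLOQ)
#' concentration times a common multiplier set: standards at 1, 2, 5, 15,
#' 50, 150, 400 and 500 times the LLOQ; QCs at 3 (LQC), 30 (MQC) and 375
#' (HQC) times the LLOQ, so the HQC always sits at 75% of the top standard.
#' Spiked samples carry 5 uL of working solution in 95 uL blank urine.
#'
#' @param level_multipliers Strictly increasing multipliers for the
#'   calibration standards; the first must be 1 (the LLOQ itself).
#' @param qc_multipliers Strictly increasing multipliers for (LQC, MQC, HQC).
#' @param spike_fraction Volume fraction of working solution in a spiked
#'   sample, in (0, 1).
#' @param dose_compound_formula Molecular formula of the dosed compound
#'   (naringin) used for molar dose conversion.
#' @return A list of class `panel_design`.
#' @export
panel_design <- function(level_multipliers = c(1, 2, 5, 15, 50, 150, 400, 500),
                         qc_multipliers = c(3, 30, 375),
                         spike_fraction = 5 / 100,
                         dose_compound_formula = "C27H32O14") {
  stopifnot(all(level_multipliers > 0), all(diff(level_multipliers) > 0),
            level_multipliers[1] == 1,
            all(qc_multipliers > 0), all(diff(qc_multipliers) > 0),
            qc_multipliers[1] > 1,
            qc_multipliers[length(qc_multipliers)] <
              level_multipliers[length(level_multipliers)],
            spike_fraction > 0, spike_fraction < 1)
  structure(
    list(level_multipliers = level_multipliers,
         qc_multipliers = qc_multipliers,
         spike_fraction = spike_fraction,
         dose_compound_formula = dose_compound_formula,
         dose_compound_molar_mass = formula_mass(dose_compound_formula)),
    class = "panel_design")
}

#' Build the default analyte panel
#'
#' Returns the eleven-member panel: ten metabolites (naringenin, its two
#' glucuronides, apigenin, eriodictyol, homoeriodictyol, hesperetin, its two
#' glucuronides and its 7-O-sulfate) plus isoquercitrin as internal
#' standard, with optimized Q1/Q3 transitions, declustering potential (DP),
#' collision energy (CE), retention times, and per-analyte LLOQ design
#' concentrations. Isomeric glucuronide pairs share one transition and are
#' separated chromatographically (distinct retention times).
#'
#' @param design A [panel_design()]; the default is the standard ladder.
#' @return A list of class `mrm_panel` with elements `analytes` (tibble, one
#'   row per panel member) and `design`.
#' @export
#' @examples
#' panel <- build_default_panel()
#' panel$analytes[, c("name", "q1", "q3", "base_level_ng_per_ml")]
build_default_panel <- function(design = panel_design()) {
  analytes <- tibble::tribble(
    ~name,                          ~formula,    ~q1,   ~q3,   ~dp,  ~ce,   ~rt_min, ~base_level_ng_per_ml, ~shared_transition_group,
    "naringenin",                   "C15H12O5",  270.9, 150.9, -24,  -44,   8.82,    2,    NA,
    "naringenin-7-O-glucuronide",   "C21H20O11", 447.0, 271.1, -33,  -72,   7.09,    20,   "naringenin-glucuronide",
    "naringenin-4'-O-glucuronide",  "C21H20O11", 447.0, 271.1, -33,  -72,   7.23,    20,   "naringenin-glucuronide",
    "apigenin",                     "C15H10O5",  269.0, 151.0, -33,  -48,   9.25,    1,    NA,
    "eriodictyol",                  "C15H12O6",  286.9, 135.0, -38,  -56,   8.19,    0.5,  NA,
    "homoeriodictyol",              "C16H14O6",  301.0, 150.9, -26,  -50,   8.89,    1,    NA,
    "hesperetin",                   "C16H14O6",  301.0, 163.9, -32,  -134,  9.03,    0.5,  NA,
    "hesperetin-7-O-glucuronide",   "C22H22O12", 477.1, 301.1, -31,  -59,   7.91,    4,    "hesperetin-glucuronide",
    "hesperetin-3'-O-glucuronide",  "C22H22O12", 477.1, 301.1, -31,  -59,   8.31,    4,    "hesperetin-glucuronide",
    "hesperetin-7-O-sulfate",       "C16H14O9S", 381.0, 301.1, -28,  -53,   8.20,    1,    NA,
    "isoquercitrin",                "C21H20O12", 463.1, 299.9, -36,  -32,   7.15,    NA,   NA
  )
  analytes$is_internal_standard <- analytes$name == "isoquercitrin"
  analytes$correction_factor <- 1
  analytes$molar_mass <- formula_mass(analytes$formula, "average")
  analytes$monoisotopic_mass <- formula_mass(analytes$formula, "monoisotopic")
  panel <- structure(list(analytes = analytes, design = design),
                     class = "mrm_panel")
  validate_panel(panel)
  panel
}

#' Assemble and validate a panel from an analyte table
#'
#' @param analytes Tibble with at least name, formula, q1, q3, dp, ce,
#'   rt_min, base_level_ng_per_ml, is_internal_standard; missing
#'   correction_factor defaults to 1 and masses are recomputed from formulas.
#' @param design A [panel_design()].
#' @return An `mrm_panel`.
#' @export
mrm_panel <- function(analytes, design = panel_design()) {
  analytes <- tibble::as_tibble(analytes)
  if (is.null(analytes$correction_factor)) analytes$correction_factor <- 1
  if (is.null(analytes$shared_transition_group)) {
    analytes$shared_transition_group <- NA_character_
  }
  analytes$molar_mass <- formula_mass(analytes$formula, "average")
  analytes$monoisotopic_mass <- formula_mass(analytes$formula, "monoisotopic")
  panel <- structure(list(analytes = analytes, design = design),
                     class = "mrm_panel")
  validate_panel(panel)
  panel
}

#' Validate panel invariants
#'
#' Checks uniqueness of names, transition ordering (q1 > q3 > 0), that the
#' stated molar mass agrees with the formula-derived mass to 0.5 g/mol,
#' that every non-IS analyte has a positive base level while the IS has
#' none, and that members sharing a transition group share q1/q3/dp/ce but
#' differ in retention time.
#'
#' @param panel An `mrm_panel`.
#' @return The panel, invisibly; errors on violation.
#' @export
validate_panel <- function(panel) {
  a <- panel$analytes
  if (anyDuplicated(a$name)) stop("analyte names must be unique")
  if (!all(a$q1 > a$q3 & a$q3 > 0)) stop("every transition must satisfy q1 > q3 > 0")
  if (!all(abs(a$molar_mass - formula_mass(a$formula)) <= 0.5)) {
    stop("molar_mass inconsistent with formula")
  }
  is_is <- a$is_internal_standard
  if (sum(is_is) != 1L) stop("exactly one internal standard required")
  if (!all(a$base_level_ng_per_ml[!is_is] > 0)) {
    stop("every non-IS analyte needs a positive base level")
  }
  if (!is.na(a$base_level_ng_per_ml[is_is])) {
    stop("the internal standard has no calibration design")
  }
  grp <- a$shared_transition_group
  for (g in unique(grp[!is.na(grp)])) {
    rows <- a[!is.na(grp) & grp == g, ]
    if (nrow(unique(rows[, c("q1", "q3", "dp", "ce")])) != 1L) {
      stop("group '", g, "' members must share q1/q3/dp/ce")
    }
    if (anyDuplicated(rows$rt_min)) {
      stop("group '", g, "' members must have distinct retention times")
    }
  }
  invisible(panel)
}

#' Extract one analyte's record from a panel
#'
#' @param panel An `mrm_panel`.
#' @param name Analyte name.
#' @return One-row tibble.
#' @export
panel_analyte <- function(panel, name) {
  row <- panel$analytes[panel$analytes$name == name, ]
  if (nrow(row) != 1L) stop("unknown analyte: ", name)
  row
}

#' Calibration standard concentrations for one analyte
#'
#' The eight-standard ladder: base level times each level multiplier
#' (e.g. 0.5, 1, 2.5, 7.5, 25, 75, 200, 250 ng/mL for eriodictyol).
#'
#' @param spec One-row analyte tibble (see [panel_analyte()]).
#' @param design A [panel_design()].
#' @return Strictly increasing numeric vector of concentrations (ng/mL).
#' @export
design_levels <- function(spec, design) {
  stopifnot(nrow(spec) == 1L)
  if (isTRUE(spec$is_internal_standard)) {
    stop("the internal standard has no calibration design", call. = FALSE)
  }
  spec$base_level_ng_per_ml * design$level_multipliers
}

#' QC concentrations (LQC, MQC, HQC) for one analyte
#'
#' @inheritParams design_levels
#' @return Named numeric vector `c(LQC = , MQC = , HQC = )` in ng/mL.
#' @export
design_qc <- function(spec, design) {
  stopifnot(nrow(spec) == 1L)
  if (isTRUE(spec$is_internal_standard)) {
    stop("the internal standard has no calibration design", call. = FALSE)
  }
  stats::setNames(spec$base_level_ng_per_ml * design$qc_multipliers,
                  c("LQC", "MQC", "HQC"))
}

#' Mass-consistency check of an MRM transition
#'
#' Compares the tuned Q1 mass against the formula-derived monoisotopic
#' \[M-H\]- m/z (quadrupole settings are tuned, hence a 0.5 Da tolerance),
#' and for glucuronide/sulfate conjugates checks the neutral loss Q1 - Q3
#' against the glucuronide residue (176.032 Da) or SO3 (79.957 Da).
#'
#' @param spec One-row analyte tibble.
#' @return One-row tibble: computed m/z, precursor delta and flag, neutral
#'   loss, expected loss (NA for non-conjugates), loss delta and flag, and
#'   the overall `pass`.
#' @export
#' @examples
#' panel <- build_default_panel()
#' check_transition(panel_analyte(panel, "naringenin"))
check_transition <- function(spec) {
  stopifnot(nrow(spec) == 1L)
  mz <- mz_deprotonated(spec$formula)
  d_prec <- abs(mz - spec$q1)
  loss <- spec$q1 - spec$q3
  expected_loss <- if (grepl("glucuronide", spec$name, ignore.case = TRUE)) {
    .glucuronide_loss
  } else if (grepl("sulfate", spec$name, ignore.case = TRUE)) {
    .sulfate_loss
  } else {
    NA_real_
  }
  loss_ok <- if (is.na(expected_loss)) TRUE else {
    abs(loss - expected_loss) <= .mass_tol_da
  }
  prec_ok <- d_prec <= .mass_tol_da
  tibble::tibble(
    name = spec$name, mz_calc = mz, q1 = spec$q1,
    precursor_delta = d_prec, precursor_ok = prec_ok,
    neutral_loss = loss, expected_loss = expected_loss,
    loss_delta = if (is.na(expected_loss)) NA_real_ else abs(loss - expected_loss),
    loss_ok = loss_ok,
    pass = prec_ok && loss_ok
  )
}

#' Run the transition check over a whole panel
#'
#' @param panel An `mrm_panel`.
#' @return Tibble with one verdict row per panel member.
#' @export
check_panel_transitions <- function(panel) {
  dplyr::bind_rows(lapply(seq_len(nrow(panel$analytes)), function(i) {
    check_transition(panel$analytes[i, ])
  }))
}
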