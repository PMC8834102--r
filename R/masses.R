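# Element mass tables. Average weights are the IUPAC 2021 conventional
# values; monoisotopic masses are those of the most abundant isotope.
.element_masses <- list(
  C  = c(average = 12.011,  monoisotopic = 12.0),
  H  = c(average = 1.008,   monoisotopic = 1.00782503),
  N  = c(average = 14.007,  monoisotopic = 14.00307401),
  O  = c(average = 15.999,  monoisotopic = 15.99491462),
  P  = c(average = 30.974,  monoisotopic = 30.97376200),
  S  = c(average = 32.06,   monoisotopic = 31.97207117),
  Na = c(average = 22.990,  monoisotopic = 22.98976928),
  K  = c(average = 39.098,  monoisotopic = 38.96370649),
  Cl = c(average = 35.45,   monoisotopic = 34.96885268)
)

# Mass of a proton, used for [M-H]- m/z.
.proton_mass <- 1.00727646

#' Parse a molecular formula into element counts
#'
#' Accepts plain Hill-notation formulas such as `"C15H12O5"`. Only element
#' symbols present in the built-in mass table are accepted; parenthesised
#' groups and isotopes are not supported (the panel never needs them).
#'
#' @param formula Character scalar, e.g. `"C21H20O11"`.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C15H12O5")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  bad <- setdiff(sym, names(.element_masses))
  if (length(bad) > 0) {
    stop("unknown element symbol(s) in formula '", formula, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- tapply(cnt, sym, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Molecular mass from a formula
#'
#' @param formula Character vector of molecular formulas.
#' @param kind `"average"` (g/mol, for ng-to-nmol conversion) or
#'   `"monoisotopic"` (Da, for m/z checks).
#' @return Numeric vector of masses.
#' @export
#' @examples
#' formula_mass("C15H12O5")                   # naringenin, ~272.26 g/mol
#' formula_mass("C15H12O5", "monoisotopic")   # ~272.068 Da
formula_mass <- function(formula, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    sum(vapply(names(counts),
               function(el) .element_masses[[el]][[kind]], numeric(1)) * counts)
  }, numeric(1), USE.NAMES = FALSE)
}

#' m/z of the deprotonated molecule [M-H]-
#'
#' @param formula Character vector of molecular formulas.
#' @return Monoisotopic m/z of the singly deprotonated anion.
#' @export
mz_deprotonated <- function(formula) {
  formula_mass(formula, "monoisotopic") - .proton_mass
}
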