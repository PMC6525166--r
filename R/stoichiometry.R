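#' Parse a molecular formula
#'
#' Understands simple Hill-notation formulas such as `"C7H8N4O2"` (no
#' brackets or charges — enough for small-molecule drugs).
#'
#' @param formula Character scalar.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C8H6N4O5")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(parts) == 0 || sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(ifelse(grepl("[0-9]+$", parts),
                         sub("^[A-Za-z]+", "", parts), "1"))
  counts <- tapply(n, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

# Standard atomic weights (IUPAC 2021, conventional values)
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, Na = 22.990, K = 39.098
)

#' Molar mass of a molecular formula
#'
#' @param formula Character scalar, e.g. `"C7H8N4O2"`.
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("H2O")
#' @export
molar_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown)) {
    stop("no atomic weight on file for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(counts * .atomic_weights[names(counts)])
}

#' Theoretical water mass fraction of a hydrate
#'
#' The weight loss a thermogravimetric run should show when a stoichiometric
#' hydrate releases all its lattice water:
#' `100 * n * M(H2O) / (M(anhydrate) + n * M(H2O))`.
#'
#' For the two model systems: theophylline (C7H8N4O2) monohydrate loses 9.1%
#' (9% to integer precision) and nitrofurantoin (C8H6N4O5) monohydrate 7.0%.
#'
#' @param formula Molecular formula of the anhydrous molecule.
#' @param n_water Moles of water per mole of drug (default 1, a monohydrate).
#' @return Water mass fraction in percent.
#' @examples
#' hydrate_water_fraction("C7H8N4O2")  # theophylline monohydrate
#' hydrate_water_fraction("C8H6N4O5")  # nitrofurantoin monohydrate
#' @export
hydrate_water_fraction <- function(formula, n_water = 1) {
  stopifnot(n_water > 0)
  m_w <- n_water * molar_mass("H2O")
  100 * m_w / (molar_mass(formula) + m_w)
}
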