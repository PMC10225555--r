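# Downstream validation calculators: flow-cytometry summaries, relative
# quantification of qPCR data, and concentration unit conversion.

#' Mean fluorescence intensity of a flow-cytometry sample
#'
#' @param events Numeric vector of event intensities (>= 1 event).
#' @return Arithmetic mean intensity.
#' @export
mfi <- function(events) {
  if (!is.numeric(events) || length(events) == 0 || anyNA(events)) {
    stop_hcs("hcs_input_error", "events must be a non-empty numeric vector without NA")
  }
  mean(events)
}

#' Select the top p percent of values (sorter-style gating)
#'
#' Returns the `ceiling(p/100 * n)` largest values; ties at the cut are all
#' included, so the selection can exceed that size when the cut value is
#' not unique.
#'
#' @param values Non-empty numeric vector.
#' @param p Percentage in (0, 100].
#' @return The selected values (order of appearance preserved).
#' @export
gate_top_percent <- function(values, p) {
  if (!is.numeric(values) || length(values) == 0 || anyNA(values)) {
    stop_hcs("hcs_input_error", "values must be a non-empty numeric vector without NA")
  }
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 100) {
    stop_hcs("hcs_domain_error", "p must be in (0, 100]")
  }
  k <- ceiling(p / 100 * length(values))
  cut <- sort(values, decreasing = TRUE)[k]
  values[values >= cut]
}

#' Relative quantification by the delta-delta-Ct method
#'
#' `ddct = (ct_target_treated - ct_hk_treated) - (ct_target_ref -
#' ct_hk_ref)`, `rq = 2^(-ddct)`: the fold change of the target gene in the
#' treated condition relative to the reference condition, normalised to a
#' housekeeping gene. The reference condition has `rq = 1` by construction.
#'
#' @param ct_target_treated,ct_hk_treated Target/housekeeping Ct in the
#'   treated condition.
#' @param ct_target_ref,ct_hk_ref Same in the reference condition.
#' @param condition Optional label carried into the result.
#' @return List of class `rq_result`: `condition`, `ddct`, `rq`.
#' @export
#' @examples
#' rq_ddct(16.755, 20, 22, 20)$rq # ~9.48-fold induction
rq_ddct <- function(ct_target_treated, ct_hk_treated, ct_target_ref, ct_hk_ref,
                    condition = "treated") {
  cts <- c(ct_target_treated, ct_hk_treated, ct_target_ref, ct_hk_ref)
  if (!is.numeric(cts) || length(cts) != 4 || any(!is.finite(cts))) {
    stop_hcs("hcs_input_error", "all four Ct values must be finite numbers")
  }
  ddct <- (ct_target_treated - ct_hk_treated) - (ct_target_ref - ct_hk_ref)
  structure(
    list(condition = condition, ddct = ddct, rq = 2^(-ddct)),
    class = "rq_result"
  )
}

#' @export
print.rq_result <- function(x, ...) {
  cat(sprintf("rq_result [%s]: ddCt = %.4g, RQ = %.4g\n", x$condition, x$ddct, x$rq))
  invisible(x)
}

# IUPAC standard atomic weights (2021, conventional/abridged values) for
# elements with a defined standard weight.
ATOMIC_MASSES <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Sc = 44.956, Ti = 47.867, V = 50.942, Cr = 51.996,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Ga = 69.723, Ge = 72.630, As = 74.922, Se = 78.971, Br = 79.904, Kr = 83.798,
  Rb = 85.468, Sr = 87.62, Y = 88.906, Zr = 91.224, Nb = 92.906, Mo = 95.95,
  Ru = 101.07, Rh = 102.91, Pd = 106.42, Ag = 107.87, Cd = 112.41,
  In = 114.82, Sn = 118.71, Sb = 121.76, Te = 127.60, I = 126.90, Xe = 131.29,
  Cs = 132.91, Ba = 137.33, La = 138.91, Ce = 140.12, Pr = 140.91,
  Nd = 144.24, Sm = 150.36, Eu = 151.96, Gd = 157.25, Tb = 158.93,
  Dy = 162.50, Ho = 164.93, Er = 167.26, Tm = 168.93, Yb = 173.05,
  Lu = 174.97, Hf = 178.49, Ta = 180.95, W = 183.84, Re = 186.21,
  Os = 190.23, Ir = 192.22, Pt = 195.08, Au = 196.97, Hg = 200.59,
  Tl = 204.38, Pb = 207.2, Bi = 208.98, Th = 232.04, Pa = 231.04, U = 238.03
)

#' Parse a Hill-notation molecular formula
#'
#' @param formula String like `"C15H22O"` or `"H2O"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || !nzchar(formula)) {
    stop_hcs("hcs_input_error", "formula must be a non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop_hcs("hcs_input_error", "cannot parse formula '%s'", formula)
  }
  elements <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
    sub("^[A-Za-z]+", "", parts), "1"
  ))
  unknown <- setdiff(elements, names(ATOMIC_MASSES))
  if (length(unknown)) {
    stop_hcs("hcs_input_error", "unknown element symbol(s): %s", paste(unknown, collapse = ", "))
  }
  counts <- tapply(counts, elements, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Molar mass of a molecular formula
#'
#' Sum of IUPAC standard atomic weights times element counts.
#'
#' @param formula Hill-notation formula string (or a named count vector
#'   from [parse_formula()]).
#' @return Molar mass in g/mol.
#' @export
#' @examples
#' molar_mass("C15H22O") # sesquiterpene phenol, ~218.33 g/mol
molar_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(ATOMIC_MASSES[names(counts)] * counts)
}

#' Describe a compound by formula and molar mass
#'
#' @param formula Hill-notation formula string.
#' @return Object of class `compound_spec`: `molecular_formula` (count
#'   vector), `molar_mass` (g/mol).
#' @export
compound_spec <- function(formula) {
  counts <- parse_formula(formula)
  structure(
    list(molecular_formula = counts, molar_mass = molar_mass(counts)),
    class = "compound_spec"
  )
}

#' Convert a micromolar concentration to micrograms per millilitre
#'
#' `ug/mL = uM * molar_mass / 1000`.
#'
#' @param concentration_uM Concentration in micromolar (>= 0, vectorised).
#' @param compound A [compound_spec()], a formula string, or a molar mass
#'   in g/mol.
#' @return Concentration in ug/mL.
#' @export
#' @examples
#' micromolar_to_ug_per_ml(75, "C15H22O") # ~16.375
micromolar_to_ug_per_ml <- function(concentration_uM, compound) {
  if (!is.numeric(concentration_uM) || any(!is.finite(concentration_uM)) ||
    any(concentration_uM < 0)) {
    stop_hcs("hcs_domain_error", "concentration_uM must be non-negative and finite")
  }
  mm <- if (inherits(compound, "compound_spec")) {
    compound$molar_mass
  } else if (is.character(compound)) {
    molar_mass(compound)
  } else if (is.numeric(compound) && length(compound) == 1 && compound > 0) {
    compound
  } else {
    stop_hcs("hcs_input_error", "compound must be a compound_spec, formula string or molar mass")
  }
  concentration_uM * mm / 1000
}
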