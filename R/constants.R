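# Physical constants and element data shared across the package.

# CODATA-consistent Hartree -> kJ/mol conversion used for CREST comment-line
# energies and distilled DFT tables.
HARTREE_KJMOL <- 2625.4996394799

KCAL_KJMOL <- 4.184

#' Convert energies to kJ/mol
#'
#' All internal energies in the package are kilojoules per mole; this helper
#' converts values read from external files.
#'
#' @param x Numeric vector of energies.
#' @param unit One of `"kjmol"`, `"hartree"`, `"kcalmol"`, `"ev"`.
#' @return Numeric vector in kJ/mol.
#' @export
#' @examples
#' to_kjmol(1, "hartree")
#' to_kjmol(3.0, "kcalmol")
to_kjmol <- function(x, unit = c("kjmol", "hartree", "kcalmol", "ev")) {
  unit <- match.arg(unit)
  switch(unit,
    kjmol   = x,
    hartree = x * HARTREE_KJMOL,
    kcalmol = x * KCAL_KJMOL,
    ev      = x * 96.4853321233
  )
}

# Bondi (1964) van der Waals radii in Angstrom, extended with the commonly
# used values for elements Bondi did not tabulate (metals from the Alvarez
# compilation rounded to the values steric-descriptor codes ship with).
.bondi_radii <- c(
  H = 1.20, He = 1.40,
  Li = 1.82, Be = 1.53, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Ne = 1.54,
  Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
  Ar = 1.88,
  K = 2.75, Ca = 2.31, Sc = 2.15, Ti = 2.11, V = 2.07, Cr = 2.06, Mn = 2.05,
  Fe = 2.04, Co = 2.00, Ni = 1.97, Cu = 1.96, Zn = 2.01, Ga = 1.87,
  Ge = 2.11, As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02,
  Rb = 3.03, Sr = 2.49, Y = 2.32, Zr = 2.23, Nb = 2.18, Mo = 2.17,
  Tc = 2.16, Ru = 2.13, Rh = 2.10, Pd = 2.10, Ag = 2.11, Cd = 2.18,
  In = 1.93, Sn = 2.17, Sb = 2.06, Te = 2.06, I = 1.98, Xe = 2.16,
  Cs = 3.43, Ba = 2.68, La = 2.43, W = 2.18, Re = 2.16, Os = 2.16,
  Ir = 2.13, Pt = 2.13, Au = 2.14, Hg = 2.23, Tl = 1.96, Pb = 2.02,
  Bi = 2.07
)

.transition_metals <- c(
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "La", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg"
)

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

#' Van der Waals radius lookup
#'
#' Bondi radii with standard extensions for the transition metals.
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(elements) {
  r <- .bondi_radii[elements]
  if (anyNA(r)) {
    stop("no van der Waals radius tabulated for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Locate the metal centre in an element list
#'
#' @param elements Character vector of element symbols.
#' @return Integer index of the single transition-metal atom.
#' @export
find_metal <- function(elements) {
  idx <- which(elements %in% .transition_metals)
  if (length(idx) == 0L) stop("no transition-metal atom found")
  if (length(idx) > 1L) {
    stop("multiple transition-metal atoms found (indices ",
         paste(idx, collapse = ", "), "); supply metal_index explicitly")
  }
  idx
}
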