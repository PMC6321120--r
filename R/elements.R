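#' Element radius and pair-potential tables
#'
#' Tabulated per-element constants used across the package: covalent radii
#' (Cordero 2008 consensus values) for bond perception, van der Waals radii
#' (Bondi 1964, with the common extensions) for packing and void analysis,
#' and generic Lennard-Jones well depths / diameters (UFF-style) for the
#' lattice-energy sums. Units: radii and sigma in angstrom, epsilon in
#' kcal/mol.
#'
#' @return A tibble with columns `element`, `r_cov`, `r_vdw`, `lj_epsilon`,
#'   `lj_sigma`.
#' @export
#' @examples
#' element_data()
element_data <- function() {
  tibble::tribble(
    ~element, ~r_cov, ~r_vdw, ~lj_epsilon, ~lj_sigma,
    "H",  0.31, 1.20, 0.044, 2.571,
    "He", 0.28, 1.40, 0.056, 2.104,
    "B",  0.84, 1.92, 0.180, 3.638,
    "C",  0.76, 1.70, 0.105, 3.431,
    "N",  0.71, 1.55, 0.069, 3.261,
    "O",  0.66, 1.52, 0.060, 3.118,
    "F",  0.57, 1.47, 0.050, 2.997,
    "Ne", 0.58, 1.54, 0.042, 2.889,
    "Na", 1.66, 2.27, 0.030, 2.658,
    "Mg", 1.41, 1.73, 0.111, 2.691,
    "Si", 1.11, 2.10, 0.402, 3.826,
    "P",  1.07, 1.80, 0.305, 3.695,
    "S",  1.05, 1.80, 0.274, 3.595,
    "Cl", 1.02, 1.75, 0.227, 3.516,
    "Ar", 1.06, 1.88, 0.185, 3.446,
    "K",  2.03, 2.75, 0.035, 3.396,
    "Ca", 1.76, 2.31, 0.238, 3.028,
    "Br", 1.20, 1.85, 0.251, 3.732,
    "I",  1.39, 1.98, 0.339, 4.009,
    "Xe", 1.40, 2.16, 0.332, 3.924
  )
}

element_lookup <- function(elements, column, context = "radius") {
  tab <- element_data()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    missing <- unique(elements[is.na(idx)])
    abort(sprintf("no tabulated %s for element(s): %s",
                  context, paste(missing, collapse = ", ")))
  }
  tab[[column]][idx]
}

#' Covalent radii for a vector of element symbols
#' @param elements character vector of element symbols.
#' @return numeric vector, angstrom.
#' @export
covalent_radius <- function(elements) {
  element_lookup(elements, "r_cov", "covalent radius")
}

#' Van der Waals radii for a vector of element symbols
#' @param elements character vector of element symbols.
#' @return numeric vector, angstrom.
#' @export
vdw_radius <- function(elements) {
  element_lookup(elements, "r_vdw", "van der Waals radius")
}
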