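# Unit conversions (CODATA 2018) and small shared helpers.

.ANG2BOHR <- 1.8897261254578281
.HARTREE2KCAL <- 627.5094740631
.FWHM_SIGMA <- 2 * sqrt(2 * log(2))

# minimum allowed interatomic / probe-atom distance (angstrom)
.MIN_DIST_ANG <- 0.1

.ATOMIC_MASSES <- c(
  H = 1.008, He = 4.0026, Li = 6.94, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998403, Na = 22.98977, Mg = 24.305,
  P = 30.973762, S = 32.06, Cl = 35.45, K = 39.0983, Br = 79.904, I = 126.90447
)

.element_mass <- function(element) {
  m <- .ATOMIC_MASSES[element]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

.unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv < 1e-12) stop("direction vector has (near-)zero norm")
  v / nv
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Center of mass of a set of atoms
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates (angstrom).
#' @return length-3 numeric vector (angstrom).
#' @keywords internal
.center_of_mass <- function(elements, coords) {
  m <- .element_mass(elements)
  unname(colSums(coords * m) / sum(m))
}
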