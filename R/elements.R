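# Element data tables used across the package.  All values are pinned here for
# the life of the repo: descriptors, geometry and scoring must not drift when
# upstream sources revise constants.

# standard atomic weights (g/mol), abridged to the elements the pipeline touches
.ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Br = 79.904, I = 126.904
)

# admissible valences for neutral atoms (first entry = default for implicit-H
# filling, further entries allow hypervalent states, e.g. S(VI) in sulfonyl)
.VALENCES <- list(
  H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L, Si = 4L
)

# van der Waals radii (Angstrom; Bondi-style), used by the scorer and the
# Gaussian overlap volume
.VDW_RADII <- c(
  H = 1.10, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Si = 2.10
)

# single-bond covalent radii (Angstrom), used to derive ideal bond lengths
.COV_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39, Si = 1.11
)

# SMILES "organic subset": elements writable without brackets
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# elements allowed to carry the aromatic flag
.AROMATIC_ELEMENTS <- c("B", "C", "N", "O", "P", "S")

atomic_weight <- function(el) {
  w <- .ATOMIC_WEIGHTS[el]
  if (anyNA(w)) stop("no atomic weight for element(s): ",
                     paste(unique(el[is.na(w)]), collapse = ", "))
  unname(w)
}

vdw_radius <- function(el) {
  r <- .VDW_RADII[el]
  r[is.na(r)] <- 1.7  # fall back to carbon-like for exotic elements
  unname(r)
}

cov_radius <- function(el) {
  r <- .COV_RADII[el]
  r[is.na(r)] <- 0.76
  unname(r)
}

#' Allowed valences for an element, adjusted for formal charge
#'
#' Standard organic-chemistry adjustments: a positive charge on N/O/S/P raises
#' the admissible valence by one, a negative charge lowers it by one; for
#' carbon and boron both signs lower it by one (carbanion/carbocation are
#' trivalent).
#' @noRd
allowed_valences <- function(element, charge = 0L) {
  base <- .VALENCES[[element]]
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  if (element %in% c("N", "O", "S", "P")) return(pmax(base + charge, 0L))
  if (element %in% c("C", "B")) return(pmax(base - abs(charge), 0L))
  pmax(base + charge, 0L)
}

#' Ideal bond length between two elements (Angstrom)
#' @noRd
ideal_bond_length <- function(el1, el2, order = 1, aromatic = FALSE) {
  len <- cov_radius(el1) + cov_radius(el2)
  scale <- ifelse(aromatic, 0.91, ifelse(order >= 3, 0.80, ifelse(order == 2, 0.87, 1.0)))
  len * scale
}
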