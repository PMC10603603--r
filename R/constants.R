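#' Physical and chemical constants
#'
#' All mass arithmetic in the package flows through one table of monoisotopic
#' atomic masses and one proton mass constant, so that doublet deltas, stub
#' masses, fragment masses and precursor neutral masses are mutually
#' consistent.
#'
#' @format `xl_constants` is a named list with elements:
#' \describe{
#'   \item{proton_mass}{mass of a proton in Da, used for all m/z <-> neutral
#'     mass conversions}
#'   \item{isotope_gap}{averaged spacing of adjacent isotopologue peaks in Da
#'     (the C13 - C12 difference averaged over typical peptide elemental
#'     composition)}
#'   \item{atomic_masses}{named numeric vector of monoisotopic atomic masses
#'     (Da) for the elements occurring in peptides and amine-reactive
#'     cross-linkers}
#' }
#' @export
xl_constants <- list(
  proton_mass = 1.007276466,
  isotope_gap = 1.00335,
  atomic_masses = c(
    H = 1.00782503207,
    C = 12.0,
    N = 14.0030740048,
    O = 15.9949146196,
    S = 31.97207100,
    P = 30.97376163
  )
)

#' Monoisotopic mass of an elemental composition
#'
#' Parses a Hill-style composition string such as `"C3H2O"` or `"C6H12N2O"`
#' (element symbols followed by optional counts) and sums monoisotopic atomic
#' masses from [xl_constants].
#'
#' @param composition character vector of composition strings.
#' @return numeric vector of monoisotopic masses in Da.
#' @examples
#' composition_mass("H2O")
#' composition_mass(c("C3H2O", "C3H2OS"))
#' @export
composition_mass <- function(composition) {
  vapply(composition, function(comp) {
    stopifnot(is.character(comp), length(comp) == 1L, nzchar(comp))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", comp)[[1]]
    tokens <- regmatches(comp, list(m))[[1]]
    if (sum(nchar(tokens)) != nchar(comp)) {
      stop("cannot parse elemental composition: ", comp, call. = FALSE)
    }
    total <- 0
    for (tok in tokens) {
      elem <- sub("[0-9]+$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      mass <- xl_constants$atomic_masses[elem]
      if (is.na(mass)) stop("unknown element '", elem, "' in ", comp, call. = FALSE)
      total <- total + mass * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

# residue (not free amino acid) elemental compositions, 20 canonical residues
.residue_compositions <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

# residue masses computed once, at build time, from the shared atomic-mass table
.residue_masses <- local({
  masses <- composition_mass(unname(.residue_compositions))
  names(masses) <- names(.residue_compositions)
  masses
})

.water_mass <- composition_mass("H2O")

#' Monoisotopic residue masses of the 20 canonical amino acids
#'
#' @return named numeric vector (one-letter residue codes) of monoisotopic
#'   residue masses in Da, derived from elemental compositions and
#'   [xl_constants].
#' @export
residue_masses <- function() .residue_masses

# neutral mass <-> m/z helpers shared by all modules
neutral_to_mz <- function(neutral_mass, charge) {
  (neutral_mass + charge * xl_constants$proton_mass) / charge
}

mz_to_neutral <- function(mz, charge) {
  (mz - xl_constants$proton_mass) * charge
}

ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
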