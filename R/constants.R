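# Physical constants and unit bridges.  Canonical internal units are
# Angstrom, kcal/mol, kcal/(mol A), fs, K, amu, elementary charge.

#' Physical constants used throughout the package
#'
#' A named list of the physical constants and unit-conversion factors the
#' package relies on.  All internal computation uses Angstrom, kcal/mol,
#' femtosecond, Kelvin, atomic mass unit and elementary charge.
#'
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal mol^-1 K^-1.}
#'   \item{coulomb}{Coulomb prefactor, kcal mol^-1 A e^-2 (the standard
#'     biomolecular force-field convention).}
#'   \item{accel}{Conversion from kcal mol^-1 A^-1 / amu to A fs^-2, used by
#'     the integrators.}
#'   \item{pN_per_kcalmolA}{Piconewton equivalent of 1 kcal mol^-1 A^-1,
#'     derived from CODATA values of the calorie and Avogadro's number;
#'     used to convert steering forces given in pN.}
#'   \item{eV_per_kcalmol}{Electronvolt equivalent of 1 kcal/mol, for
#'     converting datasets labelled in eV / eV A^-1.}
#' }
#'
#' @examples
#' gdmlrConstants$kB * 300  # thermal energy at 300 K, kcal/mol
#' @export
gdmlrConstants <- list(
  kB               = 0.0019872041,
  coulomb          = 332.06,
  accel            = 4.184e-4,
  pN_per_kcalmolA  = 69.4786,
  eV_per_kcalmol   = 0.0433641
)

# Element symbols indexed by atomic number (through Kr; ample for organic
# molecules and the toy systems).
.elementSymbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

# Standard atomic weights (amu), same indexing.
.elementMasses <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798
)

#' Standard atomic masses for a vector of atomic numbers
#'
#' @param z Integer vector of atomic numbers.
#' @return Numeric vector of standard atomic weights in amu.
#' @examples
#' atomicMass(c(1, 6, 8))
#' @export
atomicMass <- function(z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L) || any(z > length(.elementMasses)))
    stop("atomic numbers must be in 1..", length(.elementMasses))
  .elementMasses[z]
}

.symbolToZ <- function(sym) {
  z <- match(sym, .elementSymbols)
  if (anyNA(z)) {
    # allow numeric species columns
    zz <- suppressWarnings(as.integer(sym))
    z[is.na(z)] <- zz[is.na(z)]
  }
  if (anyNA(z)) stop("unknown element symbol(s): ",
                     paste(unique(sym[is.na(z)]), collapse = ", "))
  as.integer(z)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic operations in the
# package funnel through this so that user-level seeds are self-contained.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# md5 of an arbitrary R object via its serialization (provenance hashes).
.objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
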