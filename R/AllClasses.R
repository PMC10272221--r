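# S4 classes shared across the package, their validity methods, accessors
# and show methods.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' AtomicConfiguration: one molecular geometry
#'
#' Atomic numbers plus Cartesian coordinates (Angstrom) of a single
#' configuration.  Validity requires at least two atoms, one coordinate row
#' per atom, finite coordinates and strictly positive pairwise distances.
#'
#' @slot Z integer vector of atomic numbers.
#' @slot xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @export
setClass("AtomicConfiguration",
  representation(Z = "integer", xyz = "matrix"))

setValidity("AtomicConfiguration", function(object) {
  n <- length(object@Z)
  if (n < 2L) return("need at least 2 atoms")
  if (!is.numeric(object@xyz) || nrow(object@xyz) != n || ncol(object@xyz) != 3L)
    return("xyz must be an n x 3 numeric matrix matching length(Z)")
  if (any(!is.finite(object@xyz))) return("coordinates must be finite")
  if (min(stats::dist(object@xyz)) <= 0)
    return("coincident atoms: all pairwise distances must be strictly positive")
  TRUE
})

#' Construct an AtomicConfiguration
#'
#' @param Z integer vector of atomic numbers.
#' @param xyz n x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @return An [AtomicConfiguration-class] object.
#' @examples
#' atomicConfiguration(c(6, 6), rbind(c(0, 0, 0), c(1.5, 0, 0)))
#' @export
atomicConfiguration <- function(Z, xyz) {
  new("AtomicConfiguration", Z = as.integer(Z),
      xyz = matrix(as.numeric(xyz), nrow = length(Z), ncol = 3L))
}

#' MolecularDataset: labelled configurations
#'
#' An ordered collection of configurations of one molecule together with
#' reference total energies (kcal/mol) and per-atom forces
#' (kcal mol^-1 A^-1).  All frames share the same atom count and atomic
#' number sequence.
#'
#' @slot Z integer vector of atomic numbers (shared by all frames).
#' @slot coords numeric array natoms x 3 x nframes, Angstrom.
#' @slot energies numeric vector, one energy per frame, kcal/mol.
#' @slot forces numeric array natoms x 3 x nframes, kcal mol^-1 A^-1.
#' @slot name free-text dataset name.
#' @slot provenance free-text origin record (generator parameters, file path,
#'   PRNG seeds).
#' @export
setClass("MolecularDataset",
  representation(Z = "integer", coords = "array", energies = "numeric",
                 forces = "array", name = "character",
                 provenance = "character"))

setValidity("MolecularDataset", function(object) {
  n <- length(object@Z)
  dc <- dim(object@coords); df <- dim(object@forces)
  if (length(dc) != 3L || dc[1] != n || dc[2] != 3L)
    return("coords must be a natoms x 3 x nframes array")
  if (!identical(df, dc))
    return("forces array shape must match coords exactly")
  if (length(object@energies) != dc[3])
    return("one energy per frame required")
  if (any(!is.finite(object@energies))) return("energies must be finite")
  if (any(!is.finite(object@coords)) || any(!is.finite(object@forces)))
    return("coordinates and forces must be finite")
  TRUE
})

#' Construct a MolecularDataset
#'
#' @param Z integer vector of atomic numbers.
#' @param coords natoms x 3 x nframes array (Angstrom).
#' @param energies numeric vector of frame energies (kcal/mol).
#' @param forces array like `coords` (kcal mol^-1 A^-1).
#' @param name,provenance free-text metadata.
#' @return A [MolecularDataset-class].
#' @export
molecularDataset <- function(Z, coords, energies, forces, name = "",
                             provenance = "") {
  new("MolecularDataset", Z = as.integer(Z), coords = coords,
      energies = as.numeric(energies), forces = forces,
      name = name, provenance = provenance)
}

#' DescriptorSpec: the inverse-distance feature map plus an active mask
#'
#' The ordered list of atom pairs defining the global descriptor (all
#' N(N-1)/2 pairs, lexicographic in 0-based (i, j) with i < j) together with
#' a boolean mask selecting the active features.  Global, local-cutoff and
#' importance-reduced descriptors are all values of this class differing
#' only in the mask.
#'
#' @slot nAtoms integer atom count.
#' @slot pairs integer matrix with columns i, j (0-based, i < j),
#'   lexicographically ordered; one row per feature of the full map.
#' @slot active logical vector, one flag per row of `pairs`.
#' @export
setClass("DescriptorSpec",
  representation(nAtoms = "integer", pairs = "matrix", active = "logical"))

setValidity("DescriptorSpec", function(object) {
  n <- object@nAtoms
  m <- n * (n - 1L) / 2L
  if (n < 2L) return("nAtoms must be >= 2")
  if (nrow(object@pairs) != m)
    return("pairs must enumerate all n(n-1)/2 atom pairs")
  if (length(object@active) != m)
    return("active mask length must equal the number of pairs")
  if (!any(object@active)) return("at least one feature must be active")
  TRUE
})

#' GDMLModel: a trained gradient-domain kernel force field
#'
#' Holds the training geometries, the solved coefficient vectors, the kernel
#' hyperparameters and the energy integration constant, plus cached
#' descriptor quantities used by the predictors.
#'
#' @slot spec the [DescriptorSpec-class] the model was trained with.
#' @slot Z atomic numbers of the molecule.
#' @slot trainCoords natoms x 3 x M array of training geometries.
#' @slot alpha 3N x M matrix of solved coefficients (column per training
#'   point).
#' @slot sigma Matern length scale in descriptor units (A^-1).
#' @slot lambda dimensionless regularization strength (scales the mean
#'   kernel diagonal).
#' @slot energyOffset integration constant of the energy predictor,
#'   kcal/mol.
#' @slot trainDesc d x M matrix of training-point descriptor values (cache).
#' @slot trainV d x M matrix with columns J_b alpha_b (descriptor-space
#'   images of the coefficients; cache).
#' @slot provenance free text (dataset hash, training indices, seeds).
#' @export
setClass("GDMLModel",
  representation(spec = "DescriptorSpec", Z = "integer",
                 trainCoords = "array", alpha = "matrix", sigma = "numeric",
                 lambda = "numeric", energyOffset = "numeric",
                 trainDesc = "matrix", trainV = "matrix",
                 provenance = "character"))

setValidity("GDMLModel", function(object) {
  n <- length(object@Z); m <- dim(object@trainCoords)[3]
  if (nrow(object@alpha) != 3L * n || ncol(object@alpha) != m)
    return("alpha must be 3N x M")
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@lambda < 0) return("lambda must be >= 0")
  TRUE
})

#' FeatureImportance: per-feature masking losses
#'
#' The masking loss of every active feature of a model, evaluated on a test
#' subset: the summed squared change of the force prediction when that
#' feature is zeroed everywhere while all model parameters stay fixed.
#'
#' @slot featureIdx integer indices (rows of the full pair map) of the
#'   active features the losses refer to.
#' @slot losses numeric masking losses, kcal^2 mol^-2 A^-2, same order.
#' @slot nTest number of test configurations used.
#' @slot mode "both" (value and gradient channel masked) or "value".
#' @slot modelHash provenance hash of the evaluated model.
#' @export
setClass("FeatureImportance",
  representation(featureIdx = "integer", losses = "numeric",
                 nTest = "integer", mode = "character",
                 modelHash = "character"))

setValidity("FeatureImportance", function(object) {
  if (length(object@losses) != length(object@featureIdx))
    return("one loss per active feature required")
  if (any(object@losses < 0)) return("losses must be >= 0")
  TRUE
})

#' ToyTopology: an analytic toy molecular potential
#'
#' Bonded (harmonic bond/angle, cosine dihedral) plus nonbonded
#' (Lennard-Jones and screened-Coulomb) terms with exact analytic forces.
#' Serves as the reference potential-energy surface for building labelled
#' datasets.
#'
#' @slot kind "chain", "ring" or "dimer".
#' @slot Z atomic numbers of the beads.
#' @slot masses bead masses, amu.
#' @slot bonds matrix (i, j, r0, k): harmonic bonds, 1-based indices.
#' @slot angles matrix (i, j, k, theta0, ka): harmonic angles at vertex j.
#' @slot dihedrals matrix (i, j, k, l, amp, mult): cosine torsions.
#' @slot charges partial charges, e.
#' @slot ljEps,ljSigma Lennard-Jones parameters (kcal/mol, A).
#' @slot screenLength Coulomb screening length, A.
#' @slot nbPairs matrix of nonbonded pairs (1-based, excludes 1-2/1-3
#'   neighbours).
#' @slot seed integer seed the topology was built from.
#' @export
setClass("ToyTopology",
  representation(kind = "character", Z = "integer", masses = "numeric",
                 bonds = "matrix", angles = "matrix", dihedrals = "matrix",
                 charges = "numeric", ljEps = "numeric", ljSigma = "numeric",
                 screenLength = "numeric", nbPairs = "matrix",
                 seed = "integer", cache = "environment"))

setValidity("ToyTopology", function(object) {
  n <- length(object@Z)
  idx <- c(object@bonds[, 1:2], if (nrow(object@angles)) object@angles[, 1:3],
           if (nrow(object@dihedrals)) object@dihedrals[, 1:4],
           if (nrow(object@nbPairs)) object@nbPairs)
  if (length(idx) && (min(idx) < 1 || max(idx) > n))
    return("term indices out of range")
  if (nrow(object@bonds) && any(object@bonds[, 4] < 0))
    return("bond stiffness must be >= 0")
  if (length(object@masses) != n) return("one mass per atom required")
  TRUE
})

#' MDTrajectory: a sampled molecular-dynamics trajectory
#'
#' @slot Z atomic numbers.
#' @slot times sampled times, fs.
#' @slot coords natoms x 3 x nsamples array of sampled positions.
#' @slot epot,ekin potential / kinetic energy per sample, kcal/mol.
#' @slot rg gyration radius per sample, A.
#' @slot dt integration timestep, fs.
#' @slot mode "nve" or "langevin".
#' @slot temperature thermostat target, K (NA for nve).
#' @slot friction Langevin friction, fs^-1 (NA for nve).
#' @slot seed integer seed used for initial velocities / noise.
#' @slot events data.frame of logged events (step, time, type, detail).
#' @slot finalVelocities natoms x 3 matrix, A/fs.
#' @export
setClass("MDTrajectory",
  representation(Z = "integer", times = "numeric", coords = "array",
                 epot = "numeric", ekin = "numeric", rg = "numeric",
                 dt = "numeric", mode = "character", temperature = "numeric",
                 friction = "numeric", seed = "integer",
                 events = "data.frame", finalVelocities = "matrix"))

## ---- generics ----

#' @rdname MolecularDataset-class
#' @param object,x a MolecularDataset (or other class as documented).
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))
#' @rdname MolecularDataset-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname MolecularDataset-class
#' @export
setGeneric("atomicNumbers", function(object) standardGeneric("atomicNumbers"))
#' @rdname MolecularDataset-class
#' @export
setGeneric("energies", function(object) standardGeneric("energies"))
#' @rdname MolecularDataset-class
#' @export
setGeneric("forces", function(object) standardGeneric("forces"))
#' @rdname MolecularDataset-class
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname MolecularDataset-class
#' @param i frame index.
#' @export
setGeneric("getConfig", function(object, i) standardGeneric("getConfig"))

#' @rdname DescriptorSpec-class
#' @param object a DescriptorSpec.
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))
#' @rdname DescriptorSpec-class
#' @export
setGeneric("activeFeatures", function(object) standardGeneric("activeFeatures"))
#' @rdname DescriptorSpec-class
#' @export
setGeneric("featurePairs", function(object) standardGeneric("featurePairs"))

setMethod("nAtoms", "MolecularDataset", function(object) length(object@Z))
setMethod("nAtoms", "AtomicConfiguration", function(object) length(object@Z))
setMethod("nAtoms", "DescriptorSpec", function(object) object@nAtoms)
setMethod("nAtoms", "ToyTopology", function(object) length(object@Z))
setMethod("nAtoms", "GDMLModel", function(object) length(object@Z))
setMethod("nFrames", "MolecularDataset", function(object) dim(object@coords)[3])
setMethod("nFrames", "MDTrajectory", function(object) dim(object@coords)[3])
setMethod("atomicNumbers", "MolecularDataset", function(object) object@Z)
setMethod("atomicNumbers", "AtomicConfiguration", function(object) object@Z)
setMethod("atomicNumbers", "ToyTopology", function(object) object@Z)
setMethod("energies", "MolecularDataset", function(object) object@energies)
setMethod("energies", "MDTrajectory",
          function(object) data.frame(time = object@times, epot = object@epot,
                                      ekin = object@ekin,
                                      etot = object@epot + object@ekin))
setMethod("forces", "MolecularDataset", function(object) object@forces)
setMethod("coords", "MolecularDataset", function(object) object@coords)
setMethod("coords", "AtomicConfiguration", function(object) object@xyz)
setMethod("coords", "MDTrajectory", function(object) object@coords)

setMethod("getConfig", "MolecularDataset", function(object, i) {
  stopifnot(i >= 1L, i <= nFrames(object))
  atomicConfiguration(object@Z, object@coords[, , i])
})
setMethod("getConfig", "MDTrajectory", function(object, i) {
  stopifnot(i >= 1L, i <= nFrames(object))
  atomicConfiguration(object@Z, object@coords[, , i])
})

setMethod("nFeatures", "DescriptorSpec", function(object) sum(object@active))
setMethod("activeFeatures", "DescriptorSpec", function(object) which(object@active))
setMethod("featurePairs", "DescriptorSpec",
          function(object) object@pairs[object@active, , drop = FALSE])

## ---- show methods ----

setMethod("show", "AtomicConfiguration", function(object) {
  cat(sprintf("AtomicConfiguration: %d atoms, extent %.2f A\n",
              length(object@Z), max(stats::dist(object@xyz))))
})

setMethod("show", "MolecularDataset", function(object) {
  cat(sprintf("MolecularDataset '%s': %d frames of %d atoms\n",
              object@name, nFrames(object), nAtoms(object)))
  cat(sprintf("  energies: [%.4f, %.4f] kcal/mol\n",
              min(object@energies), max(object@energies)))
  cat(sprintf("  |F| rms: %.4f kcal/(mol A)\n", sqrt(mean(object@forces^2))))
})

setMethod("show", "DescriptorSpec", function(object) {
  cat(sprintf(
    "DescriptorSpec: %d atoms, %d/%d features active (%.1f%%)\n",
    object@nAtoms, sum(object@active), length(object@active),
    100 * mean(object@active)))
})

setMethod("show", "GDMLModel", function(object) {
  cat(sprintf(
    "GDMLModel: %d training points, %d atoms, %d active features\n",
    ncol(object@alpha), length(object@Z), sum(object@spec@active)))
  cat(sprintf("  sigma = %.6g, lambda = %.3g, energy offset = %.4f kcal/mol\n",
              object@sigma, object@lambda, object@energyOffset))
})

setMethod("show", "FeatureImportance", function(object) {
  cat(sprintf(
    "FeatureImportance: %d features over %d test configurations (mode '%s')\n",
    length(object@losses), object@nTest, object@mode))
  cat("  loss quartiles: ",
      paste(signif(stats::quantile(object@losses, c(.25, .5, .75)), 3),
            collapse = " / "), "\n")
})

setMethod("show", "ToyTopology", function(object) {
  cat(sprintf(
    "ToyTopology '%s': %d beads, %d bonds, %d angles, %d dihedrals, %d nonbonded pairs\n",
    object@kind, length(object@Z), nrow(object@bonds), nrow(object@angles),
    nrow(object@dihedrals), nrow(object@nbPairs)))
})

setMethod("show", "MDTrajectory", function(object) {
  cat(sprintf(
    "MDTrajectory (%s): %d samples over %.1f ps, dt = %.2f fs, %d events\n",
    object@mode, length(object@times), max(object@times) / 1000,
    object@dt, nrow(object@events)))
})
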