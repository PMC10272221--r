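# Global inverse-pairwise-distance descriptor: feature map, analytic
# Jacobian, masks and per-feature distance statistics.

#' Enumerate the all-pairs feature map
#'
#' Returns the ordered atom-pair index map of the global descriptor: all
#' n(n-1)/2 unordered pairs (i, j), 0-based, i < j, in lexicographic order.
#' Feature indices everywhere in the package refer to rows of this map.
#'
#' @param nAtoms atom count (>= 2).
#' @return Integer matrix with columns `i`, `j`.
#' @examples
#' pairIndexMap(3)        # three features: (0,1), (0,2), (1,2)
#' nrow(pairIndexMap(42)) # 861
#' @export
pairIndexMap <- function(nAtoms) {
  nAtoms <- as.integer(nAtoms)
  if (is.na(nAtoms) || nAtoms < 2L) stop("nAtoms must be >= 2")
  # (i < j) lexicographic: for each i, j runs over (i+1)..(n-1)
  ii <- rep(0:(nAtoms - 2L), times = (nAtoms - 1L):1L)
  jj <- unlist(lapply(0:(nAtoms - 2L), function(a) (a + 1L):(nAtoms - 1L)),
               use.names = FALSE)
  cbind(i = as.integer(ii), j = as.integer(jj))
}

#' Construct a DescriptorSpec
#'
#' @param nAtoms atom count.
#' @param active logical mask over the full pair map (default all active,
#'   the global descriptor), or an integer vector of active feature indices.
#' @return A [DescriptorSpec-class].
#' @examples
#' descriptorSpec(10)                      # global descriptor, 45 features
#' descriptorSpec(4, active = c(1, 2, 6))  # reduced to three features
#' @export
descriptorSpec <- function(nAtoms, active = NULL) {
  pm <- pairIndexMap(nAtoms)
  m <- nrow(pm)
  if (is.null(active)) {
    act <- rep(TRUE, m)
  } else if (is.logical(active)) {
    stopifnot(length(active) == m)
    act <- active
  } else {
    act <- rep(FALSE, m)
    act[as.integer(active)] <- TRUE
  }
  new("DescriptorSpec", nAtoms = as.integer(nAtoms), pairs = pm, active = act)
}

# Internal: descriptor values and Jacobian for a coordinate matrix.
# Returns list(values = d-vector of 1/r, jac = d x 3N matrix).  Only active
# features are represented (coordinate projection: inactive features are
# dropped from values and Jacobian alike).
.descriptor <- function(xyz, spec, jacobian = TRUE) {
  act <- spec@pairs[spec@active, , drop = FALSE]
  iIdx <- act[, 1L] + 1L
  jIdx <- act[, 2L] + 1L
  dvec <- xyz[iIdx, , drop = FALSE] - xyz[jIdx, , drop = FALSE]
  r2 <- rowSums(dvec * dvec)
  if (any(r2 <= 0))
    stop("singular descriptor: coincident atoms in pair(s) ",
         paste(which(r2 <= 0)[1], collapse = ","))
  r <- sqrt(r2)
  values <- 1 / r
  if (!jacobian) return(list(values = values, jac = NULL, r = r))
  d <- length(r)
  J <- matrix(0, d, 3L * nrow(xyz))
  g <- dvec / (r2 * r)                     # (r_i - r_j) / r^3
  rows <- seq_len(d)
  for (s in 1:3) {
    J[cbind(rows, 3L * (iIdx - 1L) + s)] <- -g[, s]
    J[cbind(rows, 3L * (jIdx - 1L) + s)] <- g[, s]
  }
  list(values = values, jac = J, r = r)
}

#' Compute the inverse-distance descriptor of a configuration
#'
#' Maps a geometry to the active features of `spec`: value 1/r_ij per active
#' pair, plus the analytic Jacobian with respect to the Cartesian
#' coordinates.  The Jacobian row of pair (i, j) is nonzero only in the six
#' columns of atoms i and j, and the two 3-blocks are exact negatives:
#' d(1/r_ij)/dr_i = -(r_i - r_j)/r_ij^3.
#'
#' @param config an [AtomicConfiguration-class] (or bare n x 3 coordinate
#'   matrix).
#' @param spec a [DescriptorSpec-class]; its atom count must match.
#' @return List with `values` (A^-1, one per active feature, in feature
#'   order) and `jacobian` (d x 3N matrix, A^-2).
#' @examples
#' cfg <- atomicConfiguration(c(6, 6), rbind(c(0, 0, 0), c(2, 0, 0)))
#' computeDescriptor(cfg, descriptorSpec(2))$values  # 0.5
#' @export
computeDescriptor <- function(config, spec) {
  xyz <- if (is(config, "AtomicConfiguration")) config@xyz else config
  if (nrow(xyz) != spec@nAtoms)
    stop("configuration has ", nrow(xyz), " atoms but spec expects ",
         spec@nAtoms)
  d <- .descriptor(xyz, spec)
  list(values = d$values, jacobian = d$jac)
}

#' Per-feature interatomic distance statistics over a dataset
#'
#' Exact min / mean / max of the interatomic distance r_ij of every active
#' feature across all frames of a dataset.  These statistics drive the
#' local-cutoff mask and the short/long-range decomposition.
#'
#' @param dataset a [MolecularDataset-class].
#' @param spec a [DescriptorSpec-class].
#' @return data.frame with columns `feature` (index into the full pair
#'   map), `i`, `j` (0-based atoms), `min`, `mean`, `max` (Angstrom).
#' @export
featureDistanceStats <- function(dataset, spec) {
  stopifnot(is(dataset, "MolecularDataset"), nFrames(dataset) >= 1L)
  act <- spec@pairs[spec@active, , drop = FALSE]
  iIdx <- act[, 1L] + 1L; jIdx <- act[, 2L] + 1L
  nf <- nFrames(dataset)
  d <- nrow(act)
  mn <- rep(Inf, d); mx <- rep(-Inf, d); sm <- numeric(d)
  for (f in seq_len(nf)) {
    xyz <- dataset@coords[, , f]
    dv <- xyz[iIdx, , drop = FALSE] - xyz[jIdx, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    mn <- pmin(mn, r); mx <- pmax(mx, r); sm <- sm + r
  }
  data.frame(feature = which(spec@active), i = act[, 1L], j = act[, 2L],
             min = mn, mean = sm / nf, max = mx)
}

#' Serialize / read a descriptor mask as JSON
#'
#' Masks are stored as a human-diffable JSON object
#' `{"n_atoms": N, "active_pairs": [[i, j], ...]}` with 0-based atom
#' indices.
#'
#' @param spec a [DescriptorSpec-class].
#' @param path output / input file path.
#' @return `readMask` returns a [DescriptorSpec-class]; `writeMask` its path,
#'   invisibly.
#' @export
writeMask <- function(spec, path) {
  ap <- spec@pairs[spec@active, , drop = FALSE]
  obj <- list(n_atoms = spec@nAtoms,
              active_pairs = lapply(seq_len(nrow(ap)),
                                    function(r) as.integer(ap[r, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(obj$n_atoms)
  pm <- pairIndexMap(n)
  ap <- if (is.matrix(obj$active_pairs)) obj$active_pairs
  else do.call(rbind, obj$active_pairs)
  storage.mode(ap) <- "integer"
  key <- pm[, 1] * n + pm[, 2]
  act <- key %in% (ap[, 1] * n + ap[, 2])
  descriptorSpec(n, active = act)
}
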