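# Decompositions of the force prediction: per-atom contributions and
# interaction maps, per-feature contribution channels and their power-law
# classification, short/long-range decomposition, descriptor scaling fits,
# and the gyration radius observable.

# Per-atom descriptor-space coefficient images: for each atom k, the d x M
# matrix with columns J_b[, cols(k)] alpha_b[cols(k)] — the piece of
# trainV carried by atom k's three Cartesian components.  Summing over k
# recovers trainV exactly.
.atomChannelV <- function(model) {
  n <- length(model@Z); M <- ncol(model@alpha)
  ds <- .descriptorSet(model@trainCoords, model@spec)
  lapply(seq_len(n), function(k) {
    cols <- 3L * (k - 1L) + 1:3
    Vk <- matrix(0, nrow(model@trainDesc), M)
    for (b in seq_len(M))
      Vk[, b] <- ds$J[[b]][, cols, drop = FALSE] %*% model@alpha[cols, b]
    Vk
  })
}

.forcesFromV <- function(pc, Vk, sigma) {
  sk <- colSums(pc$U * Vk)
  w <- -(Vk %*% pc$g) - pc$U %*% (pc$h * sk)
  matrix(crossprod(pc$jac, w), ncol = 3, byrow = TRUE)
}

#' Contribution of one atom to the force prediction
#'
#' Restricts the kernel force expansion to the three coefficient components
#' of training-point atom k (0-based), yielding that atom's contribution
#' F^k to the predicted forces on all atoms.  The contributions over all k
#' partition the full prediction exactly: sum_k F^k = F.
#'
#' @param model a [GDMLModel-class].
#' @param config an [AtomicConfiguration-class] or n x 3 matrix.
#' @param k atom index, 0-based, 0 <= k < N.
#' @return n x 3 matrix of force contributions, kcal mol^-1 A^-1.
#' @export
atomContribution <- function(model, config, k) {
  n <- length(model@Z)
  if (k < 0 || k >= n) stop("atom index k must be in 0..", n - 1L)
  xyz <- .asXYZ(config)
  pc <- .predictCore(model, xyz)
  Vk <- .atomChannelV(model)[[k + 1L]]
  .forcesFromV(pc, Vk, model@sigma)
}

#' Averaged pairwise interaction map
#'
#' Entry (k, l) is the norm of the force components on atom l of atom k's
#' contribution F^k, averaged over the given configurations.  The
#' `normalized` matrix applies the log-scale min-max mapping to [0, 1]
#' (an epsilon shift of 1e-12 * max tolerates exact zeros from masked
#' channels).  The map is a contribution of k to l and is not symmetric by
#' construction.
#'
#' @param model a [GDMLModel-class].
#' @param dataset a [MolecularDataset-class].
#' @param configIndices nonempty frame indices to average over.
#' @return List with `contributions` (N x N, kcal mol^-1 A^-1),
#'   `normalized` (N x N in [0, 1]) and `nConfigs`.
#' @export
interactionMap <- function(model, dataset, configIndices) {
  stopifnot(length(configIndices) >= 1L)
  n <- length(model@Z)
  Vks <- .atomChannelV(model)
  acc <- matrix(0, n, n)
  for (f in configIndices) {
    pc <- .predictCore(model, dataset@coords[, , f])
    for (k in seq_len(n)) {
      Fk <- .forcesFromV(pc, Vks[[k]], model@sigma)
      acc[k, ] <- acc[k, ] + sqrt(rowSums(Fk * Fk))
    }
  }
  contrib <- acc / length(configIndices)
  mx <- max(contrib)
  if (mx <= 0 || diff(range(contrib)) == 0) {
    warning("degenerate interaction map (all entries equal); ",
            "normalized map set to zeros")
    norm <- matrix(0, n, n)
  } else {
    t0 <- log(contrib + 1e-12 * mx)
    norm <- (t0 - min(t0)) / (max(t0) - min(t0))
  }
  list(contributions = contrib, normalized = norm,
       nConfigs = length(configIndices))
}

#' Mean per-feature contribution magnitudes
#'
#' Splits the force prediction into its exact chain-rule channels through
#' the query configuration's descriptor coordinates: channel n contributes
#' F_(n) = w_n * J_x[n, ], and sum_n F_(n) = F exactly.  Returns the mean
#' over configurations of ||F_(n)|| per active feature, together with the
#' mean interatomic distance of the feature — the inputs of the
#' contribution-versus-distance analysis.
#'
#' @param model a [GDMLModel-class].
#' @param dataset a [MolecularDataset-class].
#' @param configIndices nonempty frame indices.
#' @return data.frame with `feature`, `i`, `j`, `meanDistance` (A),
#'   `meanContribution` (kcal mol^-1 A^-1).
#' @export
featureContributions <- function(model, dataset, configIndices) {
  stopifnot(length(configIndices) >= 1L)
  act <- activeFeatures(model@spec)
  pm <- model@spec@pairs[act, , drop = FALSE]
  accC <- numeric(length(act)); accR <- numeric(length(act))
  for (f in configIndices) {
    pc <- .predictCore(model, dataset@coords[, , f])
    jnorm <- sqrt(rowSums(pc$jac * pc$jac))
    accC <- accC + abs(pc$w) * jnorm      # ||w_n J_x[n, ]|| = |w_n| ||J_x[n, ]||
    accR <- accR + 1 / .descriptor(dataset@coords[, , f],
                                   model@spec, jacobian = FALSE)$values
  }
  data.frame(feature = act, i = pm[, 1], j = pm[, 2],
             meanDistance = accR / length(configIndices),
             meanContribution = accC / length(configIndices))
}

# Per-feature channel forces for a single configuration (exact partition;
# used by tests and the symbolic checks).
.featureChannelForces <- function(model, config) {
  pc <- .predictCore(model, .asXYZ(config))
  # row n of jac scaled by w_n; returns d x 3N matrix of channel forces
  pc$jac * as.numeric(pc$w)
}

#' Classify feature contributions against interatomic distance
#'
#' Per feature, ordinary least squares of log(contribution) on
#' log(distance) across per-configuration samples.  Features with r-squared
#' at or above the threshold are labelled "linear" (their contribution
#' follows a power law in distance; a slope near -2 indicates Coulombic
#' scaling through the inverse-distance Jacobian), the rest "stochastic".
#' Nonpositive contributions are excluded from the fit; features with fewer
#' than 3 valid samples are skipped with a warning.
#'
#' @param distances numeric matrix, samples x features: interatomic
#'   distance of each feature per configuration (A).
#' @param contributions matching matrix of contribution magnitudes.
#' @param r2Threshold r-squared threshold for the "linear" label
#'   (default 0.9).
#' @return data.frame with `feature`, `slope`, `r2`, `class`, `nUsed`.
#' @export
classifyFeatures <- function(distances, contributions, r2Threshold = 0.9) {
  stopifnot(identical(dim(distances), dim(contributions)),
            nrow(distances) >= 3L)
  nf <- ncol(distances)
  slope <- rep(NA_real_, nf); r2 <- rep(NA_real_, nf)
  nUsed <- integer(nf)
  skipped <- 0L
  for (n in seq_len(nf)) {
    ok <- which(contributions[, n] > 0 & distances[, n] > 0)
    nUsed[n] <- length(ok)
    if (length(ok) < 3L) { skipped <- skipped + 1L; next }
    x <- log(distances[ok, n]); y <- log(contributions[ok, n])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope[n] <- fit$coefficients[2]
    ssr <- sum(fit$residuals^2); sst <- sum((y - mean(y))^2)
    r2[n] <- if (sst > 0) 1 - ssr / sst else 1
  }
  if (skipped > 0L)
    warning(skipped, " feature(s) skipped: fewer than 3 positive samples")
  cls <- ifelse(is.na(r2), NA_character_,
                ifelse(r2 >= r2Threshold, "linear", "stochastic"))
  data.frame(feature = seq_len(nf), slope = slope, r2 = r2, class = cls,
             nUsed = nUsed)
}

#' Short/long-range decomposition of a descriptor
#'
#' Counts active features below and above a distance cutoff (default 5 A,
#' the typical local-descriptor cutoff).  Two selectable criteria: `"max"`
#' calls a feature short-ranged iff its distance stays below the cutoff in
#' every configuration; `"mean"` uses the average distance instead.  The
#' two counts always sum to the number of active features.
#'
#' @param stats a [featureDistanceStats()] table covering all active
#'   features of `spec`.
#' @param spec a [DescriptorSpec-class].
#' @param cutoff distance cutoff in Angstrom.
#' @param criterion "max" or "mean".
#' @return List with `nShort`, `nLong` and the logical vector `short` in
#'   feature order.
#' @export
shortLongDecomposition <- function(stats, spec, cutoff = 5,
                                   criterion = c("max", "mean")) {
  criterion <- match.arg(criterion)
  act <- activeFeatures(spec)
  row <- match(act, stats$feature)
  if (anyNA(row)) stop("stats table does not cover all active features")
  val <- if (criterion == "max") stats$max[row] else stats$mean[row]
  short <- val < cutoff
  list(nShort = sum(short), nLong = sum(!short), short = short)
}

#' Linear fit of descriptor size against atom count
#'
#' Least-squares line through (nAtoms, nFeaturesKept) points, with the
#' quadratic all-pairs curve n(n-1)/2 tabulated alongside for comparison.
#' A high r-squared of the linear fit on reduced descriptors, against the
#' exactly quadratic global sizes, is the scaling diagnostic.
#'
#' @param points data.frame or matrix with columns nAtoms and nKept
#'   (>= 2 distinct atom counts).
#' @return List with `slope`, `intercept`, `r2` and a data.frame `points`
#'   including the `quadratic` reference column.
#' @export
scalingFit <- function(points) {
  pts <- as.data.frame(points)
  names(pts)[1:2] <- c("nAtoms", "nKept")
  if (length(unique(pts$nAtoms)) < 2L)
    stop("need at least 2 distinct atom counts")
  fit <- stats::lm(nKept ~ nAtoms, data = pts)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((pts$nKept - mean(pts$nKept))^2)
  pts$quadratic <- pts$nAtoms * (pts$nAtoms - 1) / 2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = if (sst > 0) 1 - ssr / sst else 1, points = pts)
}

#' Gyration radius of a configuration
#'
#' R_g = sqrt( sum_i w_i ||r_i - rbar||^2 / sum_i w_i ), with rbar the
#' w-weighted centroid; weights are standard atomic masses when
#' `massWeighted`, unit otherwise.
#'
#' @param config an [AtomicConfiguration-class] or n x 3 matrix (a bare
#'   matrix requires `massWeighted = FALSE` or explicit `Z`).
#' @param massWeighted use atomic masses as weights?
#' @param Z atomic numbers (only needed for a bare matrix with
#'   `massWeighted = TRUE`).
#' @return Scalar R_g in Angstrom.
#' @export
gyrationRadius <- function(config, massWeighted = FALSE, Z = NULL) {
  xyz <- .asXYZ(config)
  if (massWeighted) {
    if (is.null(Z)) {
      if (!is(config, "AtomicConfiguration"))
        stop("mass weighting needs atomic numbers")
      Z <- config@Z
    }
    w <- atomicMass(Z)
  } else w <- rep(1, nrow(xyz))
  ctr <- colSums(xyz * w) / sum(w)
  dx <- sweep(xyz, 2, ctr)
  sqrt(sum(w * rowSums(dx * dx)) / sum(w))
}

#' Write a matrix as TSV (interaction maps, distance heatmaps)
#'
#' @param m numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
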