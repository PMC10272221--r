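# Training and evaluation of the gradient-domain kernel force field.
#
# The force predictor is the kernel expansion
#   F(x) = sum_b K(x, x_b) alpha_b,
# with K(x, x_b) = J_x^T B(x, x_b) J_b the force-kernel block of kernel.R,
# and the energy predictor is its exact antiderivative
#   E(x) = c - sum_b alpha_b^T grad_{R_b} kappa(x, x_b)
#        = c + sum_b g(d_b) u_b^T v_b,
# where u_b = D(x) - D_b, v_b = J_b alpha_b and g = kappa'/d.  Both share
# the same kernel-derivative code path, so F = -grad E holds analytically.

#' Train a gradient-domain kernel force field
#'
#' Solves the regularized dense system (K + lambda * mean(diag(K)) I) alpha
#' = y by Cholesky factorization, where K is the force-kernel matrix over
#' the training configurations and y stacks the reference forces (atom
#' order, x/y/z within atom).  Energies enter only through the integration
#' constant, chosen so the mean predicted energy over the training points
#' equals the mean reference energy.
#'
#' @param dataset a [MolecularDataset-class].
#' @param indices training frame indices.
#' @param spec a [DescriptorSpec-class] (defaults to the global descriptor).
#' @param sigma Matern length scale; `NULL` selects the median-distance
#'   heuristic of [defaultSigma()].
#' @param lambda dimensionless regularization (default 1e-10); the identity
#'   is scaled by the mean kernel diagonal for unit consistency.
#' @return A [GDMLModel-class].
#' @seealso [predictForces()], [predictEnergy()], [selectSigma()].
#' @export
trainGDML <- function(dataset, indices, spec = NULL, sigma = NULL,
                      lambda = 1e-10) {
  stopifnot(is(dataset, "MolecularDataset"), length(indices) >= 1L)
  if (is.null(spec)) spec <- descriptorSpec(nAtoms(dataset))
  if (nAtoms(dataset) != spec@nAtoms)
    stop("dataset and descriptor spec disagree on atom count")
  if (lambda < 0) stop("lambda must be >= 0")
  M <- length(indices)
  n <- nAtoms(dataset); n3 <- 3L * n
  coordsArr <- dataset@coords[, , indices, drop = FALSE]
  if (is.null(sigma)) sigma <- defaultSigma(dataset, indices, spec)
  K <- assembleForceKernel(coordsArr, spec, sigma)
  if (any(!is.finite(K))) stop("kernel matrix contains non-finite entries")
  # y: per training point, forces flattened as (a1x a1y a1z a2x ...)
  y <- as.numeric(vapply(seq_len(M), function(a)
    as.numeric(t(dataset@forces[, , indices[a]])), numeric(n3)))
  diag(K) <- diag(K) + lambda * mean(diag(K))
  if (lambda == 0) {
    # exact-interpolation mode: the kernel matrix always has the
    # rigid-motion null space of the descriptor Jacobians, so solve in the
    # minimum-norm (pseudoinverse) sense; physical force labels lie in the
    # range (zero net force and torque)
    sv <- svd(K)
    tol <- max(sv$d) * length(sv$d) * .Machine$double.eps
    pos <- sv$d > tol
    alpha <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  } else {
    ch <- tryCatch(chol(K), error = function(e)
      stop("force-kernel system is numerically singular at lambda = ",
           lambda, "; raise lambda (e.g. 1e-10) or reduce near-duplicate ",
           "training configurations [", conditionMessage(e), "]",
           call. = FALSE))
    alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  }
  alphaMat <- matrix(alpha, n3, M)
  ds <- .descriptorSet(coordsArr, spec)
  V <- matrix(0, nrow(ds$D), M)
  for (b in seq_len(M)) V[, b] <- ds$J[[b]] %*% alphaMat[, b]
  model <- new("GDMLModel", spec = spec, Z = dataset@Z,
               trainCoords = coordsArr, alpha = alphaMat, sigma = sigma,
               lambda = lambda, energyOffset = 0,
               trainDesc = ds$D, trainV = V,
               provenance = sprintf("trained on %d frames of '%s'",
                                    M, dataset@name))
  rawE <- vapply(seq_len(M), function(a)
    .predictCore(model, coordsArr[, , a], wantForces = FALSE)$energy,
    numeric(1))
  model@energyOffset <- mean(dataset@energies[indices]) - mean(rawE)
  model
}

#' Median-distance length-scale heuristic
#'
#' Returns the median nonzero pairwise Euclidean distance between the
#' descriptors of (a subsample of) the indexed frames — a standard starting
#' length scale for stationary kernels, recomputed on the active features
#' only, so reduced descriptors automatically get a tighter scale.
#'
#' @param dataset a [MolecularDataset-class].
#' @param indices frame indices to measure on (subsampled to at most 128).
#' @param spec a [DescriptorSpec-class].
#' @return A positive scalar usable as `sigma`.
#' @export
defaultSigma <- function(dataset, indices, spec) {
  take <- if (length(indices) > 128L)
    indices[round(seq(1, length(indices), length.out = 128L))] else indices
  D <- vapply(take, function(f)
    .descriptor(dataset@coords[, , f], spec, jacobian = FALSE)$values,
    numeric(sum(spec@active)))
  D <- matrix(D, ncol = length(take))          # robust for 1-feature specs
  dd <- stats::dist(t(D))
  med <- suppressWarnings(stats::median(dd[dd > 0]))
  if (!is.finite(med) || med <= 0) {
    # single training point or identical descriptors: fall back to the
    # descriptor magnitude scale (interpolation at the point is exact for
    # any sigma)
    med <- stats::median(abs(D))
    if (!is.finite(med) || med <= 0)
      stop("degenerate training set: cannot infer a length scale")
  }
  med
}

# Shared predictor core.  xyz: n x 3 matrix.  Returns forces (n x 3) and
# energy.  All predictors (full, per-atom, per-feature, masked) are thin
# layers over the quantities computed here.
.predictCore <- function(model, xyz, wantForces = TRUE) {
  dsc <- .descriptor(xyz, model@spec)
  U <- dsc$values - model@trainDesc          # d x M, column u_b = D_x - D_b
  dvec <- sqrt(colSums(U * U))
  g <- .mat52g(dvec, model@sigma)
  s <- colSums(U * model@trainV)             # u_b . v_b
  energy <- model@energyOffset + sum(g * s)
  if (!wantForces)
    return(list(energy = energy))
  h <- .mat52h(dvec, model@sigma)
  w <- -(model@trainV %*% g) - U %*% (h * s)
  Fvec <- crossprod(dsc$jac, w)              # 3N
  list(energy = energy,
       forces = matrix(Fvec, ncol = 3, byrow = TRUE),
       U = U, dvec = dvec, g = g, h = h, s = s, w = w, jac = dsc$jac)
}

.asXYZ <- function(config) {
  if (is(config, "AtomicConfiguration")) config@xyz else config
}

#' Predict forces for a configuration
#'
#' Evaluates the kernel force expansion at a query geometry.  Predictions
#' are invariant under rigid translation of the query and equivariant under
#' rotation, and independent of the storage order of the training points.
#'
#' @param model a [GDMLModel-class].
#' @param config an [AtomicConfiguration-class] or n x 3 coordinate matrix.
#' @return n x 3 matrix of forces, kcal mol^-1 A^-1.
#' @export
predictForces <- function(model, config) {
  xyz <- .asXYZ(config)
  if (nrow(xyz) != length(model@Z))
    stop("configuration has ", nrow(xyz), " atoms; model expects ",
         length(model@Z))
  .predictCore(model, xyz)$forces
}

#' Predict the energy of a configuration
#'
#' The exact antiderivative of [predictForces()]: the analytic negative
#' gradient of this energy equals the predicted forces (same kernel
#' derivative code path), up to the additive constant fitted at training.
#'
#' @inheritParams predictForces
#' @return Scalar energy, kcal/mol.
#' @export
predictEnergy <- function(model, config) {
  xyz <- .asXYZ(config)
  if (nrow(xyz) != length(model@Z))
    stop("configuration has ", nrow(xyz), " atoms; model expects ",
         length(model@Z))
  .predictCore(model, xyz, wantForces = FALSE)$energy
}

#' Energy and force RMSE of a model over indexed frames
#'
#' Force RMSE pools all 3N force components of all evaluated frames;
#' energy RMSE is over frames.
#'
#' @param model a [GDMLModel-class].
#' @param dataset a [MolecularDataset-class].
#' @param indices frame indices to evaluate on (nonempty).
#' @return data.frame with `energyRMSE` (kcal/mol), `forceRMSE`
#'   (kcal mol^-1 A^-1) and `nEval`.
#' @export
evaluateModel <- function(model, dataset, indices) {
  stopifnot(length(indices) >= 1L)
  se <- 0; sf <- 0; nf <- 0L
  for (f in indices) {
    pr <- .predictCore(model, dataset@coords[, , f])
    se <- se + (pr$energy - dataset@energies[f])^2
    dF <- pr$forces - dataset@forces[, , f]
    sf <- sf + sum(dF * dF)
    nf <- nf + length(dF)
  }
  data.frame(energyRMSE = sqrt(se / length(indices)),
             forceRMSE = sqrt(sf / nf),
             nEval = length(indices))
}

#' Select the kernel length scale on a validation split
#'
#' Trains one model per candidate sigma on the training indices and returns
#' the candidate minimizing the validation force RMSE (ties broken towards
#' the smaller sigma).  Duplicated grid entries are trained once.
#'
#' @param dataset a [MolecularDataset-class].
#' @param splits a split list as returned by [splitDataset()].
#' @param spec a [DescriptorSpec-class].
#' @param sigmaGrid numeric vector of candidate length scales.
#' @param lambda regularization passed to [trainGDML()].
#' @return List with `sigma` (the winner), `reports` (one data.frame row
#'   per unique candidate) and `model` (the winning trained model).
#' @export
selectSigma <- function(dataset, splits, spec, sigmaGrid, lambda = 1e-10) {
  grid <- sort(unique(as.numeric(sigmaGrid)))
  if (length(grid) < 1L) stop("sigma grid is empty")
  models <- vector("list", length(grid))
  rep <- data.frame()
  errs <- character(0)
  for (k in seq_along(grid)) {
    r <- tryCatch({
      m <- trainGDML(dataset, splits$train, spec, sigma = grid[k],
                     lambda = lambda)
      models[[k]] <- m
      cbind(sigma = grid[k],
            evaluateModel(m, dataset, splits$validation))
    }, error = function(e) conditionMessage(e))
    if (is.character(r)) errs <- c(errs, sprintf("sigma=%g: %s", grid[k], r))
    else rep <- rbind(rep, r)
  }
  if (!nrow(rep))
    stop("all sigma candidates failed to train:\n",
         paste(errs, collapse = "\n"))
  best <- which.min(rep$forceRMSE)   # first minimum = smallest sigma on ties
  kbest <- match(rep$sigma[best], grid)
  list(sigma = rep$sigma[best], reports = rep, model = models[[kbest]])
}

#' Save / load a trained model
#'
#' Single-file archive (serialized list with a versioned schema tag)
#' holding the descriptor mask, training coordinates, coefficients,
#' hyperparameters, energy offset and provenance.
#'
#' @param model a [GDMLModel-class].
#' @param path file path.
#' @return `loadGDMLModel` returns the reconstructed [GDMLModel-class];
#'   caches are rebuilt, not stored.
#' @export
saveGDMLModel <- function(model, path) {
  saveRDS(list(schema = "gdmlr-model-1", nAtoms = model@spec@nAtoms,
               activeFeatures = which(model@spec@active), Z = model@Z,
               trainCoords = model@trainCoords, alpha = model@alpha,
               sigma = model@sigma, lambda = model@lambda,
               energyOffset = model@energyOffset,
               provenance = model@provenance),
          path)
  invisible(path)
}

#' @rdname saveGDMLModel
#' @export
loadGDMLModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "gdmlr-model-1"))
    stop("not a gdmlr model archive: ", path)
  spec <- descriptorSpec(obj$nAtoms, active = obj$activeFeatures)
  ds <- .descriptorSet(obj$trainCoords, spec)
  M <- ncol(obj$alpha)
  V <- matrix(0, nrow(ds$D), M)
  for (b in seq_len(M)) V[, b] <- ds$J[[b]] %*% obj$alpha[, b]
  new("GDMLModel", spec = spec, Z = obj$Z, trainCoords = obj$trainCoords,
      alpha = obj$alpha, sigma = obj$sigma, lambda = obj$lambda,
      energyOffset = obj$energyOffset, trainDesc = ds$D, trainV = V,
      provenance = obj$provenance)
}
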