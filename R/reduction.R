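# Automated descriptor reduction: per-feature masking losses, percentile
# thresholding, retraining, the local-cutoff baseline mask, reduction
# curves and removed-set overlap statistics.

#' Per-feature masking loss of a trained model
#'
#' For every active feature n, evaluates the model with that feature zeroed
#' for all configurations (training and query alike) while every model
#' parameter (alpha, sigma, lambda) stays fixed, and accumulates
#'   L_n = sum_i || F_original(x_i) - F_mask_n(x_i) ||^2
#' over the given test configurations.  Small L_n marks a feature the
#' similarity measure barely uses; these are candidates for removal.
#'
#' With `mode = "both"` (default) the feature is removed from the
#' descriptor values and the Jacobian (exact coordinate projection); with
#' `mode = "value"` only the value channel is zeroed while the gradient
#' channel is kept, for sensitivity studies.
#'
#' @param model a [GDMLModel-class].
#' @param dataset a [MolecularDataset-class].
#' @param testIndices nonempty frame indices to accumulate the loss over.
#' @param mode "both" or "value" (see above).
#' @param chunk number of features processed per block (memory control).
#' @return A [FeatureImportance-class].
#' @export
featureImportance <- function(model, dataset, testIndices,
                              mode = c("both", "value"), chunk = 512L) {
  mode <- match.arg(mode)
  stopifnot(is(model, "GDMLModel"), length(testIndices) >= 1L)
  dAct <- nrow(model@trainDesc)
  V <- model@trainV
  losses <- numeric(dAct)
  for (f in testIndices) {
    pc <- .predictCore(model, dataset@coords[, , f])
    Forig <- as.numeric(t(pc$forces))                 # 3N, atom-major
    U <- pc$U                                         # d x M
    tU2 <- t(U * U)                                   # M x d
    tUV <- t(U * V)                                   # M x d
    d2 <- pc$dvec^2
    s <- pc$s
    Jx <- pc$jac
    for (lo in seq(1L, dAct, by = chunk)) {
      cols <- lo:min(lo + chunk - 1L, dAct)
      Dhat <- sqrt(pmax(d2 - tU2[, cols, drop = FALSE], 0))   # M x nc
      Ghat <- .mat52g(Dhat, model@sigma)
      HS <- .mat52h(Dhat, model@sigma) *
        (s - tUV[, cols, drop = FALSE])
      UHS <- U %*% HS                                  # d x nc
      W <- -(V %*% Ghat) - UHS
      Fall <- crossprod(Jx, W)                         # 3N x nc
      if (mode == "both") {
        # row n of w is dropped along with Jacobian row n
        Wnn <- W[cbind(cols, seq_along(cols))]
        Fmask <- Fall - t(Jx[cols, , drop = FALSE] * Wnn)
      } else {
        # value channel only: u_n = 0 but Jacobian rows are kept, so the
        # u-flavoured term loses its n-th row while -g v keeps it
        UHSnn <- UHS[cbind(cols, seq_along(cols))]
        Fmask <- Fall + t(Jx[cols, , drop = FALSE] * UHSnn)
      }
      losses[cols] <- losses[cols] + colSums((Fmask - Forig)^2)
    }
  }
  new("FeatureImportance",
      featureIdx = activeFeatures(model@spec),
      losses = losses, nTest = length(testIndices), mode = mode,
      modelHash = .objectHash(list(model@alpha, model@sigma, model@lambda)))
}

#' Mask features of a trained model without retraining
#'
#' Returns a model whose descriptor drops the given features (value and
#' gradient channel) while keeping the coefficients, length scale and
#' regularization of the input model — the masked predictor the masking
#' loss is defined against.
#'
#' @param model a [GDMLModel-class].
#' @param removeFeatures indices into the full pair map to deactivate.
#' @return A [GDMLModel-class] sharing alpha/sigma/lambda with `model`.
#' @export
maskModel <- function(model, removeFeatures) {
  act <- activeFeatures(model@spec)
  pos <- match(removeFeatures, act)
  if (anyNA(pos)) stop("some features to remove are not active in the model")
  keepPos <- setdiff(seq_along(act), pos)
  if (!length(keepPos)) stop("masking would remove every active feature")
  spec2 <- descriptorSpec(model@spec@nAtoms, active = act[keepPos])
  new("GDMLModel", spec = spec2, Z = model@Z,
      trainCoords = model@trainCoords, alpha = model@alpha,
      sigma = model@sigma, lambda = model@lambda,
      energyOffset = model@energyOffset,
      trainDesc = model@trainDesc[keepPos, , drop = FALSE],
      trainV = model@trainV[keepPos, , drop = FALSE],
      provenance = paste0(model@provenance, "; masked ",
                          length(pos), " features"))
}

#' Split features at a masking-loss percentile
#'
#' Removes the floor(p/100 * n) features with the smallest losses
#' (nearest-rank truncation; ties broken by ascending feature index, lower
#' index removed first).  Removed and kept sets partition the active set,
#' and the removed set at percentile p is a subset of the removed set at
#' any p' > p.
#'
#' @param importance a [FeatureImportance-class].
#' @param p percentile in [0, 100].
#' @return List with sorted integer vectors `removed` and `kept` (indices
#'   into the full pair map).
#' @export
thresholdAtPercentile <- function(importance, p) {
  stopifnot(p >= 0, p <= 100)
  n <- length(importance@losses)
  nRemove <- floor(p / 100 * n)
  ord <- order(importance@losses, importance@featureIdx)
  rem <- importance@featureIdx[ord[seq_len(nRemove)]]
  list(removed = sort(rem),
       kept = sort(setdiff(importance@featureIdx, rem)))
}

#' Reduce the descriptor at a percentile and retrain
#'
#' Drops the features below the p-th masking-loss percentile from the
#' descriptor, retrains from scratch on the same training indices and
#' evaluates on the test split.  By default the length scale is re-selected
#' (descriptor-space distances shrink when features are dropped); pass
#' `resigma = FALSE` to keep the original sigma for strict ablation.
#'
#' @param model the trained reference model.
#' @param dataset a [MolecularDataset-class].
#' @param splits a split list from [splitDataset()].
#' @param p percentile in [0, 100).
#' @param importance optional precomputed [FeatureImportance-class]; when
#'   NULL it is computed on (at most `nImportance` of) the test split.
#' @param nImportance cap on test configurations used for the loss.
#' @param resigma re-select sigma on the reduced descriptor (median
#'   heuristic, or grid search if `sigmaGrid` is given)?
#' @param sigmaGrid optional grid for [selectSigma()].
#' @param lambda regularization for the retrain (defaults to the model's).
#' @param mode masking mode passed to [featureImportance()].
#' @return List: `model` (retrained [GDMLModel-class]), `report`
#'   (test-split RMSEs), `removed`, `kept`, `importance`.
#' @export
reduceAndRetrain <- function(model, dataset, splits, p, importance = NULL,
                             nImportance = 30L, resigma = TRUE,
                             sigmaGrid = NULL, lambda = model@lambda,
                             mode = "both") {
  stopifnot(p >= 0, p < 100)
  if (is.null(importance)) {
    idx <- splits$test
    if (length(idx) > nImportance)
      idx <- idx[round(seq(1, length(idx), length.out = nImportance))]
    importance <- featureImportance(model, dataset, idx, mode = mode)
  }
  th <- thresholdAtPercentile(importance, p)
  if (!length(th$kept)) stop("reduction removed every feature")
  spec2 <- descriptorSpec(model@spec@nAtoms, active = th$kept)
  sigma2 <- if (!resigma) model@sigma
  else if (!is.null(sigmaGrid))
    selectSigma(dataset, splits, spec2, sigmaGrid, lambda)$sigma
  else defaultSigma(dataset, splits$train, spec2)
  m2 <- trainGDML(dataset, splits$train, spec2, sigma = sigma2,
                  lambda = lambda)
  rep <- if (length(splits$test)) evaluateModel(m2, dataset, splits$test)
  else NULL
  list(model = m2, report = rep, removed = th$removed, kept = th$kept,
       importance = importance)
}

#' Local-cutoff baseline mask
#'
#' Keeps feature (i, j) iff its interatomic distance stays at or below
#' `cutoff` in every configuration of the dataset — i.e. removes any
#' feature that exceeds the cutoff in at least one configuration.  This
#' mimics the hard cutoff of local descriptors (typical value 5 A) and is
#' the baseline the importance-reduced mask is compared against.
#'
#' @param dataset a [MolecularDataset-class].
#' @param spec a [DescriptorSpec-class] (the mask is applied on its active
#'   set).
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return A [DescriptorSpec-class] with the surviving features active.
#' @export
buildLocalMask <- function(dataset, spec, cutoff) {
  stopifnot(cutoff > 0)
  st <- featureDistanceStats(dataset, spec)
  keep <- st$feature[st$max <= cutoff]
  if (!length(keep))
    stop("local cutoff ", cutoff, " A removes every feature")
  descriptorSpec(spec@nAtoms, active = keep)
}

#' Accuracy-versus-descriptor-size curve
#'
#' For each training size, trains a reference model on the leading
#' `nTrain` training indices, computes its masking losses once, and then
#' reduces + retrains at every requested percentile.  One row per
#' (percentile, nTrain) combination, in input grid order.
#'
#' @param dataset a [MolecularDataset-class].
#' @param splits a split list from [splitDataset()].
#' @param spec starting [DescriptorSpec-class] (typically global).
#' @param percentiles numeric vector of percentiles in [0, 100).
#' @param nTrainList integer vector of training sizes (each at most
#'   `length(splits$train)`).
#' @param lambda regularization.
#' @param nImportance cap on test configurations for the masking loss.
#' @param resigma re-select sigma per reduced model?
#' @return data.frame with columns `percentile`, `fractionKept`,
#'   `nFeatures`, `energyRMSE`, `forceRMSE`, `nTrain`.
#' @export
reductionCurve <- function(dataset, splits, spec, percentiles, nTrainList,
                           lambda = 1e-10, nImportance = 30L,
                           resigma = TRUE) {
  stopifnot(length(percentiles) >= 1L, length(nTrainList) >= 1L)
  total <- sum(spec@active)
  out <- data.frame()
  for (nTrain in nTrainList) {
    if (nTrain > length(splits$train))
      stop("nTrain = ", nTrain, " exceeds available training indices")
    sp <- splits; sp$train <- splits$train[seq_len(nTrain)]
    m0 <- trainGDML(dataset, sp$train, spec, lambda = lambda)
    idx <- sp$test
    if (length(idx) > nImportance)
      idx <- idx[round(seq(1, length(idx), length.out = nImportance))]
    imp <- featureImportance(m0, dataset, idx)
    for (p in percentiles) {
      if (p == 0) {
        repo <- evaluateModel(m0, dataset, sp$test)
        kept <- length(imp@featureIdx)
      } else {
        rr <- reduceAndRetrain(m0, dataset, sp, p, importance = imp,
                               resigma = resigma, lambda = lambda)
        repo <- rr$report
        kept <- length(rr$kept)
      }
      out <- rbind(out, data.frame(
        percentile = p, fractionKept = kept / total, nFeatures = kept,
        energyRMSE = repo$energyRMSE, forceRMSE = repo$forceRMSE,
        nTrain = nTrain))
    }
  }
  out
}

#' Overlap of removed-feature sets
#'
#' Fraction of features removed by *all* runs, relative to the smallest
#' removed set: |intersection| / min |set|.  Measures the robustness of the
#' reduction against resampling of training sets or test subsets.
#'
#' @param sets list (length >= 2) of integer feature-index vectors.
#' @return List with `fraction` in [0, 1], `intersection` (sorted indices)
#'   and `intersectionSize`.
#' @export
removedSetOverlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (any(lengths(sets) == 0L)) {
    warning("at least one removed set is empty; overlap fraction is 0")
    return(list(fraction = 0, intersection = integer(0),
                intersectionSize = 0L))
  }
  inter <- Reduce(intersect, sets)
  list(fraction = length(inter) / min(lengths(sets)),
       intersection = sort(inter), intersectionSize = length(inter))
}

#' Export a masking-loss table as TSV
#'
#' Writes one row per active feature: feature index, 0-based atom pair,
#' mean interatomic distance (when `stats` is supplied), masking loss and
#' percentile rank.
#'
#' @param importance a [FeatureImportance-class].
#' @param spec the matching [DescriptorSpec-class].
#' @param path output file.
#' @param stats optional [featureDistanceStats()] table for the distance
#'   column.
#' @return `path`, invisibly.
#' @export
exportImportance <- function(importance, spec, path, stats = NULL) {
  pm <- spec@pairs[importance@featureIdx, , drop = FALSE]
  df <- data.frame(feature_index = importance@featureIdx,
                   atom_i = pm[, 1], atom_j = pm[, 2],
                   mean_distance = if (!is.null(stats))
                     stats$mean[match(importance@featureIdx, stats$feature)]
                   else NA_real_,
                   L_n = importance@losses,
                   percentile_rank = 100 *
                     rank(importance@losses, ties.method = "average") /
                     length(importance@losses))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
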