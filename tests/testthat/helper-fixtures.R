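# Shared fixtures: one small thermally sampled chain dataset plus a trained
# reference model, built once per test run.  All randomness is seeded.

fixTopo <- buildToyMolecule("chain", 8, seed = 3)
fixData <- generateDataset(fixTopo, temperature = 350, nSamples = 140,
                           stride = 60, dt = 1, seed = 7)
fixSplit <- splitDataset(fixData, nTrain = 30, nValid = 20, nTest = NA,
                         seed = 1)
fixSpec <- descriptorSpec(8)
fixModel <- trainGDML(fixData, fixSplit$train, fixSpec, lambda = 1e-10)

# Random perturbed configurations drawn near dataset frames (deterministic).
perturbedConfigs <- function(dataset, k, sd = 0.03, seed = 99) {
  n <- nAtoms(dataset)
  idx <- seq_len(min(k, nFrames(dataset)))
  out <- vector("list", length(idx))
  set.seed(seed)
  for (t in seq_along(idx))
    out[[t]] <- dataset@coords[, , idx[t]] + matrix(rnorm(3 * n, sd = sd),
                                                    n, 3)
  out
}

# Central finite-difference gradient of a scalar function of coordinates.
fdGradient <- function(f, xyz, step = 1e-5) {
  g <- matrix(0, nrow(xyz), 3)
  for (i in seq_len(nrow(xyz))) for (s in 1:3) {
    xp <- xyz; xp[i, s] <- xp[i, s] + step
    xm <- xyz; xm[i, s] <- xm[i, s] - step
    g[i, s] <- (f(xp) - f(xm)) / (2 * step)
  }
  g
}

# Independent brute-force force predictor: explicit loop over training
# points, building every kernel quantity from scratch via computeDescriptor
# on the supplied spec.  Used as the oracle for the fast predictor paths and
# the masked-model algebra.
bruteForcePredict <- function(spec, trainCoords, alpha, sigma, xyz) {
  M <- dim(trainCoords)[3]
  dx <- computeDescriptor(xyz, spec)
  Fv <- numeric(3 * nrow(xyz))
  for (b in seq_len(M)) {
    db <- computeDescriptor(trainCoords[, , b], spec)
    u <- dx$values - db$values
    dd <- sqrt(sum(u^2))
    g <- gdmlr:::.mat52g(dd, sigma)
    h <- gdmlr:::.mat52h(dd, sigma)
    vb <- db$jacobian %*% alpha[, b]
    w <- -g * vb - h * sum(u * vb) * u
    Fv <- Fv + as.numeric(crossprod(dx$jacobian, w))
  }
  matrix(Fv, ncol = 3, byrow = TRUE)
}
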