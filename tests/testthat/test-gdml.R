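test_that("Matern 5/2 kernel matches its closed form and scaling law", {
  expect_identical(maternKernel(0, 2), 1)
  # k(sigma; sigma) = (1 + sqrt(5) + 5/3) exp(-sqrt(5)), frozen from a
  # direct high-precision evaluation of the closed form
  expect_equal(maternKernel(3, 3), 0.52399410883182029, tolerance = 1e-14)
  d <- c(0.1, 1, 5)
  expect_equal(maternKernel(d, 2), maternKernel(7 * d, 14), tolerance = 1e-14)
  expect_true(all(diff(maternKernel(seq(0, 10, 0.1), 2)) < 0))
  expect_error(maternKernel(1, 0), "sigma")
  expect_error(maternKernel(-1, 1), ">= 0")
})

test_that("force-kernel matrix is symmetric, PSD, with consistent blocks", {
  set.seed(21)
  cfgs <- perturbedConfigs(fixData, 4)
  arr <- array(unlist(cfgs), c(8, 3, 4))
  K <- assembleForceKernel(arr, fixSpec, sigma = 0.2)
  expect_identical(max(abs(K - t(K))), 0)          # symmetric by construction
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(abs(ev)))
  # two identical configurations: off-diagonal block equals the diagonal one
  arr2 <- array(c(arr[, , 1], arr[, , 1]), c(8, 3, 2))
  K2 <- assembleForceKernel(arr2, fixSpec, sigma = 0.2)
  expect_equal(K2[1:24, 25:48], K2[1:24, 1:24], tolerance = 1e-14)
})

test_that("kernel gradient blocks match finite differences of grad kappa", {
  # block (a,b) of the force kernel is d/dR_b of the analytic
  # grad_{R_a} kappa(x_a, x_b); compare against central differences
  set.seed(22)
  xa <- matrix(rnorm(12, sd = 1.5), 4, 3)
  xb <- xa + matrix(rnorm(12, sd = 0.3), 4, 3)
  spec4 <- descriptorSpec(4)
  sigma <- 0.3
  gradA <- function(xb) {   # grad_{R_a} kappa as a function of R_b
    da <- computeDescriptor(xa, spec4); db <- computeDescriptor(xb, spec4)
    u <- da$values - db$values
    dd <- sqrt(sum(u^2))
    as.numeric(crossprod(da$jacobian, gdmlr:::.mat52g(dd, sigma) * u))
  }
  K <- assembleForceKernel(array(c(xa, xb), c(4, 3, 2)), spec4, sigma)
  blockAB <- K[1:12, 13:24]
  fd <- matrix(0, 12, 12)
  for (col in 1:12) {
    i <- (col - 1) %/% 3 + 1; s <- (col - 1) %% 3 + 1
    xp <- xb; xp[i, s] <- xp[i, s] + 1e-5
    xm <- xb; xm[i, s] <- xm[i, s] - 1e-5
    fd[, col] <- (gradA(xp) - gradA(xm)) / 2e-5
  }
  expect_lt(max(abs(fd - blockAB)) / max(abs(blockAB)), 1e-5)
})

test_that("near-zero regularization training interpolates the training forces", {
  idx <- fixSplit$train[1:20]
  m <- trainGDML(fixData, idx, fixSpec, lambda = 1e-12)
  worst <- 0
  for (f in idx) {
    err <- max(abs(predictForces(m, getConfig(fixData, f)) -
                     fixData@forces[, , f]))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-6)
  rep <- evaluateModel(m, fixData, idx)
  expect_lt(rep$forceRMSE, 1e-6)
})

test_that("one-point training reproduces that point's forces exactly", {
  m1 <- trainGDML(fixData, fixSplit$train[1], fixSpec, lambda = 0)
  f1 <- fixSplit$train[1]
  expect_equal(predictForces(m1, getConfig(fixData, f1)),
               fixData@forces[, , f1], tolerance = 1e-9)
})

test_that("duplicating every training point leaves predictions unchanged", {
  idx <- fixSplit$train[1:10]
  m1 <- trainGDML(fixData, idx, fixSpec, sigma = 0.25, lambda = 1e-12)
  m2 <- trainGDML(fixData, c(idx, idx), fixSpec, sigma = 0.25,
                  lambda = 1e-12)
  for (f in fixSplit$test[1:5]) {
    p1 <- predictForces(m1, getConfig(fixData, f))
    p2 <- predictForces(m2, getConfig(fixData, f))
    expect_lt(max(abs(p1 - p2)) / max(abs(p1)), 1e-8)
  }
})

test_that("fast predictor agrees with the brute-force kernel expansion", {
  for (f in fixSplit$test[1:4]) {
    xyz <- fixData@coords[, , f]
    fast <- predictForces(fixModel, xyz)
    slow <- bruteForcePredict(fixModel@spec, fixModel@trainCoords,
                              fixModel@alpha, fixModel@sigma, xyz)
    expect_equal(fast, slow, tolerance = 1e-10)
  }
})

test_that("predictions respect rigid-motion symmetries", {
  xyz <- fixData@coords[, , fixSplit$test[1]]
  F0 <- predictForces(fixModel, xyz)
  # translation invariance
  Ft <- predictForces(fixModel, sweep(xyz, 2, c(5, -3, 2), `+`))
  expect_lt(max(abs(Ft - F0)), 1e-10)
  # rotation equivariance: F(xQ) = F(x) Q
  set.seed(23)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  Fr <- predictForces(fixModel, xyz %*% Q)
  expect_lt(max(abs(Fr - F0 %*% Q)), 1e-8)
  # energy is invariant
  expect_equal(predictEnergy(fixModel, xyz %*% Q),
               predictEnergy(fixModel, xyz), tolerance = 1e-10)
})

test_that("training-point storage order does not change predictions", {
  idx <- fixSplit$train[1:12]
  m1 <- trainGDML(fixData, idx, fixSpec, sigma = 0.25, lambda = 1e-10)
  m2 <- trainGDML(fixData, rev(idx), fixSpec, sigma = 0.25, lambda = 1e-10)
  xyz <- fixData@coords[, , fixSplit$test[2]]
  expect_equal(predictForces(m1, xyz), predictForces(m2, xyz),
               tolerance = 1e-8)
})

test_that("energy predictor is the exact antiderivative of the force field", {
  cfgs <- perturbedConfigs(fixData, 5)
  for (xyz in cfgs) {
    Fp <- predictForces(fixModel, xyz)
    fdF <- -fdGradient(function(x) predictEnergy(fixModel, x), xyz)
    expect_lt(max(abs(fdF - Fp)) / max(abs(Fp)), 1e-6)
  }
})

test_that("energy offset shifts linearly with the training energies", {
  idx <- fixSplit$train[1:10]
  shifted <- fixData
  shifted@energies <- fixData@energies + 123.456
  m1 <- trainGDML(fixData, idx, fixSpec, sigma = 0.25, lambda = 1e-10)
  m2 <- trainGDML(shifted, idx, fixSpec, sigma = 0.25, lambda = 1e-10)
  xyz <- fixData@coords[, , fixSplit$test[1]]
  expect_equal(predictEnergy(m2, xyz), predictEnergy(m1, xyz) + 123.456,
               tolerance = 1e-8)
})

test_that("harmonic diatomic energies are recovered along the bond", {
  # two beads, one harmonic bond, no nonbonded terms: analytic parabola
  topo <- new("ToyTopology", kind = "chain", Z = c(6L, 6L),
              masses = c(12, 12),
              bonds = cbind(1, 2, r0 = 1.5, k = 200),
              angles = matrix(0, 0, 5), dihedrals = matrix(0, 0, 6),
              charges = c(0, 0), ljEps = 0, ljSigma = 3.3,
              screenLength = 4, nbPairs = matrix(0, 0, 2), seed = 1L,
              cache = new.env())
  rGrid <- seq(1.3, 1.7, length.out = 25)
  coordsA <- array(0, c(2, 3, 25))
  for (k in seq_along(rGrid)) coordsA[2, 1, k] <- rGrid[k]
  en <- 0.5 * 200 * (rGrid - 1.5)^2
  fo <- array(0, c(2, 3, 25))
  fo[1, 1, ] <- 200 * (rGrid - 1.5)   # -dE/dx1
  fo[2, 1, ] <- -200 * (rGrid - 1.5)
  ds <- molecularDataset(c(6L, 6L), coordsA, en, fo)
  m <- trainGDML(ds, seq(1, 25, by = 2), descriptorSpec(2), lambda = 1e-12)
  # predicted energy curve vs the analytic parabola on held-out points
  hold <- seq(2, 24, by = 2)
  pred <- vapply(hold, function(k) predictEnergy(m, coordsA[, , k]),
                 numeric(1))
  # held-out energy RMSE well under 1% of the 4 kcal/mol well depth
  expect_lt(sqrt(mean((pred - en[hold])^2)), 0.01)
})

test_that("sigma selection returns the validation argmin with stable ties", {
  grid <- c(0.1, 0.25, 0.6, 0.25)   # duplicate entry collapses
  sel <- selectSigma(fixData, fixSplit, fixSpec, grid, lambda = 1e-10)
  expect_equal(nrow(sel$reports), 3)
  # exhaustive re-evaluation oracle
  best <- sel$reports$sigma[which.min(sel$reports$forceRMSE)]
  expect_equal(sel$sigma, best)
  expect_s4_class(sel$model, "GDMLModel")
  expect_equal(sel$model@sigma, best)
  # single-value grid returns that value
  one <- selectSigma(fixData, fixSplit, fixSpec, 0.3, lambda = 1e-10)
  expect_equal(one$sigma, 0.3)
})

test_that("RMSE pooling matches a hand-computed single-residual case", {
  # model interpolating 2 frames; perturb one force component by 1 in the
  # reference: pooled force RMSE must be 1/sqrt(nConfigs * 3N) = 1/sqrt(48)
  idx <- fixSplit$train[1:2]
  m <- trainGDML(fixData, idx, fixSpec, lambda = 1e-12)
  pert <- fixData
  pert@forces[1, 1, idx[1]] <- pert@forces[1, 1, idx[1]] + 1
  rep <- evaluateModel(m, pert, idx)
  expect_equal(rep$forceRMSE, 1 / sqrt(2 * 24), tolerance = 1e-4)
  expect_equal(rep$nEval, 2)
  # predictions identical to references give exactly zero
  rep0 <- evaluateModel(m, fixData, idx)
  expect_lt(rep0$forceRMSE, 1e-6)
})

test_that("model archives survive a save/load round trip", {
  path <- withr::local_tempfile(fileext = ".rds")
  saveGDMLModel(fixModel, path)
  back <- loadGDMLModel(path)
  xyz <- fixData@coords[, , fixSplit$test[1]]
  expect_equal(predictForces(back, xyz), predictForces(fixModel, xyz),
               tolerance = 1e-12)
  expect_equal(predictEnergy(back, xyz), predictEnergy(fixModel, xyz),
               tolerance = 1e-12)
})
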