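test_that("atom contributions partition the force prediction exactly", {
  n <- nAtoms(fixData)
  for (f in fixSplit$test[1:3]) {
    cfg <- getConfig(fixData, f)
    F0 <- predictForces(fixModel, cfg)
    tot <- matrix(0, n, 3)
    for (k in 0:(n - 1)) tot <- tot + atomContribution(fixModel, cfg, k)
    expect_lt(max(abs(tot - F0)) / max(abs(F0)), 1e-10)
  }
  expect_error(atomContribution(fixModel, getConfig(fixData, 1), n), "atom index")
})

test_that("single-atom restriction matches a hand-restricted coefficient sum", {
  # zero out all coefficient components except atom k's in a copy of the
  # model: predictions of that crippled model ARE the restricted sum
  k <- 3L
  cols <- 3L * k + 1:3
  restricted <- fixModel
  keepRows <- rep(FALSE, nrow(fixModel@alpha)); keepRows[cols] <- TRUE
  restricted@alpha[!keepRows, ] <- 0
  ds <- gdmlr:::.descriptorSet(restricted@trainCoords, restricted@spec)
  for (b in seq_len(ncol(restricted@alpha)))
    restricted@trainV[, b] <- ds$J[[b]] %*% restricted@alpha[, b]
  cfg <- getConfig(fixData, fixSplit$test[1])
  expect_equal(atomContribution(fixModel, cfg, k),
               predictForces(restricted, cfg), tolerance = 1e-12)
})

test_that("interaction maps agree with explicit per-configuration loops", {
  idx <- fixSplit$test[1:3]
  im <- interactionMap(fixModel, fixData, idx)
  n <- nAtoms(fixData)
  # brute force through atomContribution per configuration
  acc <- matrix(0, n, n)
  for (f in idx) {
    cfg <- getConfig(fixData, f)
    for (k in 0:(n - 1)) {
      Fk <- atomContribution(fixModel, cfg, k)
      acc[k + 1, ] <- acc[k + 1, ] + sqrt(rowSums(Fk^2))
    }
  }
  expect_equal(im$contributions, acc / length(idx), tolerance = 1e-10)
  # nonnegative entries; normalization attains [0, 1]
  expect_true(all(im$contributions >= 0))
  expect_equal(range(im$normalized), c(0, 1))
  # order invariance of the average
  imR <- interactionMap(fixModel, fixData, rev(idx))
  expect_equal(im$contributions, imR$contributions, tolerance = 1e-12)
  # single-configuration average equals the single map
  im1 <- interactionMap(fixModel, fixData, idx[1])
  expect_equal(im1$nConfigs, 1L)
})

test_that("feature channels partition the force prediction exactly", {
  for (f in fixSplit$test[1:3]) {
    xyz <- fixData@coords[, , f]
    F0 <- as.numeric(t(predictForces(fixModel, xyz)))
    chan <- gdmlr:::.featureChannelForces(fixModel, xyz)  # d x 3N
    expect_lt(max(abs(colSums(chan) - F0)) / max(abs(F0)), 1e-10)
  }
  fc <- featureContributions(fixModel, fixData, fixSplit$test[1:3])
  expect_equal(nrow(fc), nFeatures(fixSpec))
  expect_true(all(fc$meanContribution >= 0))
})

test_that("two-feature toy model channels match a symbolic expansion", {
  # M = 1 training point, 2 active features: expand the chain rule by hand
  spec2 <- descriptorSpec(3, active = c(1L, 2L))
  idx <- fixSplit$train[1]
  xyzT <- fixData@coords[1:3, , idx]
  dsT <- molecularDataset(c(6L, 6L, 6L),
                          array(xyzT, c(3, 3, 1)), 0, array(0, c(3, 3, 1)))
  m <- new("GDMLModel", spec = spec2, Z = c(6L, 6L, 6L),
           trainCoords = array(xyzT, c(3, 3, 1)),
           alpha = matrix(rnorm(9, sd = 0.1), 9, 1), sigma = 0.3,
           lambda = 0, energyOffset = 0,
           trainDesc = matrix(computeDescriptor(xyzT, spec2)$values, 2, 1),
           trainV = matrix(0, 2, 1), provenance = "hand-built")
  m@trainV[, 1] <- computeDescriptor(xyzT, spec2)$jacobian %*% m@alpha[, 1]
  xyz <- xyzT + 0.1
  xyz[1, 2] <- xyz[1, 2] + 0.2
  dq <- computeDescriptor(xyz, spec2)
  u <- dq$values - m@trainDesc[, 1]
  dd <- sqrt(sum(u^2))
  g <- gdmlr:::.mat52g(dd, 0.3); h <- gdmlr:::.mat52h(dd, 0.3)
  w <- -g * m@trainV[, 1] - h * sum(u * m@trainV[, 1]) * u
  chanHand <- rbind(w[1] * dq$jacobian[1, ], w[2] * dq$jacobian[2, ])
  chan <- gdmlr:::.featureChannelForces(m, xyz)
  expect_equal(chan, chanHand, tolerance = 1e-12)
  # masked-out features contribute exactly zero rows
  masked <- maskModel(m, 2L)
  chanM <- gdmlr:::.featureChannelForces(masked, xyz)
  expect_equal(nrow(chanM), 1L)
})

test_that("power-law channels are classified by slope and r-squared", {
  set.seed(31)
  r <- matrix(runif(200, 2, 12), 200, 3)
  contrib <- cbind(5 * r[, 1]^-2,                     # exact inverse square
                   2 * r[, 2]^-1.3,                   # shallower power law
                   exp(rnorm(200)))                   # distance-independent
  cl <- classifyFeatures(r, contrib)
  expect_equal(cl$slope[1], -2, tolerance = 1e-6)
  expect_gt(cl$r2[1], 0.999999)
  expect_equal(cl$class[1], "linear")
  expect_equal(cl$slope[2], -1.3, tolerance = 1e-6)
  expect_lt(cl$r2[3], 0.3)
  expect_equal(cl$class[3], "stochastic")
  # nonpositive contributions are excluded; sparse features are skipped
  contrib[, 1][1:198] <- -1
  expect_warning(cl2 <- classifyFeatures(r, contrib), "fewer than 3")
  expect_true(is.na(cl2$slope[1]))
})

test_that("short/long decomposition counts sum and obey both criteria", {
  st <- featureDistanceStats(fixData, fixSpec)
  sl <- shortLongDecomposition(st, fixSpec, cutoff = 5)
  expect_equal(sl$nShort + sl$nLong, nFeatures(fixSpec))
  # counting oracle
  expect_equal(sl$nShort, sum(st$max < 5))
  slMean <- shortLongDecomposition(st, fixSpec, cutoff = 5,
                                   criterion = "mean")
  expect_equal(slMean$nShort, sum(st$mean < 5))
  expect_gte(slMean$nShort, sl$nShort)   # mean criterion is more permissive
  # all features short when everything sits at 3 A
  c1 <- array(0, c(2, 3, 1)); c1[2, 1, 1] <- 3
  dsA <- molecularDataset(c(6L, 6L), c1, 0, array(0, c(2, 3, 1)))
  stA <- featureDistanceStats(dsA, descriptorSpec(2))
  slA <- shortLongDecomposition(stA, descriptorSpec(2), 5)
  expect_equal(slA$nShort, 1L)
  expect_equal(slA$nLong, 0L)
})

test_that("scaling fits recover exact lines and flag quadratic growth", {
  pts <- data.frame(nAtoms = c(10, 16, 24, 32), nKept = 10 * c(10, 16, 24, 32))
  fit <- scalingFit(pts)
  expect_equal(fit$slope, 10, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$points$quadratic, c(45, 120, 276, 496))
  # quadratic points fitted linearly cannot reach r2 = 1
  ptsQ <- data.frame(nAtoms = c(10, 16, 24, 32),
                     nKept = c(45, 120, 276, 496))
  expect_lt(scalingFit(ptsQ)$r2, 1)
  expect_error(scalingFit(data.frame(nAtoms = c(5, 5), nKept = c(1, 2))),
               "distinct")
})

test_that("gyration radius matches the pair-distance identity", {
  # symmetric dimer: two unit-mass atoms at +/-1 on an axis
  cfg <- atomicConfiguration(c(6, 6), rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(gyrationRadius(cfg), 1)
  # identity oracle: Rg^2 = (1/2) sum_ij r_ij^2 / n^2 for equal weights
  set.seed(33)
  xyz <- matrix(rnorm(60, sd = 3), 20, 3)
  rg <- gyrationRadius(xyz)
  rg2 <- sum(dist(xyz)^2) / 20^2   # dist gives each pair once
  expect_equal(rg^2, rg2, tolerance = 1e-12)
  # mass weighting shifts the centroid towards heavy atoms
  cfgH <- atomicConfiguration(c(1, 8), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_lt(abs(gyrationRadius(cfgH, massWeighted = TRUE) -
                  sqrt(sum(atomicMass(c(1, 8)) *
                             (c(0, 1) - 15.999 / 17.007)^2) / 17.007)), 1e-6)
})
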