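test_that("toy topologies have the right term combinatorics", {
  ch <- buildToyMolecule("chain", 10, seed = 1)
  expect_equal(nrow(ch@bonds), 9)
  expect_equal(nrow(ch@angles), 8)
  expect_equal(nrow(ch@dihedrals), 7)
  rg <- buildToyMolecule("ring", 10, seed = 1)
  expect_equal(nrow(rg@bonds), 10)
  expect_equal(nrow(rg@angles), 10)
  expect_equal(nrow(rg@dihedrals), 10)
  dm <- buildToyMolecule("dimer", 12, seed = 1)
  expect_equal(nrow(dm@bonds), 10)        # two 6-bead fragments
  # nonbonded pairs exclude 1-2 and 1-3 neighbours
  nb <- ch@nbPairs
  for (r in seq_len(nrow(nb)))
    expect_gte(abs(nb[r, 1] - nb[r, 2]), 3)
  # deterministic given the seed; different seeds differ
  ch2 <- buildToyMolecule("chain", 10, seed = 1)
  expect_identical(ch@bonds, ch2@bonds)
  expect_identical(ch@charges, ch2@charges)
  expect_false(identical(ch@charges,
                         buildToyMolecule("chain", 10, seed = 2)@charges))
  expect_error(buildToyMolecule("chain", 3), "at least 4")
  expect_error(buildToyMolecule("dimer", 7), "even")
})

test_that("toy forces are the exact negative gradient of the energy", {
  set.seed(41)
  for (kind in c("chain", "ring", "dimer")) {
    topo <- buildToyMolecule(kind, if (kind == "dimer") 8 else 7, seed = 2)
    n <- length(atomicNumbers(topo))
    xyz <- coords(initialConfiguration(topo)) +
      matrix(rnorm(3 * n, sd = 0.07), n, 3)
    ef <- toyEnergyForces(topo, xyz)
    fd <- -fdGradient(function(x) toyEnergyForces(topo, x)$energy, xyz)
    expect_lt(max(abs(fd - ef$forces)) / max(abs(ef$forces)), 1e-7)
  }
})

test_that("a relaxed diatomic bond has zero energy and forces", {
  topo <- new("ToyTopology", kind = "chain", Z = c(6L, 6L),
              masses = c(12, 12), bonds = cbind(1, 2, r0 = 1.5, k = 300),
              angles = matrix(0, 0, 5), dihedrals = matrix(0, 0, 6),
              charges = c(0, 0), ljEps = 0, ljSigma = 3.3, screenLength = 4,
              nbPairs = matrix(0, 0, 2), seed = 1L, cache = new.env())
  ef <- toyEnergyForces(topo, rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(ef$energy, 0)
  expect_equal(max(abs(ef$forces)), 0)
})

test_that("screened Coulomb reduces to the bare law at long screening", {
  q <- 0.3; r <- 2.5
  topo <- new("ToyTopology", kind = "dimer", Z = c(6L, 6L),
              masses = c(12, 12), bonds = matrix(0, 0, 4),
              angles = matrix(0, 0, 5), dihedrals = matrix(0, 0, 6),
              charges = c(q, -q), ljEps = 0, ljSigma = 3.3,
              screenLength = 1e9, nbPairs = cbind(1, 2), seed = 1L,
              cache = new.env())
  ef <- toyEnergyForces(topo, rbind(c(0, 0, 0), c(r, 0, 0)))
  expect_equal(ef$energy, -gdmlrConstants$coulomb * q^2 / r,
               tolerance = 1e-8)
})

test_that("thermal sampling is seeded, labelled and near the target temperature", {
  topo <- buildToyMolecule("chain", 10, seed = 5)
  d1 <- generateDataset(topo, temperature = 300, nSamples = 20, stride = 40,
                        dt = 1, seed = 11)
  d2 <- generateDataset(topo, temperature = 300, nSamples = 20, stride = 40,
                        dt = 1, seed = 11)
  expect_identical(coords(d1), coords(d2))     # bit-reproducible
  expect_identical(energies(d1), energies(d2))
  expect_equal(nFrames(d1), 20L)
  # labels are the analytic PES values
  ef <- toyEnergyForces(topo, d1@coords[, , 7])
  expect_equal(energies(d1)[7], ef$energy, tolerance = 1e-12)
  expect_equal(forces(d1)[, , 7], ef$forces, tolerance = 1e-12)
  # single-sample request works
  expect_equal(nFrames(generateDataset(topo, nSamples = 1, stride = 10,
                                       seed = 1)), 1L)
  # long-run kinetic temperature within 5% of the 300 K target
  tr <- runMD(topo, initialConfiguration(topo), mode = "langevin", dt = 1,
              nSteps = 30000, temperature = 300, friction = 0.02,
              seed = 13, sampleEvery = 50)
  Tk <- kineticTemperature(tr)
  expect_lt(abs(mean(Tk[-(1:100)]) - 300) / 300, 0.05)
})

test_that("NVE dynamics conserve the toy-potential energy", {
  topo <- buildToyMolecule("chain", 10, seed = 5)
  tr <- runMD(topo, initialConfiguration(topo), mode = "nve", dt = 0.5,
              nSteps = 10000, temperature = 300, seed = 2, sampleEvery = 20)
  et <- tr@epot + tr@ekin
  drift <- abs(unname(coef(lm(et ~ tr@times))[2])) * 1000  # kcal/mol per ps
  expect_lt(drift, 1e-3)
  # a well-behaved trajectory triggers no instability events
  expect_equal(nrow(detectInstability(tr, topo)), 0)
})

test_that("zero forces and zero velocities give a static trajectory", {
  still <- function(xyz) list(energy = 0, forces = matrix(0, nrow(xyz), 3))
  x0 <- coords(initialConfiguration(buildToyMolecule("chain", 6, seed = 1)))
  tr <- runMD(still, x0, Z = rep(6L, 6), mode = "nve", dt = 1,
              nSteps = 200, temperature = 0, seed = 1, sampleEvery = 50)
  for (f in seq_len(nFrames(tr)))
    expect_identical(tr@coords[, , f], unname(x0))
})

test_that("steering pulls the chain towards larger gyration radii", {
  topo <- buildToyMolecule("chain", 10, seed = 5)
  cfg <- initialConfiguration(topo)
  ctrl <- runMD(topo, cfg, mode = "langevin", dt = 1, nSteps = 8000,
                temperature = 300, friction = 0.02, seed = 3,
                sampleEvery = 40)
  pull <- runMD(topo, cfg, mode = "langevin", dt = 1, nSteps = 8000,
                temperature = 300, friction = 0.02, seed = 3,
                sampleEvery = 40,
                externalForce = list(atoms = c(1, 10), pN = 400))
  lastQ <- function(x) mean(utils::tail(x@rg, length(x@rg) %/% 4))
  expect_gt(lastQ(pull), lastQ(ctrl))
  # fixed-axis variant runs and logs no events
  pf <- runMD(topo, cfg, mode = "langevin", dt = 1, nSteps = 2000,
              temperature = 300, friction = 0.02, seed = 3,
              externalForce = list(atoms = c(1, 10), pN = 100),
              fixedAxis = TRUE)
  expect_equal(nrow(pf@events), 0)
})

test_that("instability detection flags planted clashes and fragmentation", {
  topo <- buildToyMolecule("chain", 6, seed = 1)
  good <- coords(initialConfiguration(topo))
  # park atom 6 within 0.5 A of (nonbonded) atom 3 while its bond to atom 5
  # stays below the fragmentation threshold
  clash <- good; clash[6, ] <- good[3, ] + c(0.5, 0, 0)
  frag <- good; frag[6, ] <- good[5, ] + c(15, 0, 0)      # bond at ~10x r0
  mk <- function(frames) new("MDTrajectory", Z = rep(6L, 6),
    times = seq_along(frames), coords = array(unlist(frames),
                                              c(6, 3, length(frames))),
    epot = numeric(length(frames)), ekin = numeric(length(frames)),
    rg = numeric(length(frames)), dt = 1, mode = "nve",
    temperature = NA_real_, friction = NA_real_, seed = 1L,
    events = data.frame(), finalVelocities = matrix(0, 6, 3))
  evC <- detectInstability(mk(list(good, clash)), topo)
  expect_equal(nrow(evC), 1)
  expect_equal(evC$type, "clash")
  expect_equal(evC$frame, 2L)
  evF <- detectInstability(mk(list(frag)), topo)
  expect_equal(evF$type, "fragmentation")
  expect_equal(nrow(detectInstability(mk(list(good)), topo)), 0)
})

test_that("trajectories export as extended XYZ with an observable log", {
  topo <- buildToyMolecule("chain", 6, seed = 1)
  tr <- runMD(topo, initialConfiguration(topo), mode = "langevin", dt = 1,
              nSteps = 500, temperature = 300, friction = 0.02, seed = 4,
              sampleEvery = 100)
  path <- withr::local_tempfile(fileext = ".xyz")
  writeTrajectory(tr, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".tsv")))
  obs <- read.delim(paste0(path, ".tsv"))
  expect_equal(nrow(obs), nFrames(tr))
  expect_true(all(c("time", "epot", "ekin", "etot", "temperature", "rg")
                  %in% names(obs)))
})
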