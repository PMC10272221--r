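# Molecular dynamics: velocity Verlet (NVE) and Langevin BAOAB
# integration, optional constant-force steering, thermal dataset
# generation from the toy potentials, and trajectory instability checks.
#
# Units: positions A, velocities A/fs, time fs, energies kcal/mol, masses
# amu.  Accelerations use a = gdmlrConstants$accel * F / m (A/fs^2), and
# kinetic energy is sum(m v^2) / (2 * accel) so that equipartition holds
# in kcal/mol.

# Uniform force-provider interface: returns function(xyz) ->
# list(energy, forces).  `energy = NA` is permitted for providers that are
# queried force-only.
.forceFun <- function(provider) {
  if (is(provider, "ToyTopology"))
    function(xyz) toyEnergyForces(provider, xyz)
  else if (is(provider, "GDMLModel"))
    function(xyz) {
      pc <- .predictCore(provider, xyz)
      list(energy = pc$energy, forces = pc$forces)
    }
  else if (is.function(provider)) provider
  else stop("force provider must be a ToyTopology, GDMLModel or function")
}

.kineticEnergy <- function(v, masses) {
  sum(masses * rowSums(v * v)) / (2 * gdmlrConstants$accel)
}

#' Maxwell-Boltzmann velocities
#'
#' @param masses bead masses, amu.
#' @param temperature target temperature, K (0 gives zero velocities).
#' @return n x 3 matrix of velocities, A/fs.
#' @export
boltzmannVelocities <- function(masses, temperature) {
  n <- length(masses)
  if (temperature <= 0) return(matrix(0, n, 3))
  sd <- sqrt(gdmlrConstants$accel * gdmlrConstants$kB * temperature / masses)
  matrix(stats::rnorm(3 * n), n, 3) * sd
}

#' Run molecular dynamics with any force provider
#'
#' Integrates Newtonian (`mode = "nve"`, velocity Verlet) or Langevin
#' dynamics (`mode = "langevin"`, BAOAB splitting) under a
#' [ToyTopology-class] potential, a trained [GDMLModel-class], or an
#' arbitrary `function(xyz) list(energy, forces)`.  Initial velocities are
#' drawn from the Boltzmann distribution at `temperature` (zero when
#' `temperature = 0`).
#'
#' Steered mode: `externalForce = list(atoms = c(i, j), pN = f)` adds a
#' constant force of magnitude f (piconewton) to atoms i and j (1-based),
#' pushing them apart along their connecting line; the direction is
#' re-evaluated every step unless `fixedAxis = TRUE` freezes the initial
#' axis.  An external force does work on the system, so NVE energy is not
#' conserved in steered runs.
#'
#' Integration aborts (with an event logged) if coordinates go non-finite.
#'
#' @param provider force provider (see above).
#' @param config starting [AtomicConfiguration-class] or n x 3 matrix.
#' @param masses bead masses in amu; defaults to standard atomic masses of
#'   `Z` (required for a bare-matrix `config` without `Z`).
#' @param Z atomic numbers (defaulted from `config` when possible).
#' @param mode "nve" or "langevin".
#' @param dt timestep, fs.
#' @param nSteps number of integration steps.
#' @param temperature initial-velocity / thermostat temperature, K.
#' @param friction Langevin friction, fs^-1.
#' @param externalForce optional steering spec (see above).
#' @param fixedAxis freeze the pull axis at its initial direction?
#' @param seed integer seed (initial velocities and thermostat noise).
#' @param sampleEvery record every this-many steps.
#' @param massWeightedRg mass-weight the recorded gyration radius?
#' @return An [MDTrajectory-class].
#' @export
runMD <- function(provider, config, masses = NULL, Z = NULL,
                  mode = c("nve", "langevin"), dt = 0.5, nSteps = 1000L,
                  temperature = 300, friction = 0.01,
                  externalForce = NULL, fixedAxis = FALSE, seed = 1L,
                  sampleEvery = 10L, massWeightedRg = FALSE) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("dt must be > 0")
  xyz <- .asXYZ(config)
  if (is.null(Z)) Z <- if (is(config, "AtomicConfiguration")) config@Z
  else if (is(provider, "ToyTopology") || is(provider, "GDMLModel"))
    provider@Z else rep(6L, nrow(xyz))
  if (is.null(masses)) masses <- if (is(provider, "ToyTopology"))
    provider@masses else atomicMass(Z)
  n <- nrow(xyz)
  ff <- .forceFun(provider)
  acc <- gdmlrConstants$accel
  pull <- NULL
  if (!is.null(externalForce)) {
    stopifnot(length(externalForce$atoms) == 2L)
    fmag <- externalForce$pN / gdmlrConstants$pN_per_kcalmolA
    ia <- externalForce$atoms[1]; ib <- externalForce$atoms[2]
    axis0 <- xyz[ia, ] - xyz[ib, ]; axis0 <- axis0 / sqrt(sum(axis0^2))
    pull <- function(x) {
      u <- if (fixedAxis) axis0 else {
        d <- x[ia, ] - x[ib, ]; d / sqrt(sum(d^2))
      }
      out <- matrix(0, n, 3)
      out[ia, ] <- fmag * u
      out[ib, ] <- -fmag * u
      out
    }
  }
  nSamp <- floor(nSteps / sampleEvery)
  times <- numeric(nSamp); epot <- numeric(nSamp); ekin <- numeric(nSamp)
  rgs <- numeric(nSamp)
  coordsOut <- array(NA_real_, c(n, 3, nSamp))
  events <- data.frame(step = integer(0), time = numeric(0),
                       type = character(0), detail = character(0))
  .withSeed(seed, {
    v <- boltzmannVelocities(masses, temperature)
    fe <- ff(xyz)
    Ftot <- fe$forces + if (is.null(pull)) 0 else pull(xyz)
    a <- acc * Ftot / masses
    if (mode == "langevin") {
      c1 <- exp(-friction * dt)
      c2 <- sqrt((1 - c1^2) * acc * gdmlrConstants$kB * temperature / masses)
    }
    si <- 0L
    for (step in seq_len(nSteps)) {
      if (mode == "nve") {
        v <- v + 0.5 * dt * a
        xyz <- xyz + dt * v
      } else {
        v <- v + 0.5 * dt * a
        xyz <- xyz + 0.5 * dt * v
        v <- c1 * v + c2 * matrix(stats::rnorm(3 * n), n, 3)
        xyz <- xyz + 0.5 * dt * v
      }
      if (any(!is.finite(xyz))) {
        events <- rbind(events, data.frame(
          step = step, time = step * dt, type = "abort",
          detail = "non-finite coordinates; integration stopped"))
        break
      }
      fe <- ff(xyz)
      Ftot <- fe$forces + if (is.null(pull)) 0 else pull(xyz)
      a <- acc * Ftot / masses
      v <- v + 0.5 * dt * a
      if (step %% sampleEvery == 0L) {
        si <- si + 1L
        times[si] <- step * dt
        epot[si] <- fe$energy
        ekin[si] <- .kineticEnergy(v, masses)
        rgs[si] <- gyrationRadius(xyz, massWeighted = massWeightedRg, Z = Z)
        coordsOut[, , si] <- xyz
      }
    }
    new("MDTrajectory", Z = as.integer(Z), times = times[seq_len(si)],
        coords = coordsOut[, , seq_len(si), drop = FALSE],
        epot = epot[seq_len(si)], ekin = ekin[seq_len(si)],
        rg = rgs[seq_len(si)], dt = dt, mode = mode,
        temperature = if (mode == "langevin") temperature else NA_real_,
        friction = if (mode == "langevin") friction else NA_real_,
        seed = as.integer(seed), events = events, finalVelocities = v)
  })
}

#' Instantaneous kinetic temperature series of a trajectory
#'
#' @param trajectory an [MDTrajectory-class].
#' @param masses bead masses (amu); defaults to standard atomic masses.
#' @return Numeric vector of temperatures (K), one per sample.
#' @export
kineticTemperature <- function(trajectory, masses = NULL) {
  if (is.null(masses)) masses <- atomicMass(trajectory@Z)
  n <- length(trajectory@Z)
  2 * trajectory@ekin / (3 * n * gdmlrConstants$kB)
}

#' Generate a labelled dataset by thermal sampling of a toy potential
#'
#' Runs Langevin dynamics on the analytic toy potential from its reference
#' geometry, discards an equilibration stretch, then records one frame
#' every `stride` steps, labelling each with the exact analytic energy and
#' forces.  Bit-reproducible for a fixed seed.
#'
#' @param topology a [ToyTopology-class].
#' @param temperature sampling temperature, K.
#' @param nSamples number of labelled frames to collect (>= 1).
#' @param stride steps between recorded frames.
#' @param dt timestep, fs.
#' @param seed integer seed.
#' @param friction Langevin friction, fs^-1.
#' @param equilSteps equilibration steps discarded before sampling.
#' @return A [MolecularDataset-class].
#' @export
generateDataset <- function(topology, temperature = 300, nSamples = 100L,
                            stride = 100L, dt = 1, seed = 1L,
                            friction = 0.02, equilSteps = 2000L) {
  stopifnot(nSamples >= 1L)
  nTot <- equilSteps + nSamples * stride
  traj <- runMD(topology, initialConfiguration(topology),
                mode = "langevin", dt = dt, nSteps = nTot,
                temperature = temperature, friction = friction,
                seed = seed, sampleEvery = stride)
  if (nrow(traj@events))
    stop("unstable sampling dynamics (", traj@events$detail[1],
         "); reduce dt")
  keep <- which(traj@times > equilSteps * dt)
  if (length(keep) < nSamples) keep <- utils::tail(seq_along(traj@times),
                                                   nSamples)
  keep <- utils::tail(keep, nSamples)
  n <- length(topology@Z)
  coords <- traj@coords[, , keep, drop = FALSE]
  energies <- numeric(length(keep))
  forcesA <- array(0, dim(coords))
  for (s in seq_along(keep)) {
    ef <- toyEnergyForces(topology, coords[, , s])
    energies[s] <- ef$energy
    forcesA[, , s] <- ef$forces
  }
  molecularDataset(topology@Z, coords, energies, forcesA,
                   name = sprintf("toy-%s-%d", topology@kind, n),
                   provenance = sprintf(
                     paste0("Langevin sampling: T=%g K, dt=%g fs, ",
                            "stride=%d, friction=%g /fs, seed=%d, ",
                            "topology seed=%d"),
                     temperature, dt, stride, friction, as.integer(seed),
                     topology@seed))
}

#' Scan a trajectory for steric clashes and fragmentation
#'
#' A clash event is any nonbonded pair (pairs not joined by a bond) closer
#' than `clashCutoff`; a fragmentation event is any bonded pair stretched
#' beyond `fragmentFactor` times its equilibrium length.  Events are
#' time-stamped per sampled frame.
#'
#' @param trajectory an [MDTrajectory-class].
#' @param topology the [ToyTopology-class] defining bonds.
#' @param clashCutoff clash distance, A (default 0.7).
#' @param fragmentFactor bond-stretch factor (default 2.5).
#' @return data.frame of events: `frame`, `time`, `type`, `i`, `j`,
#'   `distance`; zero rows for a clean trajectory.
#' @export
detectInstability <- function(trajectory, topology, clashCutoff = 0.7,
                              fragmentFactor = 2.5) {
  stopifnot(nFrames(trajectory) >= 1L)
  n <- length(topology@Z)
  bonds <- topology@bonds
  bondKey <- bonds[, 1] * (n + 1) + bonds[, 2]
  bondKey <- c(bondKey, bonds[, 2] * (n + 1) + bonds[, 1])
  pm <- pairIndexMap(n) + 1L
  nonb <- pm[!(pm[, 1] * (n + 1) + pm[, 2]) %in% bondKey, , drop = FALSE]
  ev <- list()
  for (f in seq_len(nFrames(trajectory))) {
    xyz <- trajectory@coords[, , f]
    if (nrow(nonb)) {
      dv <- xyz[nonb[, 1], , drop = FALSE] - xyz[nonb[, 2], , drop = FALSE]
      r <- sqrt(rowSums(dv * dv))
      hit <- which(r < clashCutoff)
      for (hh in hit)
        ev[[length(ev) + 1L]] <- data.frame(
          frame = f, time = trajectory@times[f], type = "clash",
          i = nonb[hh, 1], j = nonb[hh, 2], distance = r[hh])
    }
    if (nrow(bonds)) {
      dv <- xyz[bonds[, 1], , drop = FALSE] - xyz[bonds[, 2], , drop = FALSE]
      r <- sqrt(rowSums(dv * dv))
      hit <- which(r > fragmentFactor * bonds[, 3])
      for (hh in hit)
        ev[[length(ev) + 1L]] <- data.frame(
          frame = f, time = trajectory@times[f], type = "fragmentation",
          i = bonds[hh, 1], j = bonds[hh, 2], distance = r[hh])
    }
  }
  if (length(ev)) do.call(rbind, ev)
  else data.frame(frame = integer(0), time = numeric(0),
                  type = character(0), i = integer(0), j = integer(0),
                  distance = numeric(0))
}

#' Write a trajectory as extended XYZ plus a TSV observable log
#'
#' Frames go to `<path>` in the extended-XYZ dialect (comment line carries
#' time, energies, thermostat record and seed); observables (time, epot,
#' ekin, etot, temperature, Rg) go to `<path>.tsv`.
#'
#' @param trajectory an [MDTrajectory-class].
#' @param path output xyz path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  n <- length(trajectory@Z)
  sym <- .elementSymbols[trajectory@Z]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(trajectory))) {
    xyz <- trajectory@coords[, , f]
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Properties=species:S:1:pos:R:3 time=%.6f epot=%.10g ekin=%.10g mode=%s temperature=%g friction=%g seed=%d',
      trajectory@times[f], trajectory@epot[f], trajectory@ekin[f],
      trajectory@mode, trajectory@temperature, trajectory@friction,
      trajectory@seed), con)
    writeLines(sprintf("%-3s %.10g %.10g %.10g",
                       sym, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  obs <- data.frame(time = trajectory@times, epot = trajectory@epot,
                    ekin = trajectory@ekin,
                    etot = trajectory@epot + trajectory@ekin,
                    temperature = kineticTemperature(trajectory),
                    rg = trajectory@rg)
  utils::write.table(obs, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
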