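# Analytic toy molecular potentials with exact forces.  These emulate the
# statistical structure of thermally sampled flexible-molecule datasets:
# stiff short-range bonded fluctuations (bonds, angles, torsions) plus
# genuinely long-range nonbonded interactions (Lennard-Jones and
# screened-Coulomb between alternating partial charges), with energies and
# forces available in closed form.

#' Build a toy molecular topology
#'
#' Three archetypes:
#' \describe{
#'   \item{chain}{a flexible bead chain (peptide / fatty-acid analogue) with
#'     alternating partial charges, so that distant beads interact through a
#'     screened power law;}
#'   \item{ring}{the cyclic variant;}
#'   \item{dimer}{two covalent fragments bound only by nonbonded terms
#'     (base-pair / host-guest analogue).}
#' }
#' Beads are carbon-like (Z = 6, m = 12.011 amu).  Bonded terms: harmonic
#' bonds (r0 ~ 1.52 A, k = 300 kcal mol^-1 A^-2), harmonic angles
#' (114 deg, 60 kcal mol^-1 rad^-2), threefold cosine torsions
#' (1.4 kcal/mol).  Nonbonded (pairs separated by 3+ bonds): Lennard-Jones
#' (eps = 0.12 kcal/mol, sigma = 3.3 A) and screened Coulomb
#' (q = +/-0.25 e alternating, screening length 4 A).  The seed jitters
#' equilibrium bond lengths (+/-1%) and charge magnitudes (+/-5%) so
#' distinct seeds give distinct but equivalent molecules; the same
#' (kind, nAtoms, seed) is bit-reproducible.
#'
#' @param kind "chain", "ring" or "dimer".
#' @param nAtoms bead count (>= 4 for chain/ring, >= 6 and even for dimer).
#' @param seed integer seed for the parameter jitter.
#' @return A [ToyTopology-class].
#' @examples
#' buildToyMolecule("chain", 10, seed = 1)  # 9 bonds, 8 angles, 7 dihedrals
#' @export
buildToyMolecule <- function(kind = c("chain", "ring", "dimer"), nAtoms,
                             seed = 1L) {
  kind <- match.arg(kind)
  nAtoms <- as.integer(nAtoms)
  if (kind %in% c("chain", "ring") && nAtoms < 4L)
    stop(kind, " topology needs at least 4 beads")
  if (kind == "dimer" && (nAtoms < 6L || nAtoms %% 2L != 0L))
    stop("dimer topology needs an even bead count >= 6")
  .withSeed(seed, {
    mkFrag <- function(idx, cyclic = FALSE, chargeSign0 = 1) {
      n <- length(idx)
      bi <- if (cyclic) cbind(idx, idx[c(2:n, 1)]) else
        cbind(idx[-n], idx[-1])
      nb <- nrow(bi)
      bonds <- cbind(bi, r0 = 1.52 * (1 + stats::runif(nb, -0.01, 0.01)),
                     k = 300)
      tri <- if (cyclic) cbind(idx, idx[c(2:n, 1)], idx[c(3:n, 1, 2)])
      else if (n >= 3) cbind(idx[1:(n - 2)], idx[2:(n - 1)], idx[3:n])
      else NULL
      angles <- if (!is.null(tri))
        cbind(tri, theta0 = 114 * pi / 180, ka = 60) else
          matrix(0, 0, 5)
      qu <- if (cyclic) cbind(idx, idx[c(2:n, 1)], idx[c(3:n, 1, 2)],
                              idx[c(4:n, 1, 2, 3)])
      else if (n >= 4) cbind(idx[1:(n - 3)], idx[2:(n - 2)],
                             idx[3:(n - 1)], idx[4:n])
      else NULL
      dihedrals <- if (!is.null(qu)) cbind(qu, amp = 1.4, mult = 3) else
        matrix(0, 0, 6)
      charges <- chargeSign0 * (-1)^(seq_len(n) - 1) *
        0.25 * (1 + stats::runif(n, -0.05, 0.05))
      list(bonds = bonds, angles = angles, dihedrals = dihedrals,
           charges = charges)
    }
    if (kind == "dimer") {
      h <- nAtoms %/% 2L
      f1 <- mkFrag(1:h, chargeSign0 = 1)
      f2 <- mkFrag((h + 1L):nAtoms, chargeSign0 = -1)
      bonds <- rbind(f1$bonds, f2$bonds)
      angles <- rbind(f1$angles, f2$angles)
      dihedrals <- rbind(f1$dihedrals, f2$dihedrals)
      charges <- c(f1$charges, f2$charges)
    } else {
      f <- mkFrag(1:nAtoms, cyclic = (kind == "ring"))
      bonds <- f$bonds; angles <- f$angles; dihedrals <- f$dihedrals
      charges <- f$charges
    }
    # nonbonded pairs: all pairs minus 1-2 and 1-3 neighbours
    adj <- matrix(FALSE, nAtoms, nAtoms)
    adj[bonds[, 1:2]] <- TRUE; adj[bonds[, 2:1]] <- TRUE
    excl <- adj | (adj %*% adj > 0)
    pm <- pairIndexMap(nAtoms) + 1L
    nb <- pm[!excl[pm], , drop = FALSE]
    new("ToyTopology", kind = kind, Z = rep(6L, nAtoms),
        masses = rep(12.011, nAtoms),
        bonds = bonds, angles = angles, dihedrals = dihedrals,
        charges = charges, ljEps = 0.12, ljSigma = 3.3, screenLength = 4,
        nbPairs = nb, seed = as.integer(seed), cache = new.env())
  })
}

#' Reference geometry of a toy topology
#'
#' Deterministic starting structure: chains as trans zigzags at the
#' equilibrium bond length and angle, rings as regular polygons with a
#' small out-of-plane ripple, dimer fragments as two parallel chains 4 A
#' apart.
#'
#' @param topology a [ToyTopology-class].
#' @return An [AtomicConfiguration-class].
#' @export
initialConfiguration <- function(topology) {
  n <- length(topology@Z)
  zig <- function(m, r0 = 1.52, theta = 114 * pi / 180) {
    half <- theta / 2
    dx <- r0 * sin(half); dy <- r0 * cos(half)
    cbind(x = (seq_len(m) - 1) * dx,
          y = dy * (seq_len(m) %% 2),
          z = 0.02 * sin(seq_len(m)))       # tiny ripple: no exact collinearity
  }
  xyz <- switch(topology@kind,
    chain = zig(n),
    ring = {
      r0 <- mean(topology@bonds[, 3])
      R <- r0 / (2 * sin(pi / n))
      th <- 2 * pi * (seq_len(n) - 1) / n
      cbind(R * cos(th), R * sin(th), 0.05 * sin(3 * th))
    },
    dimer = {
      h <- n %/% 2L
      rbind(zig(h), sweep(zig(n - h), 2, c(0, -4, 0), `-`))
    })
  atomicConfiguration(topology@Z, xyz)
}

.vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Scatter matrix mapping stacked per-term gradient pieces onto atoms, built
# once per topology and cached (keyed on the term index vector so modified
# copies sharing the cache environment rebuild it).
.toyScatter <- function(topology) {
  b <- topology@bonds; a <- topology@angles; dh <- topology@dihedrals
  nb <- topology@nbPairs
  allIdx <- c(b[, 1], b[, 2], a[, 1], a[, 3], a[, 2],
              dh[, 1], dh[, 2], dh[, 3], dh[, 4], nb[, 1], nb[, 2])
  key <- c(length(allIdx), sum(allIdx * seq_along(allIdx)))
  cc <- topology@cache
  if (is.null(cc$S) || !identical(cc$key, key)) {
    K <- length(allIdx)
    S <- matrix(0, length(topology@Z), K)
    S[cbind(allIdx, seq_len(K))] <- 1
    cc$S <- S
    cc$key <- key
  }
  cc$S
}

#' Energy and analytic forces of a toy potential
#'
#' Sums harmonic bond and angle terms, cosine dihedrals, Lennard-Jones and
#' screened-Coulomb (k_C q_i q_j exp(-r / l) / r) contributions; forces are
#' the exact analytic negative gradient of the energy.
#'
#' @param topology a [ToyTopology-class].
#' @param config an [AtomicConfiguration-class] or n x 3 matrix.
#' @return List with `energy` (kcal/mol) and `forces` (n x 3,
#'   kcal mol^-1 A^-1).
#' @export
toyEnergyForces <- function(topology, config) {
  xyz <- .asXYZ(config)
  n <- length(topology@Z)
  if (nrow(xyz) != n) stop("configuration does not match topology")
  E <- 0
  pieces <- vector("list", 11L)

  b <- topology@bonds
  if (nrow(b)) {
    dv <- xyz[b[, 1], , drop = FALSE] - xyz[b[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    if (any(r <= 0)) stop("coincident bonded atoms")
    E <- E + sum(0.5 * b[, 4] * (r - b[, 3])^2)
    dEdr <- b[, 4] * (r - b[, 3])
    gi <- dv * (dEdr / r)
    pieces[[1]] <- -gi
    pieces[[2]] <- gi
  }

  a <- topology@angles
  if (nrow(a)) {
    u <- xyz[a[, 1], , drop = FALSE] - xyz[a[, 2], , drop = FALSE]
    v <- xyz[a[, 3], , drop = FALSE] - xyz[a[, 2], , drop = FALSE]
    nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
    ct <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rowSums(u * v) / (nu * nv)))
    th <- acos(ct)
    st <- sqrt(1 - ct * ct)
    E <- E + sum(0.5 * a[, 5] * (th - a[, 4])^2)
    dEdth <- a[, 5] * (th - a[, 4])
    # dtheta/dr_i = (ct * u/nu - v/nv) / (nu * st);  symmetric for r_k
    gi <- (u * (ct / nu) - v / nv) / (nu * st) * dEdth
    gk <- (v * (ct / nv) - u / nu) / (nv * st) * dEdth
    pieces[[3]] <- -gi
    pieces[[4]] <- -gk
    pieces[[5]] <- gi + gk
  }

  dh <- topology@dihedrals
  if (nrow(dh)) {
    b1 <- xyz[dh[, 2], , drop = FALSE] - xyz[dh[, 1], , drop = FALSE]
    b2 <- xyz[dh[, 3], , drop = FALSE] - xyz[dh[, 2], , drop = FALSE]
    b3 <- xyz[dh[, 4], , drop = FALSE] - xyz[dh[, 3], , drop = FALSE]
    n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
    nb2 <- sqrt(rowSums(b2 * b2))
    phi <- atan2(rowSums(.vcross(n1, n2) * (b2 / nb2)), rowSums(n1 * n2))
    E <- E + sum(dh[, 5] * (1 + cos(dh[, 6] * phi)))
    dEdphi <- -dh[, 5] * dh[, 6] * sin(dh[, 6] * phi)
    n1sq <- rowSums(n1 * n1); n2sq <- rowSums(n2 * n2)
    dpi <- -n1 * (nb2 / n1sq)            # dphi/dr_i
    dpl <- n2 * (nb2 / n2sq)             # dphi/dr_l
    c12 <- rowSums(b1 * b2) / nb2^2
    c32 <- rowSums(b3 * b2) / nb2^2
    dpj <- -dpi * (1 + c12) + dpl * c32  # dphi/dr_j
    dpk <- -(dpi + dpj + dpl)            # dphi/dr_k by translation invariance
    pieces[[6]] <- -dpi * dEdphi
    pieces[[7]] <- -dpj * dEdphi
    pieces[[8]] <- -dpk * dEdphi
    pieces[[9]] <- -dpl * dEdphi
  }

  nb <- topology@nbPairs
  if (nrow(nb)) {
    dv <- xyz[nb[, 1], , drop = FALSE] - xyz[nb[, 2], , drop = FALSE]
    r2 <- rowSums(dv * dv)
    if (any(r2 <= 0)) stop("coincident nonbonded atoms")
    r <- sqrt(r2)
    s6 <- (topology@ljSigma / r)^6
    Elj <- 4 * topology@ljEps * (s6 * s6 - s6)
    dEdr_lj <- 4 * topology@ljEps * (-12 * s6 * s6 + 6 * s6) / r
    qq <- gdmlrConstants$coulomb * topology@charges[nb[, 1]] *
      topology@charges[nb[, 2]]
    scr <- exp(-r / topology@screenLength)
    Ec <- qq * scr / r
    dEdr_c <- -qq * scr * (1 / (topology@screenLength * r) + 1 / r2)
    E <- E + sum(Elj) + sum(Ec)
    gi <- dv * ((dEdr_lj + dEdr_c) / r)
    pieces[[10]] <- -gi
    pieces[[11]] <- gi
  }

  C <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  F <- if (is.null(C)) matrix(0, n, 3) else .toyScatter(topology) %*% C
  list(energy = E, forces = F)
}
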