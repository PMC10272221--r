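---
title: "Gradient-domain force fields and automated descriptor reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-domain force fields and automated descriptor reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`gdmlr` implements a *global* kernel machine-learning force field.  A
molecular geometry with $N$ atoms is represented by the complete
inverse-pairwise-distance descriptor
$$
\mathbf{x}(R) = \big(1/r_{ij}\big)_{i<j} \in \mathbb{R}^{N(N-1)/2},
$$
a simplified Coulomb matrix without charge weighting.  Features are indexed
lexicographically in the 0-based atom pair $(i, j)$, $i<j$; every mask,
importance table and report in the package uses this order.  The descriptor
is invariant under rigid translations and rotations, and its Jacobian with
respect to the Cartesian coordinates is analytic:
$\partial (1/r_{ij}) / \partial \mathbf{r}_i = -(\mathbf{r}_i -
\mathbf{r}_j)/r_{ij}^3$, with the $i$ and $j$ blocks exact negatives.

Training is done in the gradient domain: the model is a Gaussian-process
posterior mean over an energy surface observed only through forces.  With a
stationary kernel $\kappa(d)$ on the descriptor-space Euclidean distance
$d = \lVert \mathbf{x}(R_a) - \mathbf{x}(R_b) \rVert$, the force–force
covariance blocks are
$$
K_{ab} \;=\; J_a^\top \big( -g(d)\, I \;-\; h(d)\, u u^\top \big) J_b,
\qquad u = \mathbf{x}_a - \mathbf{x}_b,
$$
where $g = \kappa'(d)/d$, $h = g'(d)/d$ and $J$ are descriptor Jacobians.
Training solves the dense symmetric system
$(K + \lambda\,\overline{\mathrm{diag}(K)}\, I)\,\alpha = y$ by Cholesky
factorization, where $y$ stacks the reference forces.  The force predictor
is the kernel expansion $\widehat{F}(x) = \sum_b K(x, x_b)\,\alpha_b$ and
the energy predictor is its exact antiderivative
$$
\widehat{E}(x) = c - \sum_b \alpha_b^\top \nabla_{R_b} \kappa(x, x_b)
             = c + \sum_b g(d_b)\, u_b^\top J_b \alpha_b ,
$$
so $\widehat{F} = -\nabla \widehat{E}$ holds analytically (both sides share
one kernel-derivative code path; the test suite verifies the identity to
$10^{-6}$ relative by central differences).  Energies influence the model
only through the integration constant $c$, fitted so the mean predicted
energy over the training set matches the mean reference energy.

**Kernel.**  The default is Matérn 5/2,
$\kappa(d) = (1 + \sqrt{5}d/\sigma + 5d^2/3\sigma^2)\,e^{-\sqrt{5}d/\sigma}$:
twice continuously differentiable (the minimum regularity for a
well-defined force kernel), with both $g$ and $h$ smooth at $d=0$.  Any
twice-differentiable stationary kernel could be substituted behind the same
contract.

**No permutational symmetrization** is applied: descriptors of different
models (global, local-cutoff, reduced) stay directly comparable
feature-by-feature.

# Descriptor reduction by masking loss

The reduction procedure asks, for every feature $n$ of a trained model,
how much the *similarity measure* actually uses it.  The masked predictor
$\mathrm{ML}^n_{mask}$ zeroes feature $n$ for **all** configurations
(training and query alike) while keeping $\alpha$, $\sigma$ and $\lambda$
fixed, and the masking loss accumulates the squared prediction change over
a test subset:
$$
L_n = \sum_{i=1}^{N_{test}}
\big\lVert F_{orig}(x_i) - F^n_{mask}(x_i) \big\rVert^2 .
$$
Features with small $L_n$ contribute little to the learned similarity and
are candidates for removal.  Reduction removes the
$\lfloor p/100 \cdot n \rfloor$ features with the smallest losses at a
chosen percentile $p$ (nearest-rank truncation with floor; ties broken by
ascending feature index) and retrains from scratch on the same training
indices.

Design choices worth making explicit, since the procedure admits variants:

* **Masking convention.**  Because the feature is zeroed consistently
  everywhere, zeroing equals *dropping the coordinate*: the package
  implements masked and reduced descriptors as a projection that removes
  the feature from both the value vector and the Jacobian.  This avoids
  spurious kernel-gradient contributions that a zeroed-but-present
  coordinate would still inject through its Jacobian row.  A `mode =
  "value"` flag masks only the value channel (distances change, gradients
  kept) for sensitivity studies; the default masks both channels.
* **Loss on forces.**  $L_n$ is computed on the force predictor — the
  model's native output, and the quantity that drives dynamics.  Energies
  are excluded from the loss.
* **Length scale after reduction.**  Dropping features shrinks
  descriptor-space distances, so by default the length scale is re-selected
  for the reduced model (`resigma = TRUE`); the median-distance heuristic
  recomputed on the surviving features serves as the default selector, and
  a validation-grid search (`selectSigma()`) is available where a tuned
  scale matters.  `resigma = FALSE` keeps the original $\sigma$ for strict
  ablations.
* **Percentile convention.**  The floor convention reproduces the natural
  worked counts (60% of 1770 features removes 1062; the 65th percentile of
  861 removes 559).  A rounding-up convention would remove one more feature
  when $p n / 100$ is fractional; the package fixes floor everywhere.

The local-cutoff baseline (`buildLocalMask()`) keeps a feature only if its
distance stays within the cutoff (default 5 Å) in *every* configuration of
the dataset — the hard-locality descriptor the reduced model is compared
against.  Robustness of the selection is quantified by
`removedSetOverlap()`: the fraction of features removed by all of several
runs, relative to the smallest removed set.

# Interpretation tools

Because the predictor is linear in $\alpha$, it partitions exactly:

* **Per-atom contributions** (`atomContribution()`): restricting the sum to
  the three coefficient components of training-point atom $k$ gives that
  atom's contribution $F^k$ to the prediction, with $\sum_k F^k = F$
  bit-tight.  The norm of the atom-$l$ components of $F^k$, averaged over
  configurations and log-min-max normalized to $[0,1]$ (with an
  $\varepsilon = 10^{-12}\max$ shift so masked channels' exact zeros
  survive the logarithm), is the interaction map.  The map is a
  contribution of $k$ to $l$ and is *not* symmetric by construction.
* **Per-feature channels** (`featureContributions()`): the chain rule
  splits $F = J_x^\top w$ into channels $F_{(n)} = w_n J_x[n,]$, again an
  exact partition.  The mean channel magnitude against the mean feature
  distance is the input to `classifyFeatures()`, an OLS fit of
  $\log \lVert F_{(n)} \rVert$ on $\log r$: features with $r^2$ at or above
  0.9 are labelled *linear* (power-law respondents — a slope near $-2$ is
  the Jacobian scaling of Coulombic channels), the rest *stochastic*.
  The per-feature definition is a package choice: the plotted "feature
  contribution" admits several readings, and the chain-rule channel was
  chosen because it is the unique exact partition of the predictor.
* **Short/long decomposition** (`shortLongDecomposition()`): two criteria
  are implemented — short iff the *maximum* distance over the dataset stays
  below the cutoff, or short iff the *mean* does.  Both appear in the
  literature describing this analysis; neither is endorsed as canonical,
  and both are selectable.

# The synthetic data generator

Real reference datasets for this class of model are thermally sampled DFT
trajectories of flexible molecules.  The package's stand-in
(`buildToyMolecule()` + `generateDataset()`) emulates their statistical
structure with an analytic potential: stiff harmonic bonds
(1.52 Å, 300 kcal mol⁻¹ Å⁻²) and angles (114°, 60 kcal mol⁻¹ rad⁻²),
threefold cosine torsions (1.4 kcal/mol) for conformational flexibility,
and — crucially for the long-range story — Lennard-Jones
(ε = 0.12 kcal/mol, σ = 3.3 Å) plus screened-Coulomb interactions
$k_C q_i q_j e^{-r/\ell}/r$ with alternating partial charges
(±0.25 e, ℓ = 4 Å) between beads three or more bonds apart.  Chains
(peptide/fatty-acid analogue), rings, and two-fragment dimers
(base-pair/host–guest analogue, bound only by nonbonded terms) are
provided.  Labels are exact analytic energies and forces; sampling is
Langevin dynamics (BAOAB) at 300–400 K with a 1 fs step, an equilibration
stretch discarded, and frames strided far apart for decorrelation.  Seeds
jitter bond lengths (±1%) and charges (±5%) so replicate "molecules"
differ, and every stochastic step is reproducible from its integer seed.

What this emulates well: the coexistence of stiff local fluctuations with
weak, collectively structured long-range forces — precisely the regime
where a global descriptor is over-defined and reduction has something to
remove.  What it does not emulate: electronic effects (bond
breaking/formation, polarization, many-body dispersion), hydrogen-atom
mass contrast, and the conformational multiplicity of real biomolecules.
Passing tests therefore demonstrate the correctness and internal
consistency of the machinery and the qualitative reduction phenomenology —
not chemical accuracy on any real molecule.

A deliberate feature of the chain systems: descriptor distance is dominated
by floppy long-range features while force variance is dominated by stiff
bonds, so the global model's accuracy is limited by feature dilution, and
percentile reduction on a sufficiently long chain (≈20 beads) leaves
accuracy essentially unchanged at p = 50 while collapsing at p = 95 when
essential features go.  Short chains (8–10 beads) behave like small
semi-rigid molecules: only mild reduction is tolerated — both regimes are
asserted in the test suite.

# Numerical choices

* **Regularization** defaults to $\lambda = 10^{-10}$ (dimensionless; the
  identity is scaled by the mean kernel diagonal so $\lambda$ is
  unit-consistent across descriptors).
* **$\lambda = 0$ is an explicit interpolation mode.**  The force-kernel
  matrix always carries the rigid-motion null space of the descriptor
  Jacobians (six directions per configuration), so a plain Cholesky
  factorization of the unregularized system must fail.  At $\lambda = 0$
  the package solves in the minimum-norm sense via SVD; physical force
  labels (zero net force and torque) lie in the range, so training points
  are reproduced exactly.  For $\lambda > 0$ a Cholesky failure raises a
  conditioning error advising a larger $\lambda$.
* **Length-scale heuristic**: the median nonzero pairwise descriptor
  distance over (at most 128) training frames.  Grid selection minimizes
  validation force RMSE, with ties resolved towards the smaller $\sigma$
  and duplicate grid entries trained once.
* **Integrators**: velocity Verlet (NVE) and Langevin BAOAB.  Unit bridge
  constants: $a = 4.184\times10^{-4}\, F/m$ (kcal mol⁻¹ Å⁻¹, amu → Å fs⁻²),
  $k_B = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹, Coulomb constant
  332.06 kcal mol⁻¹ Å e⁻², and 1 kcal mol⁻¹ Å⁻¹ = 69.4786 pN for
  steering-force inputs (derived from CODATA values, documented to six
  significant figures).
* **Steering** applies ±f along the instantaneous line connecting the two
  chosen atoms (re-evaluated every step, pushing them apart); a
  `fixedAxis` flag freezes the initial axis instead.  The magnitude is
  per atom.  Constant-force steering does work on the system, so NVE
  energy conservation is not expected in steered runs.
* **Instability detection**: a clash is any non-bonded pair closer than
  0.7 Å; fragmentation is any bond stretched beyond 2.5× its equilibrium
  length.  Both thresholds are arguments.

# Problem sizes used by the tests and the acceptance script

The shipped checks run desk-scale versions of the experiments: chains of
8–32 beads, training sets of 20–100 configurations, validation/test splits
of 20–100 frames, masking losses over ~30 test configurations, 10–100 ps of
dynamics at 0.5–1 fs steps, and five random seeds for every stochastic
claim (medians reported).  These sizes were chosen so that each experiment
exercises the full pipeline at comfortable interactive cost while leaving
the qualitative phenomenology — flat-then-collapsing reduction curves,
near-linear reduced-descriptor scaling against exactly quadratic global
sizes, stable reduced-model dynamics, steering-induced chain extension —
clearly resolvable above seed noise.

# Known limitations

* Dense exact training scales as $O((3NM)^3)$; the package targets
  $3NM \lesssim 10^4$ (desk scale) and provides no iterative/inducing-point
  solver, no GPU path, and no periodic boundary conditions.
* The masking loss treats features independently; correlated groups of
  features can share importance, and no grouped or sparsity-regularized
  selection is attempted.
* The energy predictor's constant is fixed from training-energy means
  only; absolute energies inherit any systematic offset of the labels.
* Element coverage of the mass/symbol tables extends through Kr, which is
  ample for the organic systems targeted.

# Pipeline configuration

`runPipeline()` accepts a YAML (or list) configuration with sections
`dataset` (a file path or a `synthetic` block: kind, n_atoms, temperature,
n_samples, stride, dt), `split` (n_train, n_valid, optional n_test),
`model` (sigma or sigma_grid, lambda), `reduction` (percentiles,
n_importance, resigma) and optional `md` settings.  Unknown keys anywhere
raise a `gdmlr_config_error` before any computation; the seed is mandatory.
Every run writes its artifacts plus a `manifest.json` with md5 content
hashes, and identical configurations reproduce all deterministic artifacts
bit-exactly.  A thin command-line wrapper lives at
`inst/scripts/gdmlr-pipeline.R`.
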