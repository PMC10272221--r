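Package: gdmlr
Type: Package
Title: Gradient-Domain Kernel Force Fields with Automated Descriptor
    Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains global kernel machine-learning force fields on molecular
    energies and forces using the complete inverse-pairwise-distance
    descriptor, and reduces the descriptor dimensionality automatically by
    ranking features with a masking loss, truncating at a percentile and
    retraining.  Includes per-atom and per-feature decompositions of the
    force prediction (interaction maps, feature contribution profiles,
    short/long-range decompositions, descriptor scaling fits), analytic toy
    molecular potentials with thermal sampling for building labelled
    datasets, and a molecular-dynamics engine (velocity Verlet and Langevin
    BAOAB, optional constant-force steering) for stability and pulling
    experiments with trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'gdmlr-package.R'
    'constants.R'
    'AllClasses.R'
    'descriptor.R'
    'dataio.R'
    'kernel.R'
    'gdml.R'
    'reduction.R'
    'analysis.R'
    'toys.R'
    'md.R'
    'pipeline.R'
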