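Package: freseanr
Title: Frequency-Selective Anharmonic Mode Analysis and Enhanced-Sampling
    Post-Processing for Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts anharmonic low-frequency vibrational modes from
    molecular dynamics trajectories by frequency-resolved eigendecomposition
    of mass-weighted velocity cross-correlation spectra (FRESEAN mode
    analysis) on a two-beads-per-residue coarse-grained representation.
    Includes reproducibility statistics for modes across replica
    simulations, export of selected modes as collective variables for
    well-tempered metadynamics (PLUMED input generation), and
    post-processing of biased trajectories (COLVAR/HILLS parsing,
    reweighting, replica-averaged free-energy surfaces with uncertainties,
    Shannon entropy and Bhattacharyya similarity metrics, state free-energy
    differences, k-means microstates, minimum free-energy paths). Ships a
    synthetic-data generator (Langevin dynamics of harmonic bead networks,
    rigid-body diffusion, two-state systems, a toy well-tempered
    metadynamics engine) providing analytic ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ggplot2,
    rlang,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    bio3d
Config/testthat/edition: 3
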