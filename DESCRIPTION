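Package: latticevibes
Title: Lattice Disorder Models for Protein Crystal Diffuse Scattering
Version: 0.1.0
Authors@R:
    person("latticevibes", "developers", email = "latticevibes@example.org",
           role = c("aut", "cre"))
Description: Tools to model and subtract lattice-disorder scattering from
    protein crystal total-scattering data. Implements a refinable rigid-body
    crystalline elastic network model of lattice vibrations solved by the
    Born/Von-Karman method (per-wavevector dynamical matrices, generalized
    coordinate covariances, TLS matrices, and atomic displacement
    parameters), one-phonon diffuse scattering simulation of halo features,
    staged symmetry-restrained refinement of spring constants against
    measured halos, a model-free estimation of inter-protein displacement
    covariances by deconvolution of 3D-delta-PDF lattice peaks against the
    Patterson origin peak, and map utilities (isotropic/variational
    splitting, missing-voxel filling, robust error-weighted Savitzky-Golay
    regridding, target-map assembly, and resolution-shell statistics).
    Includes a synthetic-fixtures module generating toy crystals, spring
    networks, and noisy diffuse maps so that the entire workflow is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
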