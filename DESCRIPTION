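Package: ardecon
Title: Anisotropic-Resolution Restoration of Cryo-EM Density Maps by
    Directional-FSC-Guided Deconvolution
Version: 0.1.0
Authors@R:
    person("ardecon", "developers", email = "ardecon@example.org",
           role = c("aut", "cre"))
Description: Restores single-particle cryo-EM density maps that suffer
    anisotropic resolution caused by preferred particle orientation.  The
    pipeline computes directional Fourier shell correlation (dFSC) between
    two half-maps over a Fibonacci set of cone directions, renders the dFSC
    as a 3D Fourier-space volume, multiplies it with the transform of a
    spherical Gaussian to obtain an optical transfer function (OTF), and
    deconvolves the full map with an entropy-regularized iterative solver
    that inpaints missing-cone information.  Includes MRC2014 volume I/O, a
    synthetic missing-cone data generator for end-to-end validation, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
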