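Package: minfluxvpp
Title: MINFLUX Excitation Simulation with a Variable Phase Plate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates MINFLUX excitation beams generated by a fast variable
    phase plate built from an electro-optical modulator (EOM), a binary
    spatial light modulator (SLM) and a polarizer. Models the
    polarization-optical chain with Jones calculus, including numerical
    compensation of SLM imperfections with a half-wave plate. Computes
    vectorial high-NA excitation point-spread functions (PSFs) for bisected,
    top-hat, vortex and interferometric pupil phase patterns via the
    vectorial Debye diffraction integral, scans their intensity minima
    through the EOM phase, and evaluates localization performance through
    Fisher information and Cramer-Rao bounds as well as Monte-Carlo photon
    probing with a Poisson maximum-likelihood position estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
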