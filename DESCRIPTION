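Package: gpqpi
Title: Geometric-Phase Quantitative Phase Imaging Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics simulator and single-shot reconstruction pipeline for
    quantitative phase imaging with geometric-phase (Pancharatnam-Berry)
    optics. Forms achromatic off-axis holograms of polarization-coded
    samples (piezo-displaced mirrors, spatial-light-modulator pixel grids,
    polarization-directed lenses, live-cell phantoms) under broadband
    spatially incoherent illumination, restores the phase retardance by
    Fourier sideband demodulation and least-squares unwrapping, and
    quantifies the result as surface height, cellular dry-mass density
    (Davies relation), temporal and spatial precision statistics, watershed
    cell morphometrics, and diffractive lens characterization by
    angular-spectrum propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
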