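Package: neodot
Title: Diffuse Optical Tomography Analysis of Neonatal Seizure Haemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing simultaneous diffuse optical tomography (DOT)
    and EEG recordings of the neonatal brain, with a focus on the haemodynamic
    response to electrographic seizures. Provides probe-geometry and recording
    containers with plain-text serialisation, DOT/EEG clock alignment from
    shared synchronisation pulses, channel quality control, spline-based
    step-artifact correction, zero-phase temporal filtering, optical-density
    conversion and modified Beer-Lambert haemoglobin spectroscopy, layered
    tetrahedral head meshes with a continuous-wave photon-diffusion finite
    element solver and adjoint sensitivity (Jacobian) construction,
    multispectral Tikhonov image reconstruction with grey-matter surface
    projection, event-locked response metrics (time-to-peak, peak-to-trough,
    recovery), a paired hemispheric EEG power comparison, and a synthetic-scene
    generator that renders ground-truth cortical haemodynamics into realistic
    dual-wavelength channel intensities for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
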