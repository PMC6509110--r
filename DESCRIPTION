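Package: sheetloc
Title: Bessel Light-Sheet 3D Single-Molecule Localization Microscopy Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for large-scale 3D single-molecule localization
    microscopy with Bessel-beam light-sheet illumination and astigmatic axial
    encoding. Models the annular-pupil excitation profile and optical-sectioning
    thickness, simulates seeded acquisitions of spontaneously blinking emitters
    on filament, nuclear-pore-ring and fiducial ground truth with sCMOS noise,
    fits an astigmatic defocusing calibration and inverts PSF widths to axial
    position, detects and fits blinking events with theoretical localization
    uncertainties, corrects drift by fiducial tracking or image cross
    correlation, deskews sample-scan coordinates to the coverslip frame,
    renders uncertainty-weighted density maps, estimates resolution by Fourier
    ring correlation versus accumulated volumes, and reconstructs nuclear pore
    complexes by candidate selection, kernel-density centering, top-ranked
    overlay averaging and ring ("donut") fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    tiff,
    png,
    minpack.lm,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
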