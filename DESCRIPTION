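Package: savehsi
Title: Spectrum-Aided Vision Enhancer for Virtual Narrow-Band Endoscopic Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts standard white-light endoscopy RGB images into per-pixel
    visible-range reflectance spectra (380-780 nm at 1 nm) and renders simulated
    narrow-band images from the 415 nm and 540 nm hemoglobin-absorption bands.
    Implements CIE 1931 colorimetry on a fixed wavelength grid, polynomial
    correction of camera tristimulus errors fitted on a 24-patch colour target,
    a PCA-basis multivariate regression from corrected tristimulus values to
    reflectance spectra, ENVI-style spectral cube input/output, synthetic
    calibration targets and vessel-bearing tissue phantoms for validation, and
    object-detection dataset utilities (Pascal-VOC to YOLO annotation
    conversion, image resizing, train/validation/test splitting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    xml2,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    farver,
    withr
Config/testthat/edition: 3
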