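Package: droiq
Title: Digital Reference Object Phantoms and Automated MR Image Quality Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates ACR-style digital reference object phantoms (simple disk,
    high-contrast resolution, low-contrast detectability) analytically in continuous
    k-space from Jinc (Bessel J1) disk transforms, samples them on an FFT grid, adds
    calibrated complex Gaussian acquisition noise, and reconstructs reference magnitude
    images by inverse FFT. Provides a fully automated image-quality evaluation suite
    (geometric accuracy, percent intensity uniformity, ghosting ratio, edge-sharpness
    FWHM via Lorentzian fits of the edge spread function derivative, NEMA
    difference-image SNR, high-contrast resolution by Otsu-thresholded peak detection,
    and low-contrast detectability by calibrated sliding-window template matching),
    plus batch orchestration so any reconstruction algorithm can be benchmarked against
    the inverse-FFT reference, including variable-density Cartesian undersampling masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    png,
    optparse
Config/testthat/edition: 3
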