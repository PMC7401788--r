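Package: pxst
Title: Ptychographic X-Ray Speckle Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Wavefront metrology and projection imaging for highly divergent
    X-ray illumination by ptychographic speckle tracking. Simulates near-field
    scan data under an aberrated astigmatic pupil (Siemens-star and hexagonal
    phantoms, Fresnel propagation, Poisson noise), and recovers the
    illuminating wavefront (phase, phase gradients, ray angles) together with
    an undistorted magnified reference hologram of the sample. Includes
    Thon-ring and sum-squared-error defocus initialization, Gaussian
    regularization schedules for quasi-periodic samples, transport-of-intensity
    and contrast-transfer-function thickness retrieval, Fourier power-spectrum
    resolution estimation, and split-half angular sensitivity metrology, with a
    CXI-style HDF5 scan container.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    pracma,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
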