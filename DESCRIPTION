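Package: mplsnir
Title: Modified Partial Least Squares Calibration for Near-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric calibration of element concentrations from
    near-infrared (NIR) reflectance spectra. Implements the scatter
    corrections (multiplicative scatter correction, standard normal
    variate, detrend) and gap-segment derivative math treatments used in
    NIR practice, modified partial least squares (MPLS) regression with
    per-wavelength residual standardization between factors, Mahalanobis
    global-H and chemistry-residual T outlier elimination, grouped
    cross-validation with factor selection, and the standard calibration
    and external-validation statistics (RMSEC, RMSECV, RMSEP, bias,
    bias-corrected RMSEP, RPD). A seeded generator of propolis-like
    datasets with correlated element concentrations and element-linked
    absorption bands supports end-to-end method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
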