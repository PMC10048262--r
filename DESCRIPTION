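Package: libsvarsel
Title: Wavelength Selection and Chemometric Regression for LIBS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of heavy metals (Cd, Cu, Pb) from laser-induced
    breakdown spectroscopy (LIBS) spectra. Provides a synthetic LIBS
    spectrum generator with known ground truth, area normalization and
    calibration/validation/prediction splitting, a from-scratch NIPALS
    partial least squares engine with cross-validation, three wavelength
    selection algorithms (competitive adaptive reweighted sampling,
    random frog, uninformative variable elimination), a uniform interface
    over PLSR, support vector regression and gradient boosting regressors,
    and an evaluation grid reporting calibration, validation and
    prediction R-squared and RMSE per element, model and selector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
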