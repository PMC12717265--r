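Package: acuitysim
Title: Visual Acuity Prediction from Ocular Wavefront Aberrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Tools to predict monocular visual acuity (VA) from ocular
    wavefront aberrations. Implements a functional simulation pipeline that
    renders Sloan optotypes at logMAR-scaled sizes, degrades them through a
    subject's Zernike-defined optics (pupil function, Stiles-Crawford
    apodization, point spread function), applies retinal sampling and a
    neural transfer function (standard contrast sensitivity over a mean
    optical transfer function with an age factor), adds neural noise, and
    scores VA with the clinical letter-by-letter line protocol using either
    a small convolutional recognizer or a template-correlation observer.
    Also provides a tabular route: least-squares gradient boosting of
    regression trees implemented from scratch (with an XGBoost adapter)
    trained on Zernike coefficients, age and gated amplitude of
    accommodation, with the metrics suite, 3-sigma outlier handling,
    feature importance and stratified analyses used in defocus-curve
    studies. A seeded synthetic-cohort generator with a psychometric
    simulated observer makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    png,
    withr
Config/testthat/edition: 3
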