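Package: barospiro
Title: Barometer-Based Wearable Spirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for performing spirometry with differential barometric
    pressure sensors embedded in a face mask. Converts inside/outside mask
    pressure differentials into airflow through physically motivated
    regression models (asymmetric root-basis curves, polynomials, and a
    small feed-forward network trained by Levenberg-Marquardt), derives
    clinical forced-vital-capacity vitals (FVC, FEV1, PEF, FEF25, FIF25)
    and continuous tidal volume from the predicted flow, and quantifies
    agreement against a reference spirometer with a range-normalised RMSE
    metric under individual, inclusive and subject-exclusive calibration
    schemes. Includes a seeded synthetic-breathing generator so the whole
    chain is exercisable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
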