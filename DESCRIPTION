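Package: flaskOD
Title: Colorimetric Soft Sensor for Optical Density of Shake-Flask Cultures
Version: 0.1.0
Authors@R: person("flaskOD", "Developers", email = "flaskod@example.org",
    role = c("aut", "cre"))
Description: Non-invasive estimation of optical density (OD), a biomass proxy,
    from colour images of shake-flask cultures. Images are converted to CIELAB,
    the flask-medium region of interest is selected by K-means clustering and
    tracked across timepoints by nearest-centre matching, and OD is predicted
    from the region's colour by a log-log multivariate linear regression with
    per-experiment baseline and whole-image illumination-reference covariates.
    Includes residual diagnostics (autocorrelation with whiteness bounds,
    Kolmogorov-Smirnov normality), leave-one-experiment-out and leave-one-out
    cross-validation, a fully seeded synthetic campaign generator with rendered
    flask scenes and ground-truth masks, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jpeg,
    jsonlite,
    optparse,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
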