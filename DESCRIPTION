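Package: aircloud
Title: Cloud-Model Assessment of Air Quality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assessment of ambient air quality with the normal cloud model.
    Daily pollutant concentrations (PM2.5, PM10, SO2, CO, NO2, O3) are
    summarised into (Ex, En, He) clouds by a moment-based backward cloud
    generator, classified against standard clouds built from the Chinese
    regulatory grading bands (GB 3095-2012 / HJ 633-2012) by the maximum
    membership principle, and cross-validated with grey relational analysis.
    Includes individual and composite air quality index (IAQI/AQI)
    computation by breakpoint interpolation, a seasonal synthetic data
    generator, and cloud-picture rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
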