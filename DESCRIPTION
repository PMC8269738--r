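Package: nestcamo
Title: Camouflage Quantification for Ground-Nest Eggs in Visible and
    Ultraviolet Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the camouflage of eggs in ground nests from
    dual-band (visible + ultraviolet) photographs. Images are calibrated to
    reflectance against an in-frame grey standard, mapped into the cone-catch
    spaces of dichromatic, trichromatic and tetrachromatic predators via a
    visual-pigment nomogram, and compared to the surrounding microhabitat with
    filter-bank texture signatures and a chi-square histogram distance. A
    synthetic nest-scene generator with a radiation-driven egg-fading model
    supports end-to-end replication of sun-exposure experiments at desk scale,
    including per-treatment radiation schedules and reflectance-change
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
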