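Package: photoloc
Title: Radiometric and Visual Modelling of Diurnal Active Photolocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models whether a small diurnal fish can detect the
    retroreflective eyeshine that its own "ocular spark" (redirected
    downwelling sunlight) induces in the pupil of a cryptic sit-and-wait
    predator. Propagates photon fluxes along the baseline and
    spark-retroreflection optical paths, computes photoreceptor quantum
    catches, receptor-noise-limited chromatic contrasts (in just-noticeable
    differences) and achromatic Michelson contrasts, and solves for the
    maximum distance at which each contrast exceeds its detection
    threshold. Includes a synthetic-data generator for underwater ambient
    light, visual-pigment sensitivity templates, reflectance spectra and
    treatment-dependent approach/retreat trajectories, plus exact 2x2
    contingency statistics (Fisher's exact test with conditional
    maximum-likelihood odds ratio) for the proximity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
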