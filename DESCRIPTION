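Package: burnsel
Title: Habitat-Selection Analysis of Predators in Burned Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible used/available habitat-selection pipeline for
    animals in post-fire landscapes, built around Random-Forest
    classification with Model-Improvement-Ratio variable selection and
    permutation tests of model significance. Includes a raster data model
    with terrain covariates (heat load index, compound topographic index,
    D8 flow accumulation, distance transforms, focal statistics, nibble
    land-cover cleanup), a synthetic fire-mosaic landscape generator with
    controlled burn-class area fractions, and a GPS telemetry simulator
    with a known habitat-selection function, so the whole analysis can be
    exercised end to end without any proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
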