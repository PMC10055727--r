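Package: cdomphoto
Title: Steady-State Photochemistry of Chromophoric Dissolved Organic Matter
    in Sunlit Surface Waters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models how the spectral properties of chromophoric dissolved
    organic matter (CDOM) control the steady-state concentrations of
    photochemically produced reactive intermediates (hydroxyl radical,
    carbonate radical, CDOM excited triplet states, and singlet oxygen) in
    well-mixed sunlit surface waters.  CDOM absorbance follows the
    exponential spectral-slope model, and CDOM competes with nitrate and
    nitrite for solar photons; absorbed-photon budgets are converted into
    formation rates, first-order sink budgets, and steady-state
    concentrations.  Includes scenario presets and a random scenario
    generator, spectral-parameter and dissolved-organic-carbon sensitivity
    sweeps, equivalent-DOC inversion, and a small pipeline front end that
    writes annotated CSV sweep tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
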