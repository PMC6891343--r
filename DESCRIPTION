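Package: leafthz
Title: Nondestructive Leaf Water Content from Terahertz Transmittance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute leaf water mass nondestructively by combining
    terahertz (2.55 THz) transmission measurements with photographic leaf area.
    Computes Beer-Lambert optical depth from raw incident/transmitted
    intensities, measures projected leaf area from scaled RGB images (manual
    polygon outline or automatic greenness segmentation), fits the per-species
    linear calibration between the optical-depth x area product and gravimetric
    water mass, and inverts the fit to predict water mass with delta-method
    uncertainty. Ships a seeded simulator of six broadleaf species (Corylus
    avellana, Ostrya carpinifolia, Quercus suber, Vitis vinifera, Quercus ilex,
    Laurus nobilis) so the whole pipeline is testable without instrument
    hardware, plus multi-species summary statistics (Tukey-Kramer compact
    letter displays, per-species correlation tables) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    MASS,
    jsonlite,
    yaml,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
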